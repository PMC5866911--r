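# 1-Mb window decomposition of genomic variance from saved MCMC states.

#' Per-window share of genomic variance
#'
#' Assigns each marker to the non-overlapping 1-Mb window
#' floor(position_bp / 1e6) on its chromosome. For every saved MCMC
#' state, the genomic value of window w is Z_w u_w and its share is the
#' variance of that value across animals divided by the variance of the
#' total genomic value Z u; the reported percentage is 100 times the
#' posterior mean of the per-state shares. States with zero total
#' genomic variance are skipped in the average (and counted). Windows
#' explaining more than `reported_pct` are flagged `reported`, more than
#' `top_pct` flagged `top`.
#'
#' @param fit a [bayesc()] fit.
#' @param map marker map (`marker_id`, `chromosome`, `position_bp`)
#'   covering the fit's markers.
#' @param window_bp window width in bp (default 1 Mb).
#' @param reported_pct,top_pct flag thresholds in percent (defaults 1.0
#'   and 3.0).
#' @return data frame of class `window_result`: `chromosome`,
#'   `window_mb`, `pct_genomic_variance`, `n_snps`, `reported`, `top`,
#'   sorted by chromosome and position. The number of skipped
#'   zero-variance states is attached as attribute `"n_skipped"`.
#' @export
window_variance <- function(fit, map, window_bp = 1e6,
                            reported_pct = 1.0, top_pct = 3.0) {
  if (!inherits(fit, "bayesc")) stop_invalid("fit must be a bayesc object")
  idx <- match(colnames(fit$effects), map$marker_id)
  if (anyNA(idx))
    stop_invalid("markers missing from the map: ",
                 paste(utils::head(colnames(fit$effects)[is.na(idx)], 5),
                       collapse = ", "))
  chrom <- as.character(map$chromosome[idx])
  win <- floor(map$position_bp[idx] / window_bp)
  wkey <- paste(chrom, win, sep = ":")
  Z <- fit$design$Z
  U <- fit$effects                     # states x markers
  tot <- col_vars(Z %*% t(U))          # total genomic variance per state
  ok <- is.finite(tot) & tot > 0
  n_skip <- sum(!ok)
  if (n_skip > 0)
    message("window_variance: skipped ", n_skip,
            " state(s) with zero total genomic variance")
  if (!any(ok))
    stop_invalid("no saved state has positive genomic variance")
  groups <- split(seq_along(wkey), wkey)
  res <- lapply(names(groups), function(key) {
    j <- groups[[key]]
    vw <- col_vars(Z[, j, drop = FALSE] %*% t(U[, j, drop = FALSE]))
    share <- mean(vw[ok] / tot[ok])
    k <- j[1]
    data.frame(chromosome = chrom[k], window_mb = win[k],
               pct_genomic_variance = 100 * share, n_snps = length(j),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chromosome, out$window_mb), , drop = FALSE]
  out$reported <- out$pct_genomic_variance > reported_pct
  out$top <- out$pct_genomic_variance > top_pct
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skip
  class(out) <- c("window_result", class(out))
  out
}

#' Prune adjacent high-variance windows
#'
#' Among each maximal run of adjacent (consecutive 1-Mb, same
#' chromosome) windows that all exceed `threshold` percent of the
#' genomic variance, only the window with the greatest percentage is
#' kept; all other windows pass through unchanged.
#'
#' @param windows a window table from [window_variance()] (needs
#'   `chromosome`, `window_mb`, `pct_genomic_variance`).
#' @param threshold percent threshold defining a run (default 3.0).
#' @return the pruned window table, same columns, sorted.
#' @export
merge_adjacent <- function(windows, threshold = 3.0) {
  w <- windows[order(windows$chromosome, windows$window_mb), , drop = FALSE]
  hot <- w$pct_genomic_variance > threshold
  run_id <- integer(nrow(w))
  cur <- 0L
  for (i in seq_len(nrow(w))) {
    if (!hot[i]) { run_id[i] <- NA_integer_; next }
    new_run <- i == 1L || !hot[i - 1L] ||
      w$chromosome[i] != w$chromosome[i - 1L] ||
      w$window_mb[i] != w$window_mb[i - 1L] + 1L
    if (new_run) cur <- cur + 1L
    run_id[i] <- cur
  }
  drop <- rep(FALSE, nrow(w))
  for (r in unique(run_id[!is.na(run_id)])) {
    members <- which(!is.na(run_id) & run_id == r)
    if (length(members) > 1L) {
      best <- members[which.max(w$pct_genomic_variance[members])]
      drop[setdiff(members, best)] <- TRUE
    }
  }
  out <- w[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a window table
#'
#' @param windows output of [window_variance()].
#' @param path destination TSV.
#' @export
write_windows <- function(windows, path) {
  write_tsv(as.data.frame(windows), path)
}

#' Read a window table written by [write_windows()]
#'
#' @param path TSV path.
#' @export
read_windows <- function(path) {
  w <- read_tsv(path)
  w$chromosome <- as.character(w$chromosome)
  w
}
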