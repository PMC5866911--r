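# Bayes-C / Bayes-Cpi whole-genome regression: design construction, the
# fitting function and its S3 methods.

#' Build a GWAS design for one pairwise-THI trait
#'
#' Assembles y, X and Z for the mixed linear model y = X beta + Z u + e.
#' Fixed effects are an intercept plus dummy-coded sex, sire breed and
#' contemporary group (farrowing group x pen), with the first level of
#' each factor dropped; aliased columns are removed so X has full column
#' rank. Z is the dosage matrix restricted to animals with the trait,
#' with each column centered on its mean. Breed and sex remain in the
#' model even though the trait is already a breed-sex deviation, to
#' absorb population stratification in the genotypes.
#'
#' @param traits trait table from [pairwise_traits()] (or any data frame
#'   with `animal_id` and the trait column).
#' @param trait_name one of [pairwise_trait_names()].
#' @param meta metadata with `animal_id`, `sex`, `sire_breed`,
#'   `farrowing_group`, `pen`.
#' @param G complete dosage matrix with animal row names.
#' @return object of class `gwas_design`: list with `y`, `X`, `Z`
#'   (centered), `animal_ids`, `marker_ids`, `allele_freq` (pre-centering
#'   allele frequencies), `trait_name`.
#' @export
build_design <- function(traits, trait_name, meta, G) {
  if (!trait_name %in% names(traits))
    stop_invalid("trait '", trait_name, "' not found in the trait table")
  y_all <- traits[[trait_name]]
  ids <- as.character(traits$animal_id)
  keep <- !is.na(y_all) & ids %in% rownames(G) & ids %in% meta$animal_id
  ids <- ids[keep]
  if (length(ids) < 2L)
    stop_invalid("fewer than 2 animals with trait, metadata and genotypes")
  y <- y_all[keep]
  mm <- meta[match(ids, meta$animal_id), , drop = FALSE]
  cg <- interaction(mm$farrowing_group, mm$pen, drop = TRUE)
  small <- table(cg)
  if (any(small < 2L))
    warning("contemporary group(s) with < 2 animals retained: ",
            paste(names(small)[small < 2L], collapse = ", "))
  fx <- data.frame(sex = factor(mm$sex), sire_breed = factor(mm$sire_breed),
                   cg = cg)
  fx <- fx[, vapply(fx, function(f) nlevels(droplevels(f)) > 1L, logical(1)),
           drop = FALSE]
  X <- if (ncol(fx) > 0L) {
    stats::model.matrix(~ ., data = droplevels(fx))
  } else {
    matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  Z <- G[ids, , drop = FALSE]
  p_allele <- colMeans(Z) / 2
  Z <- sweep(Z, 2, colMeans(Z))
  structure(
    list(y = as.numeric(y), X = X, Z = Z, animal_ids = ids,
         marker_ids = colnames(G), allele_freq = p_allele,
         trait_name = trait_name),
    class = "gwas_design"
  )
}

#' Construct a bare design from y, X, Z
#'
#' Convenience constructor for simulation studies where the design
#' matrices are already in hand. Z is centered on its column means.
#'
#' @param y trait vector.
#' @param Z animals x markers dosage (or covariate) matrix.
#' @param X fixed-effect incidence matrix; default intercept only.
#' @return a `gwas_design` object.
#' @export
new_design <- function(y, Z, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (nrow(Z) != n || nrow(X) != n)
    stop_invalid("rows of y, X, Z must align")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("M", seq_len(ncol(Z)))
  p_allele <- colMeans(Z) / 2
  Z <- sweep(Z, 2, colMeans(Z))
  structure(
    list(y = as.numeric(y), X = X, Z = Z,
         animal_ids = rownames(Z) %||% as.character(seq_len(n)),
         marker_ids = colnames(Z), allele_freq = p_allele,
         trait_name = "trait"),
    class = "gwas_design"
  )
}

#' Fit a Bayes-C or Bayes-Cpi whole-genome regression
#'
#' Gibbs sampler for y = X beta + Z u + e where each marker effect is
#' zero with probability pi and otherwise drawn from N(0, sigma^2_u)
#' with a single effect variance common to all included markers.
#' Variance components get scaled-inverse-chi-square full conditionals;
#' with `pi = "estimate"` (Bayes-Cpi) pi is sampled from its Beta full
#' conditional under a uniform prior, and the chain is extended in
#' 8000-iteration blocks until the split-half difference of the
#' posterior-mean pi drops below `pi_tol` (or `max_iter` is reached).
#'
#' The supplied genetic prior variance is interpreted on the genomic
#' scale and divided by the sum of 2 p (1 - p) over markers to obtain
#' the per-marker effect-variance scale; prior scales are set so the
#' prior mode equals the supplied value.
#'
#' @param design a `gwas_design` from [build_design()] or [new_design()].
#' @param pi `"estimate"` for Bayes-Cpi, or a fixed value in \[0, 1\]
#'   for Bayes-C.
#' @param n_iter,burnin,thin chain length, burn-in, thinning. Defaults:
#'   41000 / 1000 / 40 for fixed pi (1000 saved states); 8100 / 100 / 1
#'   when pi is estimated.
#' @param prior_pi initial pi for Bayes-Cpi (default 0.98).
#' @param prior_var_genetic,prior_var_residual prior genetic (genomic
#'   scale) and residual variances; defaults 0.10 each.
#' @param df_genetic,df_residual prior degrees of freedom (default 4).
#' @param fix_variances hold the variance components at their supplied
#'   values instead of sampling them (the infinite-df limit); used for
#'   the ridge-regression equivalence check.
#' @param var_u,var_e per-marker effect and residual variances when
#'   `fix_variances = TRUE`.
#' @param pi_tol,max_iter Bayes-Cpi convergence tolerance on the
#'   split-half difference of mean pi, and the chain-length cap.
#' @param seed integer seed; the sampler uses R's RNG stream.
#' @return an object of class `bayesc`; see Details.
#' @details The returned object contains `samples` (a data frame with
#'   one row per saved state: iteration, sigma^2_u, sigma^2_e, pi,
#'   genomic variance of Zu across animals, h^2), `effects` (saved
#'   marker-effect states, states x markers), `beta` (fixed-effect
#'   states), `pi_trace` (per-iteration pi for convergence plots),
#'   `inclusion` (posterior inclusion frequency per marker) and the
#'   design. Methods: [print.bayesc()], [summary.bayesc()],
#'   [coef.bayesc()], [predict.bayesc()], [plot.bayesc()],
#'   [residuals.bayesc()].
#' @export
bayesc <- function(design, pi = "estimate",
                   n_iter = NULL, burnin = NULL, thin = NULL,
                   prior_pi = 0.98,
                   prior_var_genetic = 0.10, prior_var_residual = 0.10,
                   df_genetic = 4, df_residual = 4,
                   fix_variances = FALSE, var_u = NULL, var_e = NULL,
                   pi_tol = 1e-4, max_iter = 56100, seed = NULL) {
  if (!inherits(design, "gwas_design"))
    stop_invalid("design must be a gwas_design (see build_design, new_design)")
  estimate_pi <- identical(pi, "estimate")
  if (!estimate_pi) {
    pi <- as.numeric(pi)
    if (is.na(pi) || pi < 0 || pi > 1)
      stop_invalid("pi must be 'estimate' or a value in [0, 1]")
  }
  n_iter <- n_iter %||% (if (estimate_pi) 8100L else 41000L)
  burnin <- burnin %||% (if (estimate_pi) 100L else 1000L)
  thin <- thin %||% (if (estimate_pi) 1L else 40L)
  if (burnin >= n_iter) stop_invalid("burnin must be smaller than n_iter")
  if (thin < 1L) stop_invalid("thin must be >= 1")

  y <- design$y; X <- design$X; Z <- design$Z
  sum2pq <- sum(2 * design$allele_freq * (1 - design$allele_freq))
  if (sum2pq <= 0) sum2pq <- ncol(Z)  # degenerate all-monomorphic fallback
  pi0 <- if (estimate_pi) prior_pi else pi
  m <- ncol(Z)
  # GenSel-style per-marker prior variance: the genomic-scale prior is
  # spread over the (1 - pi) m markers expected to carry effects.
  frac_in <- max(1 - pi0, 1 / m)
  marker_prior_var <- prior_var_genetic / (frac_in * sum2pq)

  if (fix_variances) {
    if (is.null(var_u) || is.null(var_e))
      stop_invalid("fix_variances = TRUE requires var_u and var_e")
    var_u0 <- var_u; var_e0 <- var_e
    scale_u <- scale_e <- 1  # unused
  } else {
    var_u0 <- marker_prior_var
    var_e0 <- prior_var_residual
    # prior mode of scaled-inv-chisq(nu, S) is nu S / (nu + 2); in
    # Bayes-Cpi the (1 - pi) factor is reapplied inside the sampler as
    # pi moves, so the base scale excludes it there.
    scale_u <- if (estimate_pi) {
      prior_var_genetic * (df_genetic + 2) / df_genetic / sum2pq
    } else {
      marker_prior_var * (df_genetic + 2) / df_genetic
    }
    scale_e <- prior_var_residual * (df_residual + 2) / df_residual
  }

  run <- function() {
    res <- .bayesc_gibbs(y, X, Z, as.integer(n_iter), as.integer(burnin),
                         as.integer(thin), pi0, estimate_pi,
                         var_u0, var_e0, df_genetic, scale_u,
                         df_residual, scale_e, fix_variances, estimate_pi)
    if (estimate_pi) {
      total <- n_iter
      d <- Inf
      repeat {
        pis <- res$pi[res$iter > burnin]
        half <- length(pis) %/% 2
        if (half >= 1) {
          d <- abs(mean(pis[seq_len(half)]) -
                   mean(pis[seq.int(length(pis) - half + 1, length(pis))]))
          if (d < pi_tol) break
        }
        if (total + 8000 > max_iter) {
          warning("Bayes-Cpi pi trace not converged after ", total,
                  " iterations (split-half difference ",
                  format(d, digits = 3), ")")
          break
        }
        ext <- .bayesc_gibbs(y, X, Z, 8000L, 0L, as.integer(thin),
                             pi0, estimate_pi, var_u0, var_e0,
                             df_genetic, scale_u, df_residual, scale_e,
                             fix_variances, estimate_pi, res$state,
                             as.integer(total))
        total <- total + 8000
        res <- list(U = rbind(res$U, ext$U), B = rbind(res$B, ext$B),
                    var_u = c(res$var_u, ext$var_u),
                    var_e = c(res$var_e, ext$var_e),
                    pi = c(res$pi, ext$pi),
                    var_g = c(res$var_g, ext$var_g),
                    h2 = c(res$h2, ext$h2),
                    iter = c(res$iter, ext$iter),
                    pi_trace = c(res$pi_trace, ext$pi_trace),
                    n_included_trace = c(res$n_included_trace,
                                         ext$n_included_trace),
                    state = ext$state)
      }
      res$n_iter_total <- total
    } else {
      res$n_iter_total <- n_iter
    }
    res
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())

  samples <- data.frame(iter = res$iter, var_u = res$var_u,
                        var_e = res$var_e, pi = res$pi,
                        var_g = res$var_g, h2 = res$h2)
  effects <- res$U
  colnames(effects) <- design$marker_ids
  beta <- res$B
  colnames(beta) <- colnames(X)
  structure(
    list(samples = samples, effects = effects, beta = beta,
         pi_trace = res$pi_trace,
         n_included_trace = res$n_included_trace,
         inclusion = colMeans(effects != 0),
         design = design,
         config = list(mode = if (estimate_pi) "BayesCpi" else "BayesC",
                       pi = if (estimate_pi) "estimate" else pi,
                       n_iter = res$n_iter_total, burnin = burnin,
                       thin = thin, prior_pi = prior_pi,
                       prior_var_genetic = prior_var_genetic,
                       prior_var_residual = prior_var_residual,
                       df_genetic = df_genetic, df_residual = df_residual,
                       fix_variances = fix_variances, seed = seed),
         call = match.call()),
    class = "bayesc"
  )
}

#' Posterior summary of heritability
#'
#' Posterior mean of per-sample h^2 = var_g / (var_g + sigma^2_e) over
#' all saved post-burn-in states, with the reported uncertainty computed
#' as the sample standard deviation of the final 100 saved states.
#'
#' @param object a `bayesc` fit, or a numeric vector of saved h^2 states.
#' @return list with `mean` and `sd_last100`.
#' @export
summarize_heritability <- function(object) {
  h2 <- if (inherits(object, "bayesc")) object$samples$h2 else as.numeric(object)
  if (length(h2) < 100L)
    stop_invalid("at least 100 saved samples are required (got ",
                 length(h2), ")")
  list(mean = mean(h2),
       sd_last100 = stats::sd(h2[seq.int(length(h2) - 99L, length(h2))]))
}

#' @export
print.bayesc <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s whole-genome regression: trait '%s'\n",
              cfg$mode, x$design$trait_name))
  cat(sprintf("  %d animals, %d markers, %d fixed-effect columns\n",
              length(x$design$y), ncol(x$effects), ncol(x$beta)))
  cat(sprintf("  chain: %d iterations (burn-in %d, thin %d), %d saved states\n",
              cfg$n_iter, cfg$burnin, cfg$thin, nrow(x$samples)))
  if (nrow(x$samples) >= 100L) {
    h <- summarize_heritability(x)
    cat(sprintf("  posterior mean h2: %.3f (SD of last 100 samples %.3f)\n",
                h$mean, h$sd_last100))
  } else {
    cat(sprintf("  posterior mean h2: %.3f\n", mean(x$samples$h2)))
  }
  cat(sprintf("  posterior mean pi: %.6f\n", mean(x$samples$pi)))
  invisible(x)
}

#' Summary of a Bayes-C fit
#'
#' @param object a `bayesc` fit.
#' @param n_top number of markers to list by posterior inclusion
#'   frequency.
#' @param ... unused.
#' @return a `summary.bayesc` list: posterior means of the variance
#'   components, genomic variance and pi, the heritability summary, and
#'   the top markers.
#' @export
summary.bayesc <- function(object, n_top = 10L, ...) {
  s <- object$samples
  h <- if (nrow(s) >= 100L) summarize_heritability(object) else
    list(mean = mean(s$h2), sd_last100 = NA_real_)
  ord <- order(object$inclusion, decreasing = TRUE)
  top <- data.frame(marker_id = colnames(object$effects)[ord],
                    inclusion = object$inclusion[ord],
                    mean_effect = colMeans(object$effects)[ord],
                    row.names = NULL)[seq_len(min(n_top, ncol(object$effects))), ]
  out <- list(mode = object$config$mode, trait = object$design$trait_name,
              n = length(object$design$y), m = ncol(object$effects),
              n_saved = nrow(s),
              var_u = mean(s$var_u), var_e = mean(s$var_e),
              var_g = mean(s$var_g), pi = mean(s$pi),
              h2 = h, top_markers = top)
  class(out) <- "summary.bayesc"
  out
}

#' @export
print.summary.bayesc <- function(x, ...) {
  cat(sprintf("%s fit of '%s' (n = %d, m = %d, %d saved states)\n",
              x$mode, x$trait, x$n, x$m, x$n_saved))
  cat(sprintf("  genomic variance: %.4f   residual variance: %.4f\n",
              x$var_g, x$var_e))
  cat(sprintf("  h2: %.3f (SD last 100: %.3f)   pi: %.6f\n",
              x$h2$mean, x$h2$sd_last100, x$pi))
  cat("  markers by posterior inclusion frequency:\n")
  print(format(x$top_markers, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.bayesc <- function(object, ...) {
  stats::setNames(colMeans(object$effects), colnames(object$effects))
}

#' Predict genomic values from a Bayes-C fit
#'
#' @param object a `bayesc` fit.
#' @param newZ optional dosage matrix for new animals (same markers, raw
#'   0/1/2 dosages); centered with the training-column means. If omitted,
#'   fitted values X beta + Z u for the training animals are returned.
#' @param ... unused.
#' @return numeric vector of predicted values.
#' @export
predict.bayesc <- function(object, newZ = NULL, ...) {
  u <- coef(object)
  b <- colMeans(object$beta)
  if (is.null(newZ)) {
    as.numeric(object$design$X %*% b + object$design$Z %*% u)
  } else {
    center <- 2 * object$design$allele_freq
    Zc <- sweep(newZ[, names(u), drop = FALSE], 2, center)
    as.numeric(Zc %*% u + mean(object$design$X %*% b))
  }
}

#' @export
residuals.bayesc <- function(object, ...) {
  object$design$y - predict(object)
}

#' Trace plots for a Bayes-C fit
#'
#' Plots the per-iteration pi trace (used to judge Bayes-Cpi
#' convergence) and the saved h^2 states.
#'
#' @param x a `bayesc` fit.
#' @param which any of `"pi"`, `"h2"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bayesc <- function(x, which = c("pi", "h2"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1))
  on.exit(graphics::par(op))
  if ("pi" %in% which)
    graphics::plot(x$pi_trace, type = "l", xlab = "iteration",
                   ylab = expression(pi), ...)
  if ("h2" %in% which)
    graphics::plot(x$samples$iter, x$samples$h2, type = "l",
                   xlab = "iteration", ylab = expression(h^2), ...)
  invisible(x)
}
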