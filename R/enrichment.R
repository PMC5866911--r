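# Gene-ontology over/under-representation for genes in high-variance
# 1-Mb windows: window-gene overlap via GenomicRanges, then a two-sided
# binomial test (minimum-likelihood method) with Bonferroni correction
# within each ontology aspect.

#' Genes overlapping a set of 1-Mb windows
#'
#' A gene is included when its 1-based inclusive \[start, end\] interval
#' overlaps the window interval \[k Mb, (k+1) Mb) by at least 1 bp;
#' genes hit by several windows appear once.
#'
#' @param windows window table with `chromosome` and `window_mb`
#'   (typically [window_variance()] output filtered on `reported` or
#'   `top`).
#' @param genes gene coordinates: a data frame with `gene_id`,
#'   `chromosome`, `start_bp`, `end_bp` (1-based inclusive), or a
#'   `GRanges` with a `gene_id` metadata column.
#' @param window_bp window width (default 1 Mb).
#' @return character vector of unique gene ids, in genomic order.
#' @export
genes_in_windows <- function(windows, genes, window_bp = 1e6) {
  if (nrow(windows) == 0L) return(character())
  gr <- as_gene_granges(genes)
  miss <- setdiff(unique(as.character(windows$chromosome)),
                  as.character(GenomicRanges::seqnames(gr)))
  if (length(miss) > 0L)
    warning("window chromosome(s) absent from the gene annotation: ",
            paste(miss, collapse = ", "))
  wr <- GenomicRanges::GRanges(
    seqnames = as.character(windows$chromosome),
    ranges = IRanges::IRanges(
      start = pmax(1, windows$window_mb * window_bp),
      end = (windows$window_mb + 1) * window_bp - 1
    )
  )
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(gr, wr, minoverlap = 1L)
  )
  unique(gr$gene_id[sort(unique(S4Vectors::queryHits(hits)))])
}

as_gene_granges <- function(genes) {
  if (methods::is(genes, "GRanges")) {
    if (is.null(genes$gene_id))
      stop_invalid("GRanges gene annotation needs a gene_id column")
    return(genes)
  }
  need <- c("gene_id", "chromosome", "start_bp", "end_bp")
  if (!all(need %in% names(genes)))
    stop_invalid("gene table needs columns: ", paste(need, collapse = ", "))
  if (any(genes$start_bp > genes$end_bp))
    stop_invalid("gene intervals must satisfy start_bp <= end_bp")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chromosome),
    ranges = IRanges::IRanges(start = genes$start_bp, end = genes$end_bp)
  )
  gr$gene_id <- as.character(genes$gene_id)
  gr
}

#' Two-sided binomial over/under-representation test
#'
#' For each ontology term annotated to at least one background gene, the
#' number k of list genes carrying the term is compared with the
#' expectation n K / N (list size n, K background genes with the term,
#' background size N). The two-sided p-value sums the probabilities of
#' all outcomes no more likely than the observed k under
#' Binomial(n, K/N) (minimum-likelihood method). Bonferroni correction
#' multiplies by the number of terms tested within the same ontology
#' aspect.
#'
#' @param gene_list character vector of gene ids (must be contained in
#'   the background).
#' @param annotation data frame `gene_id`, `term_id`, and optionally
#'   `aspect` (defaults to `"unspecified"`) and `term_name`.
#' @param background character vector of background gene ids; default:
#'   all genes with at least one annotation.
#' @param alpha significance level on the Bonferroni-corrected p-value.
#' @return data frame with one row per term: `term_id`, `aspect`, `K`,
#'   `k`, `n`, `N`, `expected`, `direction` (+/-), `p_raw`,
#'   `p_bonferroni`, `significant`; sorted by aspect then p-value.
#' @export
binomial_enrichment <- function(gene_list, annotation, background = NULL,
                                alpha = 0.05) {
  if (!all(c("gene_id", "term_id") %in% names(annotation)))
    stop_invalid("annotation needs columns gene_id, term_id")
  ann <- data.frame(gene_id = as.character(annotation$gene_id),
                    term_id = as.character(annotation$term_id),
                    aspect = if ("aspect" %in% names(annotation))
                      as.character(annotation$aspect) else "unspecified",
                    stringsAsFactors = FALSE)
  background <- background %||% sort(unique(ann$gene_id))
  background <- unique(as.character(background))
  gene_list <- unique(as.character(gene_list))
  if (length(gene_list) == 0L) {
    return(data.frame(term_id = character(), aspect = character(),
                      K = integer(), k = integer(), n = integer(),
                      N = integer(), expected = numeric(),
                      direction = character(), p_raw = numeric(),
                      p_bonferroni = numeric(), significant = logical()))
  }
  if (!all(gene_list %in% background))
    stop_invalid("gene_list contains ids outside the background: ",
                 paste(utils::head(setdiff(gene_list, background), 5),
                       collapse = ", "))
  ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann)
  N <- length(background)
  n <- length(gene_list)
  terms <- unique(ann[, c("term_id", "aspect")])
  K_tab <- table(paste(ann$term_id, ann$aspect, sep = "\r"))
  in_list <- ann$gene_id %in% gene_list
  k_tab <- table(paste(ann$term_id[in_list], ann$aspect[in_list], sep = "\r"))
  key <- paste(terms$term_id, terms$aspect, sep = "\r")
  K <- as.integer(K_tab[key])
  k <- as.integer(k_tab[key]); k[is.na(k)] <- 0L
  expected <- n * K / N
  p_raw <- vapply(seq_along(K), function(i) {
    binom_minlik_p(k[i], n, K[i] / N)
  }, numeric(1))
  n_tested <- table(terms$aspect)
  mult <- as.integer(n_tested[terms$aspect])
  out <- data.frame(
    term_id = terms$term_id, aspect = terms$aspect,
    K = K, k = k, n = n, N = N, expected = expected,
    direction = ifelse(k > expected, "+", "-"),
    p_raw = p_raw,
    p_bonferroni = pmin(1, p_raw * mult),
    stringsAsFactors = FALSE
  )
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$aspect, out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Two-sided binomial p-value by the minimum-likelihood method: the sum
# of P(X = j) over all j whose probability does not exceed that of the
# observed count (with a small relative tolerance for ties).
binom_minlik_p <- function(k, n, prob) {
  probs <- stats::dbinom(0:n, n, prob)
  p_obs <- probs[k + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Read gene coordinates from BED or GFF3
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates; GFF3 input is filtered to `type == feature` and the gene
#' id taken from the `ID` (or `gene_id`) attribute. Parsing is done with
#' rtracklayer.
#'
#' @param path file path (`.bed`, `.gff`, `.gff3`).
#' @param feature GFF3 feature type to keep (default `"gene"`).
#' @return data frame `gene_id`, `chromosome`, `start_bp`, `end_bp`.
#' @export
read_genes <- function(path, feature = "gene") {
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  gr <- rtracklayer::import(path)
  if (!is_bed) {
    if (!is.null(gr$type)) gr <- gr[as.character(gr$type) == feature]
    ids <- gr$ID %||% gr$gene_id %||% gr$Name
  } else {
    ids <- gr$name
  }
  if (is.null(ids)) stop_invalid("could not find gene identifiers in ", path)
  data.frame(gene_id = as.character(ids),
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a gene-to-term annotation table
#'
#' Two- or three-column TSV: `gene_id`, `term_id`, optional `aspect`.
#'
#' @param path TSV path.
#' @export
read_term_map <- function(path) {
  a <- read_tsv(path)
  if (ncol(a) < 2L) stop_invalid("annotation needs at least 2 columns")
  names(a)[1:2] <- c("gene_id", "term_id")
  if (ncol(a) >= 3L && !"aspect" %in% names(a)) names(a)[3] <- "aspect"
  a
}

#' Write an enrichment table
#'
#' @param enrichment output of [binomial_enrichment()].
#' @param path destination TSV.
#' @export
write_enrichment <- function(enrichment, path) {
  write_tsv(enrichment, path)
}
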