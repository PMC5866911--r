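test_that("genes_in_windows applies the any-overlap rule and set semantics", {
  genes <- data.frame(
    gene_id = c("g_span", "g_inside", "g_before", "g_otherchr", "g_twice"),
    chromosome = c("1", "1", "1", "2", "1"),
    start_bp = c(9e5, 1.2e6, 1e4, 1.5e6, 1.9e6),
    end_bp = c(1.1e6, 1.3e6, 5e4, 1.6e6, 3.1e6))
  win <- data.frame(chromosome = c("1", "1"), window_mb = c(1L, 2L))
  hits <- genes_in_windows(win, genes)
  # g_span overlaps window 1 by 1e5 bp; g_twice spans windows 1 (no),
  # 2 and 3 but appears once
  expect_setequal(hits, c("g_span", "g_inside", "g_twice"))
  expect_equal(anyDuplicated(hits), 0L)
  expect_equal(genes_in_windows(win[0, ], genes), character())
  expect_warning(
    genes_in_windows(data.frame(chromosome = "9", window_mb = 1L), genes),
    "absent")
})

test_that("expected counts reproduce the worked STAT-phosphorylation example", {
  # background of 21,324 annotated genes, list of 254, 36 carrying the
  # term: expectation 0.43 genes
  N <- 21324L; n_list <- 254L; K <- 36L
  ann <- data.frame(
    gene_id = sprintf("g%05d", 1:N),
    term_id = c(rep("GO:STATPHOS", K), rep("GO:OTHER", N - K)))
  gene_list <- sprintf("g%05d", c(1:10, seq(K + 1, K + n_list - 10)))
  enr <- binomial_enrichment(gene_list, ann)
  row <- enr[enr$term_id == "GO:STATPHOS", ]
  expect_equal(round(row$expected, 2), 0.43)
  expect_equal(row$k, 10L)
  expect_equal(row$direction, "+")
  expect_lt(row$p_raw, 1e-6)
})

test_that("binomial p-values match exact enumeration on small lists", {
  oracle <- function(k, n, p) {
    probs <- sapply(0:n, function(j)
      choose(n, j) * p^j * (1 - p)^(n - j))
    sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
  }
  for (n in c(5, 10, 12)) {
    for (k in 0:n) {
      for (p in c(0.1, 0.37, 0.5)) {
        expect_equal(heatfeed:::binom_minlik_p(k, n, p), oracle(k, n, p),
                     tolerance = 1e-12)
      }
    }
  }
  # the documented N=100, n=10, K=10 instance
  expect_equal(heatfeed:::binom_minlik_p(5, 10, 0.1), oracle(5, 10, 0.1),
               tolerance = 1e-12)
})

test_that("Bonferroni is per aspect, never below raw, and direction flips", {
  ann <- data.frame(
    gene_id = c(sprintf("g%02d", 1:20), sprintf("g%02d", 1:20)),
    term_id = c(rep("T1", 20), rep(c("T2", "T3"), each = 10)),
    aspect = c(rep("biological_process", 20),
               rep("molecular_function", 20)))
  gl <- sprintf("g%02d", 1:5)
  enr <- binomial_enrichment(gl, ann)
  expect_true(all(enr$p_bonferroni >= enr$p_raw))
  # one BP term, two MF terms -> multipliers 1 and 2
  expect_equal(enr$p_bonferroni[enr$term_id == "T1"],
               enr$p_raw[enr$term_id == "T1"])
  expect_equal(enr$p_bonferroni[enr$term_id == "T2"],
               pmin(1, 2 * enr$p_raw[enr$term_id == "T2"]))

  # single-term fixture: swapping the list for its complement flips the
  # over/under direction
  ann1 <- data.frame(gene_id = sprintf("g%02d", 1:30),
                     term_id = c(rep("T", 10), rep("U", 20)))
  lst <- sprintf("g%02d", 1:8)         # term-rich list
  comp <- setdiff(sprintf("g%02d", 1:30), lst)
  e1 <- binomial_enrichment(lst, ann1)
  e2 <- binomial_enrichment(comp, ann1)
  expect_equal(e1$direction[e1$term_id == "T"], "+")
  expect_equal(e2$direction[e2$term_id == "T"], "-")

  # empty list -> empty result
  expect_equal(nrow(binomial_enrichment(character(), ann1)), 0L)
  # list outside background errors
  expect_error(binomial_enrichment("nope", ann1), "background")
})

test_that("expected counts are additive over terms", {
  set.seed(71)
  genes <- sprintf("g%03d", 1:200)
  ann <- data.frame(
    gene_id = sample(genes, 600, replace = TRUE),
    term_id = sample(paste0("T", 1:25), 600, replace = TRUE))
  ann <- unique(ann)
  gl <- sample(unique(ann$gene_id), 40)
  enr <- binomial_enrichment(gl, ann)
  n <- length(unique(gl))
  mean_terms_per_gene <- nrow(ann) / length(unique(ann$gene_id))
  expect_equal(sum(enr$expected), n * mean_terms_per_gene,
               tolerance = 1e-12)
})

test_that("gene coordinates read from BED and GFF3 agree", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  # BED is 0-based half-open: [900000, 1100000) -> 1-based 900001..1100000
  writeLines(c("1\t900000\t1100000\tgeneA\t0\t+",
               "2\t5000\t6000\tgeneB\t0\t-"), bed)
  gb <- read_genes(bed)
  expect_equal(gb$start_bp, c(900001, 5001))
  expect_equal(gb$end_bp, c(1100000, 6000))
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t900001\t1100000\t.\t+\t.\tID=geneA",
               "2\tsrc\tgene\t5001\t6000\t.\t-\t.\tID=geneB",
               "2\tsrc\texon\t5001\t5100\t.\t-\t.\tID=exon1"), gff)
  gg <- read_genes(gff)
  expect_equal(nrow(gg), 2L)
  expect_equal(gg[c("gene_id", "chromosome", "start_bp", "end_bp")],
               gb[c("gene_id", "chromosome", "start_bp", "end_bp")])
})
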