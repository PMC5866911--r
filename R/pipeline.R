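# End-to-end orchestration: simulate/ingest -> classify -> phenotypes ->
# genotype QC -> Bayes-Cpi then Bayes-C per trait -> windows ->
# enrichment, with a JSON manifest of seeds, counts and checksums.

#' Default pipeline configuration
#'
#' @param out output directory.
#' @param seed master seed.
#' @param thi_thresholds the three category cut points (deg C).
#' @param maf_threshold MAF removal threshold.
#' @param window_reported_pct,window_top_pct window flag thresholds.
#' @param cpi,cc chain settings (lists with `n_iter`, `burnin`, `thin`)
#'   for the Bayes-Cpi prior run and the Bayes-C analysis run.
#' @param simulate NULL to read inputs from `paths`, or a list of
#'   [sim_config()] overrides used to generate the inputs.
#' @param paths named list of input files (`weather` or `days`, `pings`,
#'   `meta`, `geno`, `map`, optionally `genes`, `terms`).
#' @param traits trait names to analyse; default all six.
#' @param min_hours minimum hourly records per retained day.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out = "heatfeed_run", seed = 1,
                            thi_thresholds = c(Alert = 23.33,
                                               Danger = 26.11,
                                               Emergency = 28.88),
                            maf_threshold = 0.05,
                            window_reported_pct = 1.0, window_top_pct = 3.0,
                            cpi = list(n_iter = 8100, burnin = 100, thin = 1),
                            cc = list(n_iter = 41000, burnin = 1000,
                                      thin = 40),
                            simulate = list(), paths = list(),
                            traits = pairwise_trait_names(),
                            min_hours = 18) {
  cfg <- list(out = out, seed = as.integer(seed),
              thi_thresholds = thi_thresholds,
              maf_threshold = maf_threshold,
              window_reported_pct = window_reported_pct,
              window_top_pct = window_top_pct,
              cpi = cpi, cc = cc, simulate = simulate, paths = paths,
              traits = traits, min_hours = min_hours)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (any(diff(cfg$thi_thresholds) <= 0))
    stop_invalid("THI thresholds must be strictly increasing")
  if (cfg$window_reported_pct >= cfg$window_top_pct)
    stop_invalid("window thresholds must be increasing (reported < top)")
  if (cfg$maf_threshold < 0 || cfg$maf_threshold > 0.5)
    stop_invalid("maf_threshold must lie in [0, 0.5]")
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) stop_invalid("input path does not exist: ", p)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes: simulate (or read inputs) -> day classification ->
#' pairwise-THI traits -> genotype QC -> per-trait Bayes-Cpi (to obtain
#' pi) then Bayes-C -> 1-Mb window decomposition -> optional GO
#' enrichment. Every stage writes TSV outputs under `cfg$out` and is
#' logged in a JSON manifest with record counts and md5 checksums. A
#' stage is skipped when the manifest shows its outputs already exist
#' with unchanged inputs (disable with `force = TRUE`).
#'
#' @param cfg a [pipeline_config()] (or YAML path).
#' @param force rerun all stages even when outputs are up to date.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config(), force = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  validate_pipeline_config(cfg)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out, "manifest.json")
  old_manifest <- if (!force && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  manifest <- list(package = as.character(utils::packageVersion("heatfeed")),
                   seed = cfg$seed, started = format(Sys.time(), tz = "UTC"),
                   stages = list())

  path_of <- function(name) file.path(cfg$out, name)
  log_stage <- function(name, outputs, counts) {
    manifest$stages[[name]] <<- list(
      outputs = outputs,
      md5 = as.list(tools::md5sum(outputs)),
      counts = counts)
    message("[", name, "] ",
            paste(names(counts), unlist(counts), sep = "=", collapse = " "))
  }
  # Skip the run when a previous manifest with the same seed is present
  # and every recorded output still exists with an unchanged checksum.
  if (!is.null(old_manifest) &&
      isTRUE(as.numeric(old_manifest$seed) == as.numeric(cfg$seed))) {
    outs <- unlist(lapply(old_manifest$stages, `[[`, "outputs"))
    md5s <- unlist(lapply(old_manifest$stages, `[[`, "md5"))
    if (length(outs) > 0 && all(file.exists(outs)) &&
        identical(unname(md5s), unname(tools::md5sum(outs)))) {
      message("run_pipeline: outputs up to date, skipping (force = TRUE to rerun)")
      return(invisible(old_manifest))
    }
  }

  # --- stage: inputs (simulate or ingest) ---
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    scfg <- do.call(sim_config, sim_args)
    sim_dir <- path_of("sim")
    sim <- simulate_study(scfg, use_weather = TRUE)
    write_sim(sim, sim_dir)
    weather <- sim$weather
    pings <- sim$pings
    meta <- sim$meta
    G_raw <- sim$G
    map_raw <- sim$map
    log_stage("simulate",
              file.path(sim_dir, c("pings.tsv", "meta.tsv", "genotypes.tsv",
                                   "map.tsv", "weather.tsv")),
              list(animals = nrow(meta), markers = ncol(G_raw),
                   ping_records = nrow(pings)))
  } else {
    p <- cfg$paths
    weather <- if (!is.null(p$weather)) read_weather(p$weather)
    pings <- read_pings(p$pings)
    meta <- read_meta(p$meta)
    G_raw <- read_dosage(p$geno)
    map_raw <- read_marker_map(p$map)
  }

  # --- stage: classify ---
  days <- if (!is.null(weather)) {
    classify_days(weather, min_hours = cfg$min_hours,
                  thresholds = cfg$thi_thresholds)
  } else {
    read_day_classes(cfg$paths$days)
  }
  write_day_classes(days, path_of("days.tsv"))
  log_stage("classify", path_of("days.tsv"),
            list(days = nrow(days),
                 categories = length(unique(days$category))))

  # --- stage: phenotypes ---
  prof <- category_profile(daily_counts(pings), days)
  z <- standardize_deviations(prof, meta)
  traits <- pairwise_traits(z)
  write_traits(traits, path_of("traits.tsv"))
  cors <- trait_correlations(traits)
  write_tsv(data.frame(trait = rownames(cors), cors, check.names = FALSE),
            path_of("trait_correlations.tsv"))
  log_stage("phenotypes", path_of(c("traits.tsv", "trait_correlations.tsv")),
            list(animals_in = length(unique(pings$animal_id)),
                 animals_with_traits = nrow(traits)))

  # --- stage: qc ---
  qc <- qc_genotypes(G_raw, map_raw, cfg$maf_threshold)
  write_dosage(qc$G, path_of("genotypes_qc.tsv"))
  write_tsv(qc$map, path_of("map_qc.tsv"))
  write_tsv(qc$report, path_of("qc_report.tsv"))
  log_stage("qc", path_of(c("genotypes_qc.tsv", "map_qc.tsv",
                            "qc_report.tsv")),
            list(markers_in = ncol(G_raw), markers_kept = ncol(qc$G)))

  # --- stage: gwas + windows per trait ---
  gwas_counts <- list()
  all_windows <- list()
  for (tr in cfg$traits) {
    if (!tr %in% names(traits)) next
    n_avail <- sum(!is.na(traits[[tr]]) & traits$animal_id %in% rownames(qc$G))
    if (n_avail < 10L) {
      message("[gwas] skipping trait ", tr, ": only ", n_avail,
              " animals with data")
      next
    }
    design <- build_design(traits, tr, meta, qc$G)
    fit_pi <- bayesc(design, pi = "estimate",
                     n_iter = cfg$cpi$n_iter, burnin = cfg$cpi$burnin,
                     thin = cfg$cpi$thin, seed = cfg$seed + 100L)
    pi_hat <- mean(fit_pi$samples$pi)
    fit <- bayesc(design, pi = pi_hat,
                  n_iter = cfg$cc$n_iter, burnin = cfg$cc$burnin,
                  thin = cfg$cc$thin, seed = cfg$seed + 200L)
    safe <- gsub("[^A-Za-z0-9]", "_", tr)
    write_tsv(fit$samples, path_of(paste0("samples_", safe, ".tsv")))
    write_tsv(data.frame(iteration = seq_along(fit_pi$pi_trace),
                         pi = fit_pi$pi_trace),
              path_of(paste0("pi_trace_", safe, ".tsv")))
    write_tsv(data.frame(marker_id = colnames(fit$effects),
                         inclusion = fit$inclusion,
                         mean_effect = colMeans(fit$effects)),
              path_of(paste0("markers_", safe, ".tsv")))
    win <- window_variance(fit, qc$map,
                           reported_pct = cfg$window_reported_pct,
                           top_pct = cfg$window_top_pct)
    write_windows(win, path_of(paste0("windows_", safe, ".tsv")))
    all_windows[[tr]] <- win
    h <- summarize_heritability(fit)
    gwas_counts[[tr]] <- list(n = length(design$y),
                              pi = round(pi_hat, 6),
                              h2 = round(h$mean, 4))
  }
  log_stage("gwas",
            path_of(paste0("samples_",
                           gsub("[^A-Za-z0-9]", "_", names(gwas_counts)),
                           ".tsv")),
            list(traits = length(gwas_counts)))
  manifest$gwas <- gwas_counts

  # --- stage: enrichment (optional) ---
  if (!is.null(cfg$paths$genes) && !is.null(cfg$paths$terms)) {
    genes <- read_genes(cfg$paths$genes)
    terms <- read_term_map(cfg$paths$terms)
    reported <- do.call(rbind, lapply(all_windows, function(w)
      w[w$reported, c("chromosome", "window_mb"), drop = FALSE]))
    reported <- unique(reported)
    gl <- genes_in_windows(reported, genes)
    gl <- intersect(gl, unique(terms$gene_id))
    enr <- binomial_enrichment(gl, terms)
    write_enrichment(enr, path_of("enrichment.tsv"))
    log_stage("enrich", path_of("enrichment.tsv"),
              list(windows = nrow(reported), genes = length(gl),
                   significant_terms = sum(enr$significant)))
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
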