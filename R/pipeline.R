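#' Default run configuration
#'
#' All thresholds of the evaluation pipeline with their conventional
#' values: panel MAF floor 1%, tagging and high-imputation-quality
#' r-squared 0.8, low-quality cut-off 0.3, CADD 20, genome-wide
#' significance 5e-8, journal impact factor 5, call rate 0.975,
#' Hardy-Weinberg p 1e-7, genome-wide SNV count 19 million and a 1 Mb
#' tag-search window.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    maf_min = 0.01,
    r2_tag = 0.8,
    r2_impute_high = 0.8,
    r2_impute_low = 0.3,
    cadd_min = 20,
    p_max = 5e-8,
    if_min = 5,
    call_rate_min = 0.975,
    hwe_p_min = 1e-7,
    genome_snvs = 19e6,
    window_bp = 1e6,
    seed = 1L,
    sim = list()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown run_config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  stopifnot(
    cfg$maf_min >= 0, cfg$maf_min <= 0.5,
    cfg$r2_tag >= 0, cfg$r2_tag <= 1,
    cfg$r2_impute_high >= 0, cfg$r2_impute_high <= 1,
    cfg$p_max > 0, cfg$p_max <= 1,
    cfg$call_rate_min >= 0, cfg$call_rate_min <= 1
  )
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip through serialisation unchanged.
#'
#' @param path YAML file path.
#' @param cfg A `run_config`.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.write_report <- function(x, path, thresholds) {
  hdr <- sprintf("# %s", paste(sprintf("%s=%s", names(thresholds), thresholds),
                               collapse = " "))
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Run the full synthetic evaluation pipeline
#'
#' Simulates a panel, an array, an imputed callset, a synthetic exome
#' pair, star alleles and a catalog under one seed, runs every evaluation
#' stage, and writes one TSV per result into `out_dir`. Each output file
#' starts with a comment line naming the thresholds used. Intended both
#' as an end-to-end smoke harness and as the template for assembling the
#' same stages around real manifests and panels.
#'
#' @param cfg A [run_config()]; its `sim` element is passed to
#'   [sim_config()] (the `seed` is shared).
#' @param out_dir Output directory, created if absent.
#' @param stages Character vector of stages to run, any of `"manifest"`,
#'   `"coverage"`, `"imputation"`, `"concordance"`, `"catalog"`,
#'   `"star_alleles"`. Default all.
#' @return Invisibly, a named list of the stage results; the TSVs land in
#'   `out_dir`.
#' @export
run_all <- function(cfg = run_config(), out_dir = tempfile("arrayscope_run_"),
                    stages = c("manifest", "coverage", "imputation",
                               "concordance", "catalog", "star_alleles")) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg[c("maf_min", "r2_tag", "r2_impute_high", "r2_impute_low",
              "p_max", "if_min", "genome_snvs", "window_bp", "seed")]

  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  panel <- simulate_panel(scfg)
  manifest <- simulate_manifest(
    panel,
    tags_per_block = 1L,
    n_tag_blocks = max(1L, round(0.8 * scfg$n_blocks)),
    off_panel_snvs = 10L,
    seed = cfg$seed
  )
  results <- list(config = cfg)

  if ("manifest" %in% stages) {
    results$content <- summarize_content(manifest)
    .write_report(results$content, file.path(out_dir, "content_summary.tsv"), th)
  }
  if ("coverage" %in% stages) {
    results$coverage <- coverage_by_ancestry(
      manifest, panel,
      G = cfg$genome_snvs, r2_min = cfg$r2_tag,
      window_bp = cfg$window_bp, min_maf = cfg$maf_min
    )
    .write_report(as_tibble(results$coverage),
                  file.path(out_dir, "coverage.tsv"), th)
  }
  imputed <- simulate_imputed(panel, manifest, scfg)
  if ("imputation" %in% stages) {
    results$quality <- summarize_quality(imputed)
    .write_report(as_tibble(results$quality),
                  file.path(out_dir, "imputation_quality.tsv"), th)
  }
  if ("concordance" %in% stages) {
    pair <- simulate_wes_pair(imputed, e = scfg$wes_flip_rate,
                              seed = cfg$seed + 2L)
    results$concordance <- per_individual_concordance(pair$imputed, pair$wes)
    .write_report(tidy(results$concordance),
                  file.path(out_dir, "concordance.tsv"), th)
  }
  if ("catalog" %in% stages) {
    sim_cat <- simulate_catalog(n_records = 500L, seed = cfg$seed + 3L)
    filt <- filter_catalog(sim_cat$records, p_max = cfg$p_max,
                           if_min = cfg$if_min)
    results$catalog_filter <- filt
    results$catalog_coverage <- marker_coverage(
      filt$markers, manifest, imputed, r2_min = cfg$r2_impute_high
    )
    .write_report(filt$report, file.path(out_dir, "catalog_filter.tsv"), th)
    .write_report(as_tibble(results$catalog_coverage),
                  file.path(out_dir, "catalog_coverage.tsv"), th)
  }
  if ("star_alleles" %in% stages) {
    sim_star <- simulate_star_alleles(manifest, seed = cfg$seed + 4L)
    results$star_alleles <- percent_star_alleles(sim_star$alleles, manifest)
    .write_report(results$star_alleles,
                  file.path(out_dir, "star_alleles.tsv"), th)
  }
  results$out_dir <- out_dir
  invisible(results)
}
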