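#' Default non-disease trait keywords
#'
#' Used by [filter_catalog()] when a record has no `trait_class` column:
#' traits matching any of these keywords (case-insensitive) are classed
#' non-disease. The published association catalogs mix disease endpoints
#' with benign quantitative and appearance traits (hair colour, eye
#' colour, height, ...) that are not useful for clinical screening.
#'
#' @return Character vector of lower-case keywords.
#' @export
default_trait_blocklist <- function() {
  c(
    "hair color", "hair colour", "eye color", "eye colour", "skin pigment",
    "freckl", "tanning", "baldness", "height", "educational attainment",
    "handedness", "morning", "chronotype", "word reading", "intelligence"
  )
}

.catalog_cols <- c(
  "rsid", "trait", "p_value", "odds_ratio", "risk_allele_freq",
  "study_design", "trait_class", "journal_if_2019"
)

#' Filter a GWAS-catalog export for clinically usable markers
#'
#' Applies, in order: effect size (odds ratio) reported; risk allele
#' frequency reported; p-value at most `p_max` (inclusive); removal of
#' duplicate phenotype--locus associations (same `(trait, rsid)` pair,
#' keeping the record with the smallest p-value, ties broken by row order
#' after sorting on rsid); case-control study design; disease phenotype;
#' and journal impact factor strictly greater than `if_min`. The report
#' itemises per-step removals so the filter is auditable and reconciles
#' exactly with the input and output counts.
#'
#' @param records A data frame with columns `rsid, trait, p_value,
#'   odds_ratio, risk_allele_freq, study_design` (`"case_control"` or
#'   other), `journal_if_2019`, and either `trait_class` (`"disease"` /
#'   `"non_disease"`) or a free-text `trait` matched against
#'   `trait_blocklist`. Optional `chrom`/`pos` columns pass through.
#' @param p_max Genome-wide significance threshold, default 5e-8
#'   (inclusive).
#' @param if_min Minimum 2019 journal impact factor (exclusive),
#'   default 5.
#' @param trait_blocklist Keywords marking non-disease traits, used only
#'   when `trait_class` is absent; default [default_trait_blocklist()].
#' @return A list of class `catalog_filter`: `markers` (surviving
#'   records) and `report` (tibble `step, criterion, removed` plus
#'   attributes), with `input_count` and `output_count` reconciling.
#' @export
filter_catalog <- function(records, p_max = 5e-8, if_min = 5,
                           trait_blocklist = default_trait_blocklist()) {
  x <- as_tibble(records)
  need <- setdiff(.catalog_cols, c("trait_class", "odds_ratio",
                                   "risk_allele_freq", "journal_if_2019"))
  if (!all(need %in% names(x))) {
    abort(sprintf("catalog needs columns: %s", paste(need, collapse = ", ")))
  }
  for (col in c("odds_ratio", "risk_allele_freq", "journal_if_2019")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  if (!"trait_class" %in% names(x)) {
    pat <- paste(trait_blocklist, collapse = "|")
    x$trait_class <- ifelse(
      grepl(pat, tolower(x$trait)), "non_disease", "disease"
    )
  }
  if (nrow(x) > 0 && any(!is.na(x$p_value) & (x$p_value <= 0 | x$p_value > 1))) {
    abort("`p_value` must lie in (0, 1]")
  }

  input_count <- nrow(x)
  steps <- list(
    or_reported   = function(d) !is.na(d$odds_ratio),
    raf_reported  = function(d) !is.na(d$risk_allele_freq),
    p_significant = function(d) !is.na(d$p_value) & d$p_value <= p_max,
    deduplicated  = NULL,  # handled separately
    case_control  = function(d) d$study_design == "case_control",
    disease_trait = function(d) d$trait_class == "disease",
    impact_factor = function(d) !is.na(d$journal_if_2019) & d$journal_if_2019 > if_min
  )
  report <- tibble(step = integer(), criterion = character(), removed = integer())
  for (i in seq_along(steps)) {
    crit <- names(steps)[i]
    if (crit == "deduplicated") {
      before <- nrow(x)
      x <- x |>
        arrange(.data$trait, .data$rsid, .data$p_value) |>
        distinct(.data$trait, .data$rsid, .keep_all = TRUE)
      removed <- before - nrow(x)
    } else {
      keep <- steps[[i]](x)
      removed <- sum(!keep)
      x <- x[keep, ]
    }
    report <- bind_rows(report, tibble(step = i, criterion = crit,
                                       removed = as.integer(removed)))
  }
  stopifnot(input_count - sum(report$removed) == nrow(x))
  attr(report, "input_count") <- input_count
  attr(report, "output_count") <- nrow(x)
  structure(list(markers = x, report = report), class = "catalog_filter")
}

#' @export
print.catalog_filter <- function(x, ...) {
  cat(sprintf(
    "<catalog_filter> %d -> %d records\n",
    attr(x$report, "input_count"), attr(x$report, "output_count")
  ))
  print(x$report)
  invisible(x)
}

#' @export
tidy.catalog_filter <- function(x, ...) x$report

#' @export
glance.catalog_filter <- function(x, ...) {
  tibble(
    input_count = attr(x$report, "input_count"),
    removed = sum(x$report$removed),
    output_count = attr(x$report, "output_count")
  )
}

#' Append extra markers to a filtered marker list
#'
#' Adds hand-picked markers (for example the two causal APOE*4 coding
#' variants, which genome-wide scans only see through a nearby tag) to a
#' filtered catalog, skipping rsIDs already present.
#'
#' @param markers A data frame of markers with an `rsid` column.
#' @param extras A data frame with `rsid` and optionally `chrom, pos` and
#'   any other marker columns.
#' @return `markers` with the novel extras appended.
#' @export
append_extra_markers <- function(markers, extras) {
  markers <- as_tibble(markers)
  extras <- as_tibble(extras)
  if (!"rsid" %in% names(extras)) abort("`extras` needs an `rsid` column")
  novel <- extras[!extras$rsid %in% markers$rsid, ]
  bind_rows(markers, novel)
}

#' Array coverage of a marker list, directly and after imputation
#'
#' Classifies each marker as *genotyped* (its position is on the array),
#' *imputed at high quality* (off-array but present in the imputed
#' callset with imputation R-squared strictly above `r2_min`), or
#' uncovered. Markers whose position cannot be resolved (missing
#' `chrom`/`pos`) count as uncovered and are tallied in the result.
#'
#' @param markers Data frame with `rsid` and `chrom, pos` columns.
#' @param manifest An `array_manifest`.
#' @param imputed Data frame of imputed variants with `chrom, pos, r2`
#'   (may be `NULL` for array-only coverage).
#' @param r2_min High-imputation-quality threshold (strict), default 0.8.
#' @return A one-row tibble of class `marker_coverage`: `array,
#'   n_markers, n_genotyped, n_imputed_high, n_unresolved,
#'   fraction_genotyped, fraction_covered`.
#' @export
marker_coverage <- function(markers, manifest, imputed = NULL, r2_min = 0.8) {
  markers <- as_tibble(markers)
  if (!all(c("chrom", "pos") %in% names(markers))) {
    abort("`markers` needs `chrom` and `pos` columns")
  }
  n <- nrow(markers)
  resolved <- !is.na(markers$chrom) & !is.na(markers$pos)
  if (any(!resolved)) {
    inform(sprintf("%d marker(s) without resolvable position counted as uncovered",
                   sum(!resolved)))
  }
  mk <- paste(normalize_chrom(markers$chrom[resolved]), markers$pos[resolved])
  on_array <- mk %in% paste(manifest$chrom, manifest$pos)
  imp_high <- rep(FALSE, length(mk))
  if (!is.null(imputed) && nrow(as_tibble(imputed)) > 0) {
    imputed <- as_tibble(imputed)
    hi <- imputed[imputed$r2 > r2_min, ]
    imp_high <- !on_array & mk %in% paste(normalize_chrom(hi$chrom), hi$pos)
  }
  out <- tibble(
    array = array_name(manifest),
    n_markers = n,
    n_genotyped = sum(on_array),
    n_imputed_high = sum(imp_high),
    n_unresolved = sum(!resolved),
    fraction_genotyped = sum(on_array) / n,
    fraction_covered = (sum(on_array) + sum(imp_high)) / n
  )
  structure(out, class = c("marker_coverage", class(tibble())))
}

#' @export
tidy.marker_coverage <- function(x, ...) as_tibble(x)
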