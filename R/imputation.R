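#' Genotype tables
#'
#' Several functions in this package operate on *genotype tables*: tibbles
#' with the variant key columns `chrom, pos, ref, alt` followed by one
#' integer column per sample coding the diploid genotype as the
#' alternate-allele count (0 = hom-ref, 1 = het, 2 = hom-alt,
#' `NA` = missing). [genotype_cols()] returns the sample column names.
#'
#' @param x A genotype table.
#' @return Character vector of sample column names.
#' @export
genotype_cols <- function(x) {
  setdiff(names(x), c("chrom", "pos", "ref", "alt", "maf", "r2"))
}

.check_gt <- function(x, arg = "callset") {
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(x))) {
    abort(sprintf("`%s` must have chrom, pos, ref, alt key columns", arg))
  }
  if (length(genotype_cols(x)) == 0) {
    abort(sprintf("`%s` has no sample genotype columns", arg))
  }
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed minor-allele count,
#' the probability of each possible heterozygote count is computed under
#' random mating, and the p-value sums the probabilities of all
#' configurations no more probable than the observed one. Probabilities
#' are evaluated in log space for stability at large sample sizes.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative; total
#'   at least 1).
#' @return P-value in `(0, 1]`. A monomorphic site returns 1.
#' @examples
#' hwe_exact_p(25, 50, 25)
#' hwe_exact_p(50, 0, 50)   # no hets at 50/50 allele counts: p << 1e-7
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) abort("at least one genotype required")
  n_minor <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  if (n_minor == 0L || n_minor == 2L * n) return(1)

  # possible het counts share the parity of the minor-allele count
  hets <- seq(n_minor %% 2L, min(n_minor, 2L * n - n_minor), by = 2L)
  log_p <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2          # minor-allele homozygotes
    b <- n - h - a                  # major-allele homozygotes
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Standard pre-imputation quality control
#'
#' Applies the usual pre-imputation filters to a genotype table, in order:
#' SNVs with call rate below `call_rate_min`; samples with call rate below
#' `call_rate_min`; autosomal SNVs failing the Hardy-Weinberg exact test
#' at `hwe_p_min`; and samples with excess heterozygosity, defined as an
#' inbreeding coefficient more than `het_sd` standard deviations below the
#' cohort mean. Every exclusion is itemised with its reason and the
#' offending value.
#'
#' @param callset A genotype table (see [genotype_cols()]).
#' @param call_rate_min Minimum call rate for SNVs and samples,
#'   default 0.975.
#' @param hwe_p_min Hardy-Weinberg exact p-value threshold (exclusive),
#'   default 1e-7.
#' @param het_sd How many SDs below the mean inbreeding coefficient counts
#'   as excess heterozygosity, default 4.
#' @return A list of class `qc_result`: `callset` (filtered genotype
#'   table) and `exclusions` (tibble `type, id, reason, value`).
#' @export
qc_filter <- function(callset, call_rate_min = 0.975, hwe_p_min = 1e-7,
                      het_sd = 4) {
  .check_gt(callset)
  if (nrow(callset) == 0) abort("callset is empty")
  excl <- list()
  scols <- genotype_cols(callset)
  g <- as.matrix(callset[scols])

  snv_id <- paste(callset$chrom, callset$pos, callset$ref, callset$alt, sep = ":")
  snv_cr <- rowMeans(!is.na(g))
  drop_v <- snv_cr < call_rate_min
  if (any(drop_v)) {
    excl <- c(excl, list(tibble(
      type = "snv", id = snv_id[drop_v],
      reason = "call_rate", value = snv_cr[drop_v]
    )))
    callset <- callset[!drop_v, ]
    g <- g[!drop_v, , drop = FALSE]
    snv_id <- snv_id[!drop_v]
  }

  samp_cr <- colMeans(!is.na(g))
  drop_s <- samp_cr < call_rate_min
  if (any(drop_s)) {
    excl <- c(excl, list(tibble(
      type = "sample", id = scols[drop_s],
      reason = "call_rate", value = samp_cr[drop_s]
    )))
    callset <- callset[c("chrom", "pos", "ref", "alt", scols[!drop_s])]
    scols <- scols[!drop_s]
    g <- g[, !drop_s, drop = FALSE]
  }
  if (nrow(callset) == 0 || length(scols) == 0) {
    abort("quality control removed every SNV or sample")
  }

  auto <- callset$chrom %in% .AUTOSOMES
  hwe_p <- rep(NA_real_, nrow(callset))
  hwe_p[auto] <- vapply(which(auto), function(i) {
    hwe_exact_p(sum(g[i, ] == 0, na.rm = TRUE),
                sum(g[i, ] == 1, na.rm = TRUE),
                sum(g[i, ] == 2, na.rm = TRUE))
  }, numeric(1))
  drop_h <- !is.na(hwe_p) & hwe_p < hwe_p_min
  if (any(drop_h)) {
    excl <- c(excl, list(tibble(
      type = "snv", id = snv_id[drop_h],
      reason = "hwe", value = hwe_p[drop_h]
    )))
    callset <- callset[!drop_h, ]
    g <- g[!drop_h, , drop = FALSE]
  }

  # sample inbreeding coefficient F = 1 - observed het / expected het,
  # expected from per-SNV allele frequencies over called genotypes
  p_alt <- rowMeans(g, na.rm = TRUE) / 2
  e_het <- 2 * p_alt * (1 - p_alt)
  f_coef <- vapply(seq_along(scols), function(j) {
    called <- !is.na(g[, j])
    exp_h <- sum(e_het[called])
    if (exp_h == 0) return(0)
    1 - sum(g[called, j] == 1) / exp_h
  }, numeric(1))
  if (length(f_coef) >= 2 && sd(f_coef) > 0) {
    lim <- mean(f_coef) - het_sd * sd(f_coef)
    drop_f <- f_coef < lim
    if (any(drop_f)) {
      excl <- c(excl, list(tibble(
        type = "sample", id = scols[drop_f],
        reason = "excess_heterozygosity", value = f_coef[drop_f]
      )))
      callset <- callset[c("chrom", "pos", "ref", "alt", scols[!drop_f])]
    }
  }

  structure(
    list(
      callset = as_tibble(callset),
      exclusions = if (length(excl)) bind_rows(excl) else
        tibble(type = character(), id = character(),
               reason = character(), value = numeric())
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> %d SNVs x %d samples retained; %d exclusion(s)\n",
    nrow(x$callset), length(genotype_cols(x$callset)), nrow(x$exclusions)
  ))
  if (nrow(x$exclusions)) print(count(x$exclusions, .data$type, .data$reason))
  invisible(x)
}

#' @export
tidy.qc_result <- function(x, ...) x$exclusions

#' @export
glance.qc_result <- function(x, ...) {
  tibble(
    n_snvs = nrow(x$callset),
    n_samples = length(genotype_cols(x$callset)),
    n_excluded = nrow(x$exclusions)
  )
}

#' Assign minor-allele-frequency bins
#'
#' Bins MAF into the four conventional categories: ultra-rare (below
#' 0.5%), rare (0.5--1%), low-frequency (1--5%) and common (above 5%).
#' Interval edges are left-closed/right-open at 0.005, 0.01 and 0.05, so
#' a MAF of exactly 0.01 is `low_frequency`.
#'
#' @param maf Numeric vector of minor allele frequencies in `(0, 0.5]`.
#' @return Factor with levels `ultra_rare, rare, low_frequency, common`.
#' @examples
#' assign_maf_bin(c(0.002, 0.005, 0.01, 0.2))
#' @export
assign_maf_bin <- function(maf) {
  if (any(is.na(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    abort("`maf` must be in (0, 0.5]")
  }
  f <- cut(maf, breaks = c(0, 0.005, 0.01, 0.05, 0.5),
           labels = c("ultra_rare", "rare", "low_frequency", "common"),
           right = FALSE, include.lowest = FALSE)
  f[maf == 0.5] <- "common"  # right = FALSE leaves the upper edge open
  f
}

#' Assign imputation-quality bins
#'
#' Imputation R-squared below 0.3 is low quality, above 0.8 high quality,
#' and the closed interval between them medium quality.
#'
#' @param r2 Numeric vector of per-variant imputation R-squared in `[0, 1]`.
#' @return Factor with levels `low, medium, high`.
#' @export
assign_quality_bin <- function(r2) {
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) abort("`r2` must be in [0, 1]")
  f <- cut(r2, breaks = c(-Inf, 0.3, 0.8, Inf),
           labels = c("low", "medium", "high"), right = FALSE)
  f[r2 == 0.8] <- "medium"  # medium is the closed interval [0.3, 0.8]
  f
}

#' Cross-tabulate imputation quality by MAF bin
#'
#' Counts imputed variants in each MAF bin by quality bin and reports the
#' within-MAF-bin proportions, the table behind the usual stacked-bar
#' comparison of arrays.
#'
#' @param callset A data frame with per-variant columns `maf` and `r2`.
#' @return A tibble of class `quality_summary`: `maf_bin, quality, n,
#'   prop` (proportions sum to 1 within each occupied MAF bin; empty bins
#'   are absent).
#' @export
summarize_quality <- function(callset) {
  callset <- as_tibble(callset)
  if (!all(c("maf", "r2") %in% names(callset))) {
    abort("`callset` needs `maf` and `r2` columns")
  }
  out <- callset |>
    mutate(
      maf_bin = assign_maf_bin(.data$maf),
      quality = assign_quality_bin(.data$r2)
    ) |>
    count(.data$maf_bin, .data$quality, .drop = FALSE, name = "n") |>
    group_by(.data$maf_bin) |>
    mutate(prop = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_) |>
    ungroup() |>
    filter(!is.na(.data$prop))
  structure(out, class = c("quality_summary", class(tibble())))
}

#' @export
tidy.quality_summary <- function(x, ...) as_tibble(x)

#' Mask homozygous-reference genotypes
#'
#' Sets every hom-ref call (0) to missing. Used before concordance in the
#' ultra-rare and rare MAF bins, where the overabundance of reference
#' alleles would otherwise inflate concordance; only genotypes carrying a
#' variant allele remain comparable. Idempotent.
#'
#' @param callset A genotype table.
#' @return The genotype table with hom-ref calls set to `NA`.
#' @export
mask_hom_ref <- function(callset) {
  .check_gt(callset)
  mutate(as_tibble(callset), across(
    dplyr::all_of(genotype_cols(callset)),
    ~ ifelse(!is.na(.x) & .x == 0L, NA_integer_, .x)
  ))
}

#' Per-individual genotype concordance between two callsets
#'
#' Matches variants on full `(chrom, pos, ref, alt)` identity and samples
#' by column name, then computes for each shared sample the fraction of
#' concordant genotypes over positions non-missing in both callsets. For
#' the ultra-rare and rare MAF bins, hom-ref genotypes are masked in both
#' callsets first, so only variant-allele-carrying genotypes are compared.
#' A sample with no comparable genotypes is reported with `NA` concordance
#' and excluded from the aggregate mean.
#'
#' @param a,b Genotype tables (e.g. an imputed callset and a WES callset
#'   of the same samples).
#' @param maf_bin Optional MAF bin label of the variants being compared;
#'   `"ultra_rare"` and `"rare"` trigger hom-ref masking.
#' @return A list of class `concordance_result`: `per_sample` (tibble
#'   `sample_id, compared, discordant, concordance`) and
#'   `mean_concordance`.
#' @export
per_individual_concordance <- function(a, b, maf_bin = NULL) {
  .check_gt(a, "a"); .check_gt(b, "b")
  if (!is.null(maf_bin) && maf_bin %in% c("ultra_rare", "rare")) {
    a <- mask_hom_ref(a)
    b <- mask_hom_ref(b)
  }
  samples <- intersect(genotype_cols(a), genotype_cols(b))
  if (length(samples) == 0) abort("no shared samples between callsets")
  key <- c("chrom", "pos", "ref", "alt")
  j <- inner_join(
    a[c(key, samples)], b[c(key, samples)],
    by = key, suffix = c("..a", "..b")
  )
  per_sample <- purrr::map(samples, function(s) {
    ga <- j[[paste0(s, "..a")]]
    gb <- j[[paste0(s, "..b")]]
    ok <- !is.na(ga) & !is.na(gb)
    compared <- sum(ok)
    discordant <- sum(ga[ok] != gb[ok])
    tibble(
      sample_id = s, compared = compared, discordant = discordant,
      concordance = if (compared > 0) 1 - discordant / compared else NA_real_
    )
  }) |> bind_rows()
  structure(
    list(
      per_sample = per_sample,
      mean_concordance = mean(per_sample$concordance, na.rm = TRUE)
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> %d sample(s); mean concordance %.4f\n",
    nrow(x$per_sample), x$mean_concordance
  ))
  invisible(x)
}

#' @export
tidy.concordance_result <- function(x, ...) x$per_sample

#' @export
glance.concordance_result <- function(x, ...) {
  tibble(
    n_samples = nrow(x$per_sample),
    n_defined = sum(!is.na(x$per_sample$concordance)),
    mean_concordance = x$mean_concordance,
    mean_discordance = 1 - x$mean_concordance
  )
}
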