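#' Construct a phased haplotype panel
#'
#' A haplotype panel holds phased biallelic variants as a binary matrix of
#' haplotypes (rows; two consecutive rows per diploid sample) by variants
#' (columns), together with a variant table and per-sample ancestry labels.
#' It is the reference against which array tagging and genome-wide coverage
#' are computed.
#'
#' @param variants Data frame with columns `chrom, pos, ref, alt` (one row
#'   per biallelic SNV, in column order of `haplotypes`).
#' @param haplotypes Integer/numeric matrix of 0/1 alternate-allele
#'   indicators, `2 * nrow(samples)` rows by `nrow(variants)` columns.
#' @param samples Data frame with columns `sample_id, ancestry`.
#' @return A `haplotype_panel` list with elements `variants` (including a
#'   recomputed `maf` column), `haplotypes` and `samples`.
#' @export
haplotype_panel <- function(variants, haplotypes, samples) {
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(variants))) {
    abort("`variants` needs columns chrom, pos, ref, alt")
  }
  if (!all(c("sample_id", "ancestry") %in% names(samples))) {
    abort("`samples` needs columns sample_id, ancestry")
  }
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (!all(haplotypes %in% c(0L, 1L))) abort("haplotype entries must be 0/1")
  if (nrow(haplotypes) != 2L * nrow(samples)) {
    abort("haplotype rows must equal 2 x number of samples (phased diploids)")
  }
  if (ncol(haplotypes) != nrow(variants)) {
    abort("haplotype columns must match the variant table")
  }
  variants$chrom <- normalize_chrom(variants$chrom)
  .check_chrom(variants$chrom, "panel variants")
  variants$pos <- as.integer(variants$pos)
  variants$maf <- .col_maf(haplotypes)
  structure(
    list(variants = variants, haplotypes = haplotypes, samples = samples),
    class = "haplotype_panel"
  )
}

.col_maf <- function(h) {
  f <- colMeans(h)
  pmin(f, 1 - f)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  anc <- table(x$samples$ancestry)
  cat(sprintf(
    "<haplotype_panel> %d variants x %d haplotypes (%d samples: %s)\n",
    nrow(x$variants), nrow(x$haplotypes), nrow(x$samples),
    paste(sprintf("%s=%d", names(anc), anc), collapse = ", ")
  ))
  invisible(x)
}

#' Restrict a panel to one ancestry and a minimum MAF
#'
#' Keeps the samples of the requested ancestry and the variants whose
#' minor allele frequency, recomputed within that subset, is at least
#' `min_maf` (inclusive: a variant at exactly the threshold is retained).
#' Comparing arrays at lower frequencies would be misleading because most
#' arrays are designed for common variation, so 1% is the default floor.
#'
#' @param panel A `haplotype_panel`.
#' @param ancestry Ancestry label present in `panel$samples$ancestry`.
#' @param min_maf Minimum minor allele frequency, default 0.01.
#' @return A `haplotype_panel` restricted to that ancestry, with `maf`
#'   recomputed within the subset.
#' @export
filter_panel_by_maf <- function(panel, ancestry, min_maf = 0.01) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!ancestry %in% panel$samples$ancestry) {
    abort(sprintf("ancestry '%s' not present in panel (have: %s)",
                  ancestry, paste(unique(panel$samples$ancestry), collapse = ", ")))
  }
  keep_s <- which(panel$samples$ancestry == ancestry)
  hap_rows <- as.vector(rbind(2L * keep_s - 1L, 2L * keep_s))
  h <- panel$haplotypes[hap_rows, , drop = FALSE]
  maf <- .col_maf(h)
  keep_v <- which(maf >= min_maf)
  haplotype_panel(
    variants = panel$variants[keep_v, c("chrom", "pos", "ref", "alt")],
    haplotypes = h[, keep_v, drop = FALSE],
    samples = panel$samples[keep_s, ]
  )
}

#' Linkage disequilibrium r-squared between two variants
#'
#' The squared correlation between two biallelic variants' alternate-allele
#' indicators across phased haplotypes, equivalently
#' \eqn{D^2 / (p_A p_a p_B p_b)} computed from haplotype counts. It is
#' symmetric and invariant to swapping the ref/alt coding of either
#' variant. If either variant is monomorphic in the subset, r-squared is
#' undefined and `NA_real_` is returned; such pairs never count as tagged.
#'
#' @param a,b Equal-length 0/1 haplotype indicator vectors (length >= 2).
#' @return A single numeric in `[0, 1]`, or `NA_real_` when undefined.
#' @examples
#' ld_r2(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1
#' ld_r2(c(0, 1, 0, 1), c(0, 0, 1, 1))  # 0
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    abort("`a` and `b` must be equal-length vectors of length >= 2")
  }
  pA <- mean(a)
  pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  d <- mean(a * b) - pA * pB
  d^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# r2 between columns of h indexed by `cand` and `tag`; rows of the result are
# candidates. Monomorphic columns yield NA. Uses centred cross-products, which
# equals the haplotype-count D^2/(pA pa pB pb) form exactly.
.r2_matrix <- function(h, cand, tag) {
  hc <- h[, cand, drop = FALSE]
  ht <- h[, tag, drop = FALSE]
  n <- nrow(h)
  mc <- colMeans(hc)
  mt <- colMeans(ht)
  vc <- colMeans(hc^2) - mc^2
  vt <- colMeans(ht^2) - mt^2
  cov <- crossprod(hc, ht) / n - outer(mc, mt)
  r2 <- cov^2 / outer(vc, vt)
  r2[vc == 0, ] <- NA_real_
  if (any(vt == 0)) r2[, vt == 0] <- NA_real_
  r2
}

#' Count off-array panel SNVs tagged by the array
#'
#' A panel SNV not itself on the array is *tagged* when at least one array
#' SNV on the same chromosome within `window_bp` has r-squared strictly
#' greater than `r2_min` with it. Ties at exactly `r2_min` are not tagged.
#' The returned flags permit a full audit of the L count that enters the
#' genome-wide coverage equation.
#'
#' @param array_positions Data frame with columns `chrom, pos` (an
#'   `array_manifest` works directly).
#' @param panel A MAF-filtered `haplotype_panel`.
#' @param r2_min Tagging threshold (strict), default 0.8.
#' @param window_bp Maximum tag distance in bp, default 1e6.
#' @return A list with `L` (integer) and `flags`, a tibble over panel
#'   variants with columns `chrom, pos, on_array, tagged`.
#' @export
count_tagged <- function(array_positions, panel, r2_min = 0.8, window_bp = 1e6) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (window_bp <= 0) abort("`window_bp` must be positive")
  ap <- as_tibble(array_positions)[c("chrom", "pos")]
  ap$chrom <- normalize_chrom(ap$chrom)
  ap <- distinct(ap)
  key <- paste(panel$variants$chrom, panel$variants$pos)
  on_array <- key %in% paste(ap$chrom, ap$pos)
  tagged <- rep(FALSE, nrow(panel$variants))

  for (chr in unique(panel$variants$chrom)) {
    idx <- which(panel$variants$chrom == chr)
    tag_i <- idx[on_array[idx]]
    cand_i <- idx[!on_array[idx]]
    if (length(tag_i) == 0 || length(cand_i) == 0) next
    r2 <- .r2_matrix(panel$haplotypes, cand_i, tag_i)
    dist_ok <- abs(outer(panel$variants$pos[cand_i], panel$variants$pos[tag_i], "-")) <= window_bp
    hit <- (r2 > r2_min) & dist_ok
    hit[is.na(hit)] <- FALSE
    tagged[cand_i] <- rowSums(hit) > 0
  }
  list(
    L = sum(tagged),
    flags = tibble(
      chrom = panel$variants$chrom,
      pos = panel$variants$pos,
      on_array = on_array,
      tagged = tagged
    )
  )
}

#' Genome-wide coverage rate
#'
#' The coverage rate of an array is estimated from linkage-disequilibrium
#' tagging of a reference panel as
#' \deqn{CR = \frac{\frac{L}{R-T}(G-T) + T}{G}}
#' where `L` is the number of off-array reference SNVs tagged at
#' r-squared above the threshold, `R` the reference-panel SNV count after
#' MAF filtering, `T` the total number of variants on the array, and `G`
#' the assumed genome-wide SNV count (about 19 million validated SNVs with
#' MAF above 1%).
#'
#' @param L,R,T Counts as defined above; requires `R > T` and `L <= R - T`.
#' @param G Genome-wide SNV count, default 19e6.
#' @return A one-row tibble of class `coverage_result` with columns
#'   `L, R, T, G, cr`.
#' @examples
#' coverage_rate(L = 5, R = 20, T = 10, G = 100)  # cr = 0.55
#' @export
coverage_rate <- function(L, R, T, G = 19e6) {
  if (any(c(L, R, T, G) < 0)) abort("counts must be non-negative")
  if (R <= T) abort("`R` must exceed `T`: the panel must contain off-array SNVs")
  if (L > R - T) abort("`L` cannot exceed `R - T` (off-array panel SNVs)")
  if (G < T) abort("`G` must be at least `T`")
  cr <- (L / (R - T) * (G - T) + T) / G
  structure(
    tibble(L = L, R = R, T = T, G = G, cr = cr),
    class = c("coverage_result", class(tibble()))
  )
}

#' Genome-wide coverage per ancestry
#'
#' For each ancestry: the panel is restricted to that ancestry and filtered
#' at `min_maf`, off-array SNVs tagged by array SNVs (r-squared strictly
#' above `r2_min` within `window_bp`) are counted as `L`, the filtered panel
#' size is `R`, and `T` is the array's total variant count (including
#' probes absent from the panel, per the definition of the equation's
#' symbols). The coverage rate is then computed by [coverage_rate()].
#'
#' @param manifest An `array_manifest`.
#' @param panel A `haplotype_panel` (unfiltered; filtering happens per
#'   ancestry here).
#' @param ancestries Ancestry labels to evaluate; default all in the panel.
#' @param G Genome-wide SNV count, default 19e6.
#' @param r2_min Tagging threshold, default 0.8.
#' @param window_bp Tag search window, default 1e6.
#' @param min_maf Panel MAF floor, default 0.01.
#' @return A tibble of class `coverage_result`, one row per ancestry:
#'   `array, ancestry, L, R, T, G, cr`.
#' @export
coverage_by_ancestry <- function(manifest, panel, ancestries = NULL,
                                 G = 19e6, r2_min = 0.8, window_bp = 1e6,
                                 min_maf = 0.01) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ancestries <- ancestries %||% unique(panel$samples$ancestry)
  T_arr <- nrow(manifest)
  rows <- purrr::map(ancestries, function(anc) {
    sub <- filter_panel_by_maf(panel, anc, min_maf = min_maf)
    tg <- count_tagged(manifest, sub, r2_min = r2_min, window_bp = window_bp)
    res <- coverage_rate(L = tg$L, R = nrow(sub$variants), T = T_arr, G = G)
    mutate(as_tibble(res), ancestry = anc, .before = 1)
  })
  out <- bind_rows(rows) |>
    mutate(array = array_name(manifest), .before = 1)
  structure(out, class = c("coverage_result", class(tibble())))
}

#' @export
tidy.coverage_result <- function(x, ...) as_tibble(x)

#' @export
glance.coverage_result <- function(x, ...) {
  tibble(
    n_ancestries = if ("ancestry" %in% names(x)) dplyr::n_distinct(x$ancestry) else 1L,
    cr_min = min(x$cr),
    cr_max = max(x$cr)
  )
}

#' Fraction of panel SNVs taggable by another panel SNV
#'
#' The upper bound on what any array could capture through tagging: the
#' fraction of panel SNVs that have at least one *other* panel SNV (self
#' pairs excluded) within `window_bp` at r-squared strictly above
#' `r2_min`.
#'
#' @inheritParams count_tagged
#' @return A single numeric fraction in `[0, 1]`.
#' @export
taggability <- function(panel, r2_min = 0.8, window_bp = 1e6) {
  stopifnot(inherits(panel, "haplotype_panel"))
  m <- nrow(panel$variants)
  if (m == 0) return(NA_real_)
  tagged <- rep(FALSE, m)
  for (chr in unique(panel$variants$chrom)) {
    idx <- which(panel$variants$chrom == chr)
    if (length(idx) < 2) next
    r2 <- .r2_matrix(panel$haplotypes, idx, idx)
    diag(r2) <- NA_real_
    dist_ok <- abs(outer(panel$variants$pos[idx], panel$variants$pos[idx], "-")) <= window_bp
    hit <- (r2 > r2_min) & dist_ok
    hit[is.na(hit)] <- FALSE
    tagged[idx] <- rowSums(hit) > 0
  }
  mean(tagged)
}
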