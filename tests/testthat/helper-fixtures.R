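# Fixture builders and independent oracles used across the suite.

toy_manifest <- function(n = 10, chrom = "1", name = "toy", start = 100L, by = 100L) {
  as_manifest(
    data.frame(
      chrom = chrom,
      pos = seq(start, by = by, length.out = n),
      ref = "A", alt = "G"
    ),
    name = name
  )
}

# Random genotype table: variants x samples, alt-dosage coding.
toy_genotypes <- function(n_var = 20, n_samp = 5, seed = 1,
                          miss_rate = 0, maf = NULL) {
  withr::with_seed(seed, {
    p <- if (is.null(maf)) runif(n_var, 0.05, 0.5) else rep(maf, n_var)
    g <- vapply(seq_len(n_samp), function(j) rbinom(n_var, 2L, p), integer(n_var))
    if (miss_rate > 0) g[runif(length(g)) < miss_rate] <- NA_integer_
    out <- tibble::tibble(
      chrom = as.character(sample(1:22, n_var, replace = TRUE)),
      pos = seq_len(n_var) * 50L,
      ref = "A", alt = "G"
    )
    gm <- tibble::as_tibble(matrix(g, nrow = n_var),
                            .name_repair = "minimal")
    names(gm) <- sprintf("S%03d", seq_len(n_samp))
    dplyr::bind_cols(out, gm)
  })
}

# Small random haplotype panel (no block structure): for oracle-equivalence
# tests of the windowed tagging code.
random_panel <- function(n_snvs, n_dip, seed, n_chrom = 2) {
  withr::with_seed(seed, {
    chrom <- sort(as.character(sample(seq_len(n_chrom), n_snvs, replace = TRUE)))
    pos <- integer(n_snvs)
    for (ch in unique(chrom)) {
      i <- chrom == ch
      pos[i] <- sort(sample.int(5e5, sum(i)))
    }
    p <- runif(n_snvs, 0.05, 0.95)
    h <- vapply(p, function(pp) rbinom(2L * n_dip, 1L, pp), integer(2L * n_dip))
    haplotype_panel(
      variants = tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "G"),
      haplotypes = h,
      samples = tibble::tibble(sample_id = sprintf("S%03d", seq_len(n_dip)),
                               ancestry = "EUR")
    )
  })
}

# --- independent oracles ---------------------------------------------------

# r-squared from explicit 2x2 haplotype counts (D^2 / pA pa pB pb).
oracle_r2 <- function(a, b) {
  n11 <- sum(a == 1 & b == 1)
  n <- length(a)
  pA <- sum(a) / n
  pB <- sum(b) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- n11 / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# All-pairs brute-force tagging: no windowing, no matrix algebra.
oracle_count_tagged <- function(array_positions, panel, r2_min = 0.8,
                                window_bp = Inf) {
  ap <- paste(array_positions$chrom, array_positions$pos)
  key <- paste(panel$variants$chrom, panel$variants$pos)
  on_array <- key %in% ap
  tagged <- logical(length(key))
  for (i in which(!on_array)) {
    for (j in which(on_array)) {
      if (panel$variants$chrom[i] != panel$variants$chrom[j]) next
      if (abs(panel$variants$pos[i] - panel$variants$pos[j]) > window_bp) next
      r2 <- oracle_r2(panel$haplotypes[, i], panel$haplotypes[, j])
      if (!is.na(r2) && r2 > r2_min) {
        tagged[i] <- TRUE
        break
      }
    }
  }
  sum(tagged)
}

# Exact HWE p-value by direct enumeration of heterozygote counts with
# plain choose() arithmetic (no log-space trick).
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_minor <- 2 * min(n_aa, n_bb) + n_ab
  if (n_minor == 0 || n_minor == 2 * n) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  pr <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2
    b <- n - h - a
    choose(n, h) * choose(n - h, a) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs * (1 + 1e-12)])
}
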