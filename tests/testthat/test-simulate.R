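small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, n_samples = c(EUR = 40, AFR = 30),
             n_blocks = 20, snvs_per_block = 5, ...)
}

test_that("panel generation is seed-deterministic and degenerates correctly", {
  p1 <- simulate_panel(small_cfg())
  p2 <- simulate_panel(small_cfg())
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$variants, p2$variants)
  expect_false(identical(p1$haplotypes, simulate_panel(small_cfg(seed = 8))$haplotypes))

  # K = 1, mutation 0: monomorphic panel
  mono <- simulate_panel(small_cfg(k_founders = 1, mutation_rate = 0))
  expect_true(all(mono$variants$maf == 0))

  # K = 2 complementary founders, mutation 0: every within-block pair r2 = 1
  perfect <- simulate_panel(small_cfg(mutation_rate = 0,
                                      founder_freq_range = c(0.5, 0.5)))
  b1 <- which(perfect$variants$block == 1)
  for (j in b1[-1]) {
    expect_equal(ld_r2(perfect$haplotypes[, b1[1]], perfect$haplotypes[, j]), 1)
  }
})

test_that("panel haplotype frequencies track the configured founder frequencies", {
  cfg <- sim_config(seed = 3, n_samples = c(EUR = 250), n_blocks = 30,
                    snvs_per_block = 4, mutation_rate = 0,
                    founder_freq_range = c(0.3, 0.3))
  p <- simulate_panel(cfg)
  # founder-2 frequency 0.3 at every block: allele frequency is 0.3 or 0.7,
  # so MAF has expectation 0.3; check within 3 binomial SE at 2n = 500
  se <- sqrt(0.3 * 0.7 / 500)
  mean_maf <- mean(p$variants$maf)
  expect_lt(abs(mean_maf - 0.3), 3 * se)
})

test_that("simulated manifests record covered blocks with analytic expectation", {
  p <- simulate_panel(small_cfg())
  # all blocks tagged with every SNV: the array is the panel, L = 0
  m_all <- simulate_manifest(p, tags_per_block = 5, n_tag_blocks = 20, seed = 1)
  res <- count_tagged(m_all, p)
  expect_equal(res$L, 0)

  # off-panel probes inflate T beyond the panel overlap
  m_off <- simulate_manifest(p, tags_per_block = 1, n_tag_blocks = 10,
                             off_panel_snvs = 10, seed = 1)
  on_panel <- sum(paste(m_off$chrom, m_off$pos) %in%
                  paste(p$variants$chrom, p$variants$pos))
  expect_equal(nrow(m_off) - on_panel, 10)

  # half the blocks covered in a perfect-LD panel: recovered fraction equals
  # the recorded analytic expectation exactly
  perfect <- simulate_panel(small_cfg(mutation_rate = 0,
                                      founder_freq_range = c(0.5, 0.5)))
  m_half <- simulate_manifest(perfect, tags_per_block = 1, n_tag_blocks = 10,
                              seed = 2)
  tg <- count_tagged(m_half, perfect)
  frac <- tg$L / sum(!tg$flags$on_array)
  expect_equal(frac, attr(m_half, "expected_tagged_fraction"))
  expect_equal(attr(m_half, "expected_tagged_fraction"),
               (10 * 4) / (10 * 4 + 10 * 5))
})

test_that("imputed r2 is 1 on-array and degrades with MAF off-array", {
  cfg <- sim_config(seed = 5, n_samples = c(EUR = 150), n_blocks = 60,
                    snvs_per_block = 5, founder_freq_range = c(0.02, 0.5))
  p <- simulate_panel(cfg)
  m <- simulate_manifest(p, tags_per_block = 1, n_tag_blocks = 30, seed = 5)
  imp <- simulate_imputed(p, m, cfg)
  on <- paste(imp$chrom, imp$pos) %in% paste(m$chrom, m$pos)
  expect_true(all(imp$r2[on] == 1))
  off <- imp[!on & imp$maf > 0, ]
  lo <- off$r2[off$maf < 0.05]
  hi <- off$r2[off$maf >= 0.2]
  expect_gt(mean(hi), mean(lo))  # quality decays as variants get rarer
  # determinism
  imp2 <- simulate_imputed(p, m, cfg)
  expect_identical(imp$r2, imp2$r2)
})

test_that("wes pair flips genotypes at the configured rate", {
  gt <- toy_genotypes(n_var = 400, n_samp = 40, seed = 9)
  # e = 0: concordance exactly 1
  p0 <- simulate_wes_pair(gt, e = 0, seed = 1)
  expect_equal(per_individual_concordance(p0$imputed, p0$wes)$mean_concordance, 1)
  # e = 1: concordance exactly 0
  p1 <- simulate_wes_pair(gt, e = 1, seed = 1)
  expect_equal(per_individual_concordance(p1$imputed, p1$wes)$mean_concordance, 0)
  # intermediate rate recovered within 3 binomial SE
  e <- 0.05
  pe <- simulate_wes_pair(gt, e = e, seed = 2)
  disc <- 1 - per_individual_concordance(pe$imputed, pe$wes)$mean_concordance
  se <- sqrt(e * (1 - e) / (400 * 40))
  expect_lt(abs(disc - e), 3 * se)
})

test_that("star-allele generator emits exact callable truth", {
  m <- toy_manifest(50)
  sim <- simulate_star_alleles(m, n_genes = 10, alleles_per_gene = 10,
                               frac_tags_on_array = 0.5, seed = 13)
  st <- star_allele_status(sim$alleles, m)
  joined <- dplyr::inner_join(st, sim$truth, by = c("gene", "allele"))
  expect_equal(nrow(joined), 100)
  expect_identical(joined$status == "callable", joined$callable_truth)

  # frac = 1 -> all callable; frac = 0 -> none
  s1 <- simulate_star_alleles(m, n_genes = 2, alleles_per_gene = 5,
                              frac_tags_on_array = 1, seed = 1)
  expect_true(all(star_allele_status(s1$alleles, m)$status == "callable"))
  s0 <- simulate_star_alleles(m, n_genes = 2, alleles_per_gene = 5,
                              frac_tags_on_array = 0, seed = 1)
  expect_true(all(star_allele_status(s0$alleles, m)$status == "not_callable"))
})

test_that("catalog generator truth reconciles with the filter report", {
  sim <- simulate_catalog(n_records = 300, n_duplicates = 7, seed = 17)
  res <- filter_catalog(sim$records)
  expect_equal(res$report$removed, sim$truth$removed)
  expect_equal(attr(res$report, "output_count"),
               attr(sim$truth, "expected_survivors"))

  # all-pass config: output = input
  clean <- simulate_catalog(n_records = 50, fail_probs = c(or_missing = 0),
                            seed = 17)
  res_c <- filter_catalog(clean$records)
  expect_equal(attr(res_c$report, "output_count"), 50)

  # determinism
  sim2 <- simulate_catalog(n_records = 300, n_duplicates = 7, seed = 17)
  expect_identical(sim$records, sim2$records)
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_panel(small_cfg()))
  expect_identical(.Random.seed, before)
})
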