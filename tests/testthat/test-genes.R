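toy_genes <- function() {
  # G1: two CDS exons 100-199 and 300-399 (length 200)
  # G2: 150-349, overlaps G1 (length 200)
  # G3: separate chromosome, 100-1099 (length 1000)
  tibble::tibble(
    gene = c("G1", "G1", "G2", "G3"),
    chrom = c("1", "1", "1", "2"),
    start = c(100L, 300L, 150L, 100L),
    end = c(199L, 399L, 349L, 1099L),
    category = "acmg"
  )
}

test_that("gene variant counting honours overlap and reports zeros", {
  m <- as_manifest(data.frame(
    chrom = c("1", "1", "1", "1", "2", "2"),
    pos = c(120, 180, 320, 500, 150, 600),
    ref = "A", alt = "G"
  ), name = "g")
  cnt <- count_gene_variants(m, toy_genes())
  expect_equal(cnt$n_variants[cnt$gene == "G1"], 3L)   # 120, 180, 320
  expect_equal(cnt$n_variants[cnt$gene == "G2"], 2L)   # 180, 320 (shared with G1)
  expect_equal(cnt$n_variants[cnt$gene == "G3"], 2L)
  # variant in two overlapping genes counts for both
  expect_gte(sum(cnt$n_variants), 6L)
})

test_that("interval merging collapses overlapping and book-ended exons", {
  g <- tibble::tibble(
    gene = "G", chrom = "1",
    start = c(100L, 150L, 200L, 400L),
    end = c(160L, 199L, 250L, 450L)
  )
  merged <- merge_gene_intervals(g)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$start, c(100L, 400L))
  expect_equal(merged$end, c(250L, 450L))
  expect_error(merge_gene_intervals(dplyr::mutate(g, start = 0L)), "start")
})

test_that("proxy-deleterious counting uses a strict CADD threshold", {
  m <- as_manifest(data.frame(
    chrom = "1", pos = c(120, 150, 320, 330, 340),
    ref = "A", alt = "G"
  ), name = "cadd")
  cadd <- tibble::tibble(
    chrom = "1", pos = c(120, 150, 320, 330, 340), ref = "A", alt = "G",
    cadd_phred = c(25, 20, 30, 15, 22)
  )
  res <- count_proxy_deleterious(m, toy_genes(), cadd)
  # score exactly 20 excluded; qualifying: 120 (G1), 320 (G1+G2), 340 (G1+G2)
  expect_equal(res$per_gene$n_deleterious[res$per_gene$gene == "G1"], 3L)
  expect_equal(res$per_gene$n_deleterious[res$per_gene$gene == "G2"], 2L)
  expect_equal(res$per_gene$n_deleterious[res$per_gene$gene == "G3"], 0L)
  expect_equal(res$total, 5L)
  expect_equal(res$total_distinct, 3L)

  # all scores at or below threshold: zero everywhere
  low <- dplyr::mutate(cadd, cadd_phred = 20)
  res0 <- count_proxy_deleterious(m, toy_genes(), low)
  expect_equal(res0$total, 0L)
  expect_equal(res0$median, 0)
})

test_that("median and IQR are over all genes including zero counts", {
  # five one-exon genes engineered to counts 0, 1, 2, 3, 10
  genes <- tibble::tibble(
    gene = sprintf("G%d", 1:5), chrom = "3",
    start = c(1000L, 2000L, 3000L, 4000L, 5000L),
    end = c(1999L, 2999L, 3999L, 4999L, 5999L)
  )
  pos <- c(2100, 3100, 3200, 4100, 4200, 4300, 5000 + seq(50, 950, by = 100))
  m <- as_manifest(data.frame(chrom = "3", pos = pos, ref = "C", alt = "T"),
                   name = "iqr")
  cadd <- tibble::tibble(chrom = "3", pos = pos, ref = "C", alt = "T",
                         cadd_phred = 30)
  res <- count_proxy_deleterious(m, genes, cadd)
  expect_equal(sort(res$per_gene$n_deleterious), c(0L, 1L, 2L, 3L, 10L))
  expect_equal(res$median, 2)
  expect_equal(res$iqr, c(1, 3))
})

test_that("star alleles are callable only when every tag is assayable", {
  m <- toy_manifest(5)  # chrom 1, pos 100..500, A>G
  tags3 <- tibble::tibble(
    gene = "CYP", allele = "*2", ancestry = "all",
    chrom = "1", pos = c(100L, 200L, 300L), ref = "A", alt = "G"
  )
  expect_equal(star_allele_callable(tags3, m), "callable")

  # one tag off the array: all-or-nothing
  tags_miss <- dplyr::mutate(tags3, pos = c(100L, 200L, 999L))
  expect_equal(star_allele_callable(tags_miss, m), "not_callable")

  # allele identity matters by default, position-only behind the flag
  tags_allele <- dplyr::mutate(tags3, alt = c("G", "G", "T"))
  expect_equal(star_allele_callable(tags_allele, m), "not_callable")
  expect_equal(star_allele_callable(tags_allele, m, match_alleles = FALSE),
               "callable")

  # empty/CNV tag sets are not evaluable
  cnv <- tibble::tibble(gene = "CYP", allele = "*5", ancestry = "all",
                        chrom = NA_character_, pos = NA_integer_,
                        ref = NA_character_, alt = NA_character_,
                        cnv_based = TRUE)
  expect_equal(star_allele_callable(cnv, m), "not_evaluable")
})

test_that("imputed tags rescue alleles at strictly high quality", {
  m <- toy_manifest(2)  # pos 100, 200
  tags <- tibble::tibble(
    gene = "CYP", allele = "*3", ancestry = "all",
    chrom = "1", pos = c(100L, 900L), ref = "A", alt = "G"
  )
  expect_equal(star_allele_callable(tags, m), "not_callable")
  imp_hi <- tibble::tibble(chrom = "1", pos = 900L, ref = "A", alt = "G", r2 = 0.9)
  imp_at <- dplyr::mutate(imp_hi, r2 = 0.8)
  expect_equal(star_allele_callable(tags, m, imputed = imp_hi), "callable")
  expect_equal(star_allele_callable(tags, m, imputed = imp_at), "not_callable")

  # imputed-mode callable set is a superset when all array variants are
  # imputable at r2 = 1
  sim <- simulate_star_alleles(toy_manifest(30), n_genes = 3,
                               alleles_per_gene = 6, frac_tags_on_array = 0.6,
                               seed = 11)
  arr_mode <- star_allele_status(sim$alleles, toy_manifest(30))
  imp_all <- dplyr::mutate(tibble::as_tibble(toy_manifest(30)), r2 = 1)
  imp_mode <- star_allele_status(sim$alleles, toy_manifest(30), imputed = imp_all)
  callable_arr <- arr_mode$status == "callable"
  callable_imp <- imp_mode$status == "callable"
  expect_true(all(callable_imp[callable_arr]))
})

test_that("percent_star_alleles computes per-gene percentages", {
  m <- toy_manifest(5)
  alleles <- dplyr::bind_rows(
    tibble::tibble(gene = "CYP", allele = "*2", ancestry = "all",
                   chrom = "1", pos = 100L, ref = "A", alt = "G"),
    tibble::tibble(gene = "CYP", allele = "*3", ancestry = "all",
                   chrom = "1", pos = 200L, ref = "A", alt = "G"),
    tibble::tibble(gene = "CYP", allele = "*4", ancestry = "all",
                   chrom = "1", pos = 998L, ref = "A", alt = "G"),
    tibble::tibble(gene = "CYP", allele = "*5", ancestry = "all",
                   chrom = "1", pos = 999L, ref = "A", alt = "G")
  )
  p <- percent_star_alleles(alleles, m)
  expect_equal(p$pct_callable, 50)
  expect_equal(p$n_evaluable, 4L)
  # monotone when variants are added to the manifest
  m_bigger <- as_manifest(dplyr::bind_rows(
    tibble::as_tibble(m),
    tibble::tibble(chrom = "1", pos = 998L, ref = "A", alt = "G",
                   probe_class = "snv", functional = "other")
  ), name = "bigger")
  p2 <- percent_star_alleles(alleles, m_bigger)
  expect_gte(p2$pct_callable, p$pct_callable)
  expect_equal(p2$pct_callable, 75)
})

test_that("HLA percentages are ancestry-specific with per-gene mean and SD", {
  m <- toy_manifest(10)  # pos 100..1000
  mk_tags <- function(gene, allele, anc, pos) {
    tibble::tibble(gene = gene, allele = allele, ancestry = anc,
                   chrom = "1", pos = as.integer(pos), ref = "A", alt = "G")
  }
  alleles <- dplyr::bind_rows(
    # HLA-A*01: EUR needs pos 100; AFR needs 100 AND an off-array extra
    mk_tags("HLA-A", "*01", "EUR", 100),
    mk_tags("HLA-A", "*01", "AFR", c(100, 5000)),
    mk_tags("HLA-A", "*01", "ASN", 100),
    mk_tags("HLA-A", "*02", "EUR", 200),
    mk_tags("HLA-A", "*02", "AFR", 200),
    mk_tags("HLA-A", "*02", "ASN", 200)
  )
  res <- hla_percent_by_ancestry(alleles, m)
  by_anc <- res$by_ancestry
  expect_equal(by_anc$pct_callable[by_anc$ancestry == "EUR"], 100)
  expect_equal(by_anc$pct_callable[by_anc$ancestry == "AFR"], 50)
  g <- res$per_gene
  expect_equal(g$mean_pct, mean(c(100, 50, 100)))
  expect_equal(g$sd_pct, sd(c(100, 50, 100)))

  # identical tag sets across ancestries give identical columns
  same <- dplyr::bind_rows(mk_tags("HLA-B", "*07", "EUR", 300),
                           mk_tags("HLA-B", "*07", "AFR", 300),
                           mk_tags("HLA-B", "*07", "ASN", 300))
  res2 <- hla_percent_by_ancestry(same, m)
  expect_equal(unique(res2$by_ancestry$pct_callable), 100)
  expect_equal(res2$per_gene$sd_pct, 0)

  # a gene with no alleles for one ancestry warns and leaves NA
  partial <- dplyr::bind_rows(mk_tags("HLA-C", "*04", "EUR", 400),
                              mk_tags("HLA-C", "*04", "AFR", 400))
  expect_warning(res3 <- hla_percent_by_ancestry(partial, m), "no defined")
  expect_true(is.na(
    res3$by_ancestry$pct_callable[res3$by_ancestry$ancestry == "ASN"]
  ))
})

test_that("mtDNA tallies count per overlapping locus and distinct in total", {
  m <- as_manifest(data.frame(
    chrom = c("MT", "MT", "MT", "MT", "MT", "1"),
    pos = c(100, 150, 200, 300, 16000, 500),
    ref = "A", alt = "G"
  ), name = "mt")
  loci <- tibble::tibble(
    locus = c("L1", "L2", "L3"),
    start = c(50L, 120L, 250L),
    end = c(220L, 180L, 16569L)
  )
  res <- mtdna_tally(m, loci)
  expect_equal(res$per_locus$n_variants, c(3L, 1L, 2L))
  expect_equal(res$total, 5L)
  # per-locus sums exceed total when loci overlap
  expect_gte(sum(res$per_locus$n_variants), res$total)

  # zero-MT manifest
  m0 <- toy_manifest(3)
  res0 <- mtdna_tally(m0, loci)
  expect_true(all(res0$per_locus$n_variants == 0))
  expect_equal(res0$total, 0L)
  expect_error(mtdna_tally(m, dplyr::mutate(loci, end = 20000L)), "16569")
})

test_that("the bundled synthetic mtDNA locus table loads and tallies", {
  loci <- readr::read_tsv(
    system.file("extdata", "mtdna_loci_synthetic.tsv", package = "arrayscope"),
    show_col_types = FALSE
  )
  expect_equal(nrow(loci), 75)
  m <- as_manifest(
    data.frame(chrom = "MT", pos = seq(100, 16500, by = 500),
               ref = "A", alt = "G"),
    name = "mtprobe"
  )
  res <- mtdna_tally(m, loci)
  expect_equal(res$total, nrow(m))
  expect_gte(sum(res$per_locus$n_variants), res$total)  # loci overlap
})

test_that("CDS density satisfies its defining identity", {
  genes <- tibble::tibble(gene = "G", chrom = "1", start = 1L, end = 1000L)
  m4 <- as_manifest(data.frame(chrom = "1", pos = c(10, 20, 30, 40),
                               ref = "A", alt = "G"), name = "d")
  d <- cds_density(m4, genes)
  expect_equal(d$mean_distance, 200)           # 1000 / (4 + 1)
  expect_equal(d$mean_distance * (d$n_snvs + 1), d$cds_length)

  # no SNVs: distance equals CDS length
  m0 <- as_manifest(data.frame(chrom = "2", pos = 10, ref = "A", alt = "G"),
                    name = "d0")
  expect_equal(cds_density(m0, genes)$mean_distance, 1000)

  # saturation: 999 SNVs in 1000 bp -> 1 bp
  m999 <- as_manifest(data.frame(chrom = "1", pos = 1:999, ref = "A", alt = "G"),
                      name = "d999")
  expect_equal(cds_density(m999, genes)$mean_distance, 1)
})

test_that("window density counts, sums and summarises over fixed windows", {
  chrom_lengths <- tibble::tibble(chrom = "1", length = 5000L)
  # uniform one variant per 1 kb window
  m_u <- as_manifest(data.frame(chrom = "1", pos = c(500, 1500, 2500, 3500, 4500),
                                ref = "A", alt = "G"), name = "u")
  wu <- window_density(m_u, 1000, chrom_lengths)
  expect_equal(wu$mean, 1)
  expect_equal(wu$sd, 0)
  expect_equal(wu$n_windows, 5)

  # hand-computed mean/SD over 5 windows with counts 4,3,2,1,0
  pos <- c(1, 2, 3, 999, 1001, 1002, 1003, 2001, 2002, 3001)
  m_h <- as_manifest(data.frame(chrom = "1", pos = pos, ref = "A", alt = "G"),
                     name = "h")
  wh <- window_density(m_h, 1000, chrom_lengths)
  expect_equal(sort(wh$windows$n), c(0L, 1L, 2L, 3L, 4L))
  expect_equal(wh$mean, mean(c(4, 3, 2, 1, 0)))
  expect_equal(wh$sd, sd(c(4, 3, 2, 1, 0)))
  expect_equal(wh$n_variants, 10)
  expect_equal(sum(wh$windows$n), 10)

  # empty manifest (after mapping): mean 0, sd 0
  m_e <- as_manifest(data.frame(chrom = "2", pos = 10, ref = "A", alt = "G"),
                     name = "e")
  expect_message(we <- window_density(m_e, 1000, chrom_lengths), "dropping")
  expect_equal(we$mean, 0)
  expect_equal(we$sd, 0)

  # variant beyond the stated chromosome length errors
  m_bad <- as_manifest(data.frame(chrom = "1", pos = 6000, ref = "A", alt = "G"),
                       name = "b")
  expect_error(window_density(m_bad, 1000, chrom_lengths), "beyond")
})
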