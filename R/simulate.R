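#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults
#' emulate the structure of a phased continental reference panel: three
#' ancestries with the familiar 379/286/246 sample split, block-structured
#' LD from a founder-copy model, a uniform founder-frequency spectrum, a
#' small allele-flip rate standing in for recurrent mutation and
#' genotyping noise, an imputation-quality model whose mean R-squared
#' decays with decreasing MAF, and a 1% genotype-flip rate for synthetic
#' exome comparisons.
#'
#' @param seed Integer seed; the same seed and config give bit-identical
#'   output.
#' @param n_samples Named integer vector of diploid sample counts per
#'   ancestry.
#' @param n_blocks Number of independent LD blocks.
#' @param block_length Block length in bp.
#' @param snvs_per_block SNVs per block (evenly spaced).
#' @param k_founders Founder haplotypes per block. With the default 2 the
#'   two founders are complementary, so every within-block pair of SNVs is
#'   in complete LD before mutation.
#' @param recomb_prob Probability that a haplotype redraws its founder
#'   between adjacent blocks (1 = independent blocks).
#' @param mutation_rate Per-allele flip probability after founder copying.
#' @param founder_freq_range Range the per-block, per-ancestry founder-2
#'   frequency is drawn from (uniform).
#' @param maf_floor MAF floor used when filtering panels.
#' @param r2_intercept,r2_slope Logistic link for the mean imputation
#'   R-squared: `plogis(r2_intercept + r2_slope * log10(maf))`.
#' @param r2_dispersion Beta-distribution precision of simulated R-squared
#'   around its mean (larger = tighter).
#' @param wes_flip_rate Probability a synthetic exome copy flips a
#'   non-missing genotype to a different state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = c(EUR = 379L, ASN = 286L, AFR = 246L),
                       n_blocks = 100L,
                       block_length = 10000L,
                       snvs_per_block = 10L,
                       k_founders = 2L,
                       recomb_prob = 1,
                       mutation_rate = 0.002,
                       founder_freq_range = c(0.1, 0.9),
                       maf_floor = 0.01,
                       r2_intercept = 4,
                       r2_slope = 1.6,
                       r2_dispersion = 30,
                       wes_flip_rate = 0.01) {
  cfg <- list(
    seed = as.integer(seed), n_samples = n_samples, n_blocks = as.integer(n_blocks),
    block_length = as.integer(block_length), snvs_per_block = as.integer(snvs_per_block),
    k_founders = as.integer(k_founders), recomb_prob = recomb_prob,
    mutation_rate = mutation_rate, founder_freq_range = founder_freq_range,
    maf_floor = maf_floor, r2_intercept = r2_intercept, r2_slope = r2_slope,
    r2_dispersion = r2_dispersion, wes_flip_rate = wes_flip_rate
  )
  stopifnot(
    all(cfg$n_samples >= 1), !is.null(names(cfg$n_samples)),
    cfg$n_blocks >= 1, cfg$snvs_per_block >= 1, cfg$k_founders >= 1,
    cfg$recomb_prob >= 0, cfg$recomb_prob <= 1,
    cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
    cfg$wes_flip_rate >= 0, cfg$wes_flip_rate <= 1
  )
  structure(cfg, class = "sim_config")
}

# Runs code under a local RNG state seeded from `seed`, leaving the
# caller's RNG untouched.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a phased block-LD haplotype panel
#'
#' A founder-copy model: each block carries `k_founders` founder
#' haplotypes; every sampled haplotype copies one founder per block
#' (chosen by an ancestry- and block-specific frequency) and then flips
#' each allele independently at `mutation_rate`. With two complementary
#' founders every within-block pair of SNVs is in complete LD up to
#' mutation, while founder choices are independent across blocks (at
#' `recomb_prob = 1`), so between-block r-squared is at noise level. This
#' yields analytic tagging expectations; it does not attempt realistic
#' genealogies, recombination maps or allele-frequency spectra.
#'
#' All variants are placed on chromosome 1, block `b` occupying
#' `[(b-1) * block_length + 1, b * block_length]`, SNVs evenly spaced.
#'
#' @param cfg A [sim_config()].
#' @return A `haplotype_panel`; its `variants` table carries a `block`
#'   column as generator truth.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    n_tot <- sum(cfg$n_samples)
    anc <- rep(names(cfg$n_samples), cfg$n_samples)
    n_hap <- 2L * n_tot
    B <- cfg$n_blocks
    s <- cfg$snvs_per_block
    m <- B * s

    # founder allele patterns per block: k x s; with k = 2 the founders are
    # complementary so every SNV is polymorphic across founders
    founders <- lapply(seq_len(B), function(b) {
      if (cfg$k_founders == 2L) {
        f1 <- rbinom(s, 1L, 0.5)
        rbind(f1, 1L - f1)
      } else {
        matrix(rbinom(cfg$k_founders * s, 1L, 0.5), nrow = cfg$k_founders)
      }
    })
    # per-ancestry, per-block founder-2 (or dirichlet-ish) weights
    freq <- matrix(
      runif(B * length(cfg$n_samples), cfg$founder_freq_range[1], cfg$founder_freq_range[2]),
      nrow = B, dimnames = list(NULL, names(cfg$n_samples))
    )

    h <- matrix(0L, nrow = n_hap, ncol = m)
    hap_anc <- rep(anc, each = 2L)
    prev_choice <- integer(n_hap)
    for (b in seq_len(B)) {
      if (cfg$k_founders == 2L) {
        p2 <- freq[b, hap_anc]
        draw <- rbinom(n_hap, 1L, p2) + 1L
      } else {
        draw <- sample.int(cfg$k_founders, n_hap, replace = TRUE)
      }
      if (b > 1L && cfg$recomb_prob < 1) {
        keep <- runif(n_hap) >= cfg$recomb_prob
        draw[keep] <- prev_choice[keep]
      }
      prev_choice <- draw
      block <- founders[[b]][draw, , drop = FALSE]
      if (cfg$mutation_rate > 0) {
        flips <- matrix(rbinom(n_hap * s, 1L, cfg$mutation_rate), nrow = n_hap)
        block <- (block + flips) %% 2L
      }
      h[, ((b - 1L) * s + 1L):(b * s)] <- block
    }

    spacing <- max(1L, cfg$block_length %/% (s + 1L))
    variants <- tibble(
      chrom = "1",
      pos = as.integer(rep((seq_len(B) - 1L) * cfg$block_length, each = s) +
                         spacing * seq_len(s)),
      ref = "A",
      alt = "G",
      block = rep(seq_len(B), each = s)
    )
    panel <- haplotype_panel(
      variants = variants[c("chrom", "pos", "ref", "alt")],
      haplotypes = h,
      samples = tibble(sample_id = sprintf("S%04d", seq_len(n_tot)), ancestry = anc)
    )
    panel$variants$block <- variants$block
    panel
  })
}

#' Simulate an array manifest as a tag-SNV subset of a panel
#'
#' Chooses `n_tag_blocks` blocks (deterministically the first ones, or at
#' random with `random_blocks = TRUE`) and puts `tags_per_block` of their
#' SNVs on the array, plus `off_panel_snvs` probes at positions absent
#' from the panel. Which blocks are covered is recorded in the
#' `tagged_blocks` attribute, making the expected tagged fraction of
#' off-array SNVs analytic: with complete within-block LD every off-array
#' SNV in a covered block is tagged and no other SNV is.
#'
#' @param panel A `haplotype_panel` from [simulate_panel()] (its
#'   `variants` must carry the `block` column).
#' @param tags_per_block Tag SNVs placed on the array per covered block.
#' @param n_tag_blocks Number of blocks covered; default all.
#' @param off_panel_snvs Number of probes at non-panel positions,
#'   default 0.
#' @param seed Integer seed.
#' @param random_blocks Sample covered blocks at random instead of taking
#'   the first `n_tag_blocks`, default `FALSE`.
#' @param name Array name for the manifest.
#' @return An `array_manifest` with attributes `tagged_blocks` (integer
#'   vector) and `expected_tagged_fraction` (analytic fraction of
#'   off-array panel SNVs in covered blocks).
#' @export
simulate_manifest <- function(panel, tags_per_block = 1L, n_tag_blocks = NULL,
                              off_panel_snvs = 0L, seed = 1L,
                              random_blocks = FALSE, name = "sim_array") {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!"block" %in% names(panel$variants)) {
    abort("panel variants need the generator's `block` column")
  }
  blocks <- sort(unique(panel$variants$block))
  n_tag_blocks <- n_tag_blocks %||% length(blocks)
  snvs_per_block <- max(table(panel$variants$block))
  if (tags_per_block > snvs_per_block) {
    abort("`tags_per_block` exceeds SNVs per block")
  }
  .with_seed(seed, {
    covered <- if (random_blocks) sort(sample(blocks, n_tag_blocks)) else
      blocks[seq_len(n_tag_blocks)]
    tag_rows <- panel$variants |>
      mutate(.row = dplyr::row_number()) |>
      filter(.data$block %in% covered) |>
      group_by(.data$block) |>
      slice_head(n = tags_per_block) |>
      ungroup()
    probes <- tag_rows[c("chrom", "pos", "ref", "alt")]
    if (off_panel_snvs > 0) {
      # off-panel probes live on a chromosome the panel never uses
      probes <- bind_rows(probes, tibble(
        chrom = "2",
        pos = as.integer(seq_len(off_panel_snvs) * 1000L),
        ref = "C", alt = "T"
      ))
    }
    on_array <- panel$variants$pos %in% tag_rows$pos &
      panel$variants$chrom == "1"
    off_array <- !on_array
    expected <- if (sum(off_array) > 0) {
      sum(off_array & panel$variants$block %in% covered) / sum(off_array)
    } else NA_real_
    m <- as_manifest(probes, name = name)
    attr(m, "tagged_blocks") <- covered
    attr(m, "expected_tagged_fraction") <- expected
    m
  })
}

#' Simulate an imputed callset from a panel and a manifest
#'
#' Emulates the per-variant output of an imputation service: every panel
#' variant receives an imputation R-squared and the diploid genotypes of
#' the panel's samples. Variants on the array get R-squared 1 (they are
#' genotyped, not imputed); off-array variants draw R-squared from a Beta
#' distribution whose mean follows the configured logistic link in
#' log10(MAF), so quality degrades as variants get rarer -- the
#' qualitative pattern real imputation shows.
#'
#' @param panel A `haplotype_panel`.
#' @param manifest An `array_manifest` (positions define what was
#'   genotyped).
#' @param cfg A [sim_config()]; uses `r2_intercept`, `r2_slope`,
#'   `r2_dispersion` and `seed`.
#' @return A genotype table (see [genotype_cols()]) with extra per-variant
#'   columns `maf` and `r2`.
#' @export
simulate_imputed <- function(panel, manifest, cfg) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 1L, {
    maf <- panel$variants$maf
    on_array <- paste(panel$variants$chrom, panel$variants$pos) %in%
      paste(manifest$chrom, manifest$pos)
    mu <- plogis(cfg$r2_intercept + cfg$r2_slope * log10(pmax(maf, 1e-4)))
    r2 <- rbeta(length(maf), mu * cfg$r2_dispersion, (1 - mu) * cfg$r2_dispersion)
    r2[on_array] <- 1
    g <- panel$haplotypes[seq(1, nrow(panel$haplotypes), by = 2), , drop = FALSE] +
      panel$haplotypes[seq(2, nrow(panel$haplotypes), by = 2), , drop = FALSE]
    gt <- as_tibble(t(g), .name_repair = "minimal")
    names(gt) <- panel$samples$sample_id
    bind_cols(
      panel$variants[c("chrom", "pos", "ref", "alt")],
      tibble(maf = maf, r2 = r2),
      gt
    )
  })
}

#' Simulate a genotyped/exome callset pair with a known flip rate
#'
#' Copies the truth genotypes twice: the first copy is returned unchanged
#' (standing for the imputed/array callset), the second has every
#' non-missing genotype flipped to one of the other two states with
#' probability `e` (standing for an exome-sequencing callset with a known
#' discordance). Expected per-genotype discordance is exactly `e`.
#'
#' @param truth A genotype table.
#' @param e Genotype flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with elements `imputed` and `wes`, both genotype
#'   tables.
#' @export
simulate_wes_pair <- function(truth, e, seed = 1L) {
  .check_gt(truth, "truth")
  stopifnot(e >= 0, e <= 1)
  scols <- genotype_cols(truth)
  .with_seed(seed, {
    wes <- truth
    g <- as.matrix(truth[scols])
    flip <- !is.na(g) & matrix(runif(length(g)) < e, nrow = nrow(g))
    if (any(flip)) {
      # move to one of the two other states, uniformly
      shift <- matrix(sample(1:2, length(g), replace = TRUE), nrow = nrow(g))
      g[flip] <- (g[flip] + shift[flip]) %% 3L
    }
    wes[scols] <- as_tibble(g, .name_repair = "minimal")
    list(imputed = as_tibble(truth), wes = as_tibble(wes))
  })
}

#' Simulate star-allele definitions with known callability truth
#'
#' Builds `n_genes * alleles_per_gene` star alleles whose tag SNVs are
#' drawn from the manifest with probability `frac_tags_on_array` per tag
#' (off-array tags get positions no manifest probe occupies), and emits
#' the resulting callable truth per allele, so identifiability code can
#' be checked against construction rather than re-derivation.
#'
#' @param manifest An `array_manifest`.
#' @param n_genes,alleles_per_gene Table dimensions.
#' @param frac_tags_on_array Per-tag probability of being drawn from the
#'   manifest.
#' @param tags_range Range of tag-set sizes per allele, default 1--3.
#' @param seed Integer seed.
#' @return A list: `alleles` (tag-row table for [star_allele_status()])
#'   and `truth` (tibble `gene, allele, callable_truth`).
#' @export
simulate_star_alleles <- function(manifest, n_genes = 5L, alleles_per_gene = 10L,
                                  frac_tags_on_array = 0.5, tags_range = c(1L, 3L),
                                  seed = 1L) {
  stopifnot(frac_tags_on_array >= 0, frac_tags_on_array <= 1, nrow(manifest) > 0)
  .with_seed(seed, {
    off_pos_pool <- setdiff(seq_len(max(manifest$pos) + 10000L), manifest$pos)
    rows <- list()
    truth <- list()
    for (gi in seq_len(n_genes)) {
      gene <- sprintf("GENE%02d", gi)
      for (ai in seq_len(alleles_per_gene)) {
        allele <- sprintf("*%d", ai + 1L)
        n_tags <- sample(seq(tags_range[1], tags_range[2]), 1L)
        on <- runif(n_tags) < frac_tags_on_array
        tag_rows <- vector("list", n_tags)
        for (t in seq_len(n_tags)) {
          if (on[t]) {
            i <- sample.int(nrow(manifest), 1L)
            tag_rows[[t]] <- tibble(
              chrom = manifest$chrom[i], pos = manifest$pos[i],
              ref = manifest$ref[i], alt = manifest$alt[i]
            )
          } else {
            tag_rows[[t]] <- tibble(
              chrom = manifest$chrom[1],
              pos = sample(off_pos_pool, 1L),
              ref = "A", alt = "C"
            )
          }
        }
        rows[[length(rows) + 1L]] <- bind_rows(tag_rows) |>
          mutate(gene = gene, allele = allele, ancestry = "all", .before = 1)
        truth[[length(truth) + 1L]] <- tibble(
          gene = gene, allele = allele, callable_truth = all(on)
        )
      }
    }
    list(alleles = bind_rows(rows), truth = bind_rows(truth))
  })
}

#' Simulate a GWAS-catalog export with planted filter failures
#'
#' Generates `n_records` association records that would all survive the
#' standard filter, then independently plants one failure per criterion
#' with the given probabilities, and finally appends duplicated
#' `(trait, rsid)` records at higher p-values. The emitted truth counts
#' removals per criterion in filter-application order (a record failing
#' several criteria is attributed to the first), so a filter report can
#' be checked against construction.
#'
#' @param n_records Number of base records.
#' @param fail_probs Named probabilities for `or_missing, raf_missing,
#'   p_high, not_case_control, non_disease, low_if` (missing names
#'   default to 0).
#' @param n_duplicates Number of duplicated records appended.
#' @param seed Integer seed.
#' @return A list: `records` (catalog tibble with `chrom`/`pos`) and
#'   `truth` (tibble `criterion, removed` in application order plus an
#'   `expected_survivors` attribute).
#' @export
simulate_catalog <- function(n_records = 100L,
                             fail_probs = c(or_missing = 0.1, raf_missing = 0.1,
                                            p_high = 0.1, not_case_control = 0.1,
                                            non_disease = 0.1, low_if = 0.1),
                             n_duplicates = 0L, seed = 1L) {
  all_crit <- c("or_missing", "raf_missing", "p_high", "not_case_control",
                "non_disease", "low_if")
  probs <- setNames(rep(0, length(all_crit)), all_crit)
  probs[names(fail_probs)] <- fail_probs
  .with_seed(seed, {
    rec <- tibble(
      rsid = sprintf("rs%07d", seq_len(n_records)),
      trait = sprintf("disease_%03d", sample.int(max(1L, n_records %/% 2L),
                                                 n_records, replace = TRUE)),
      chrom = as.character(sample(1:22, n_records, replace = TRUE)),
      pos = sample.int(5e7, n_records),
      p_value = 10^runif(n_records, -30, -8.5),
      odds_ratio = exp(runif(n_records, -0.7, 0.7)),
      risk_allele_freq = runif(n_records, 0.01, 0.99),
      study_design = "case_control",
      trait_class = "disease",
      journal_if_2019 = runif(n_records, 5.1, 50)
    )
    fails <- sapply(all_crit, function(cr) runif(n_records) < probs[cr])
    rec$odds_ratio[fails[, "or_missing"]] <- NA_real_
    rec$risk_allele_freq[fails[, "raf_missing"]] <- NA_real_
    rec$p_value[fails[, "p_high"]] <- 10^runif(sum(fails[, "p_high"]), -7.2, -2)
    rec$study_design[fails[, "not_case_control"]] <- "cohort"
    rec$trait_class[fails[, "non_disease"]] <- "non_disease"
    rec$journal_if_2019[fails[, "low_if"]] <- runif(sum(fails[, "low_if"]), 0.5, 5)

    # removal attribution in filter-application order; duplicates are
    # removed at the dedup step only if both copies survive p/OR/RAF checks
    first_fail <- apply(fails, 1, function(f) {
      i <- which(f)
      if (length(i) == 0) NA_integer_ else min(i)
    })
    order_crit <- c("or_reported", "raf_reported", "p_significant",
                    "deduplicated", "case_control", "disease_trait",
                    "impact_factor")
    map_to_step <- c(or_missing = 1L, raf_missing = 2L, p_high = 3L,
                     not_case_control = 5L, non_disease = 6L, low_if = 7L)
    removed <- setNames(rep(0L, 7L), order_crit)
    for (i in seq_len(n_records)) {
      if (!is.na(first_fail[i])) {
        removed[map_to_step[all_crit[first_fail[i]]]] <-
          removed[map_to_step[all_crit[first_fail[i]]]] + 1L
      }
    }
    dups <- tibble()
    if (n_duplicates > 0) {
      survivors <- which(is.na(first_fail))
      if (length(survivors) < 1) abort("no surviving records to duplicate")
      src <- sample(survivors, n_duplicates, replace = TRUE)
      dups <- rec[src, ]
      dups$p_value <- pmin(dups$p_value * 10, 4.9e-8)  # worse but still significant
      removed["deduplicated"] <- removed["deduplicated"] + n_duplicates
    }
    truth <- tibble(criterion = order_crit, removed = unname(removed))
    attr(truth, "expected_survivors") <- sum(is.na(first_fail))
    list(records = bind_rows(rec, dups), truth = truth)
  })
}
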