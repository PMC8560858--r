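#' Read a phased haplotype panel from a VCF
#'
#' Reads biallelic SNV records with phased GT fields into a
#' [haplotype_panel()]. Multi-allelic sites are decomposed into biallelic
#' records (one per alternate allele); indels are dropped, as LD tagging
#' and coverage are defined over SNVs. Sample ancestries come from a
#' two-column mapping.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param ancestry_map A data frame `sample_id, ancestry`, or a path to a
#'   TSV with those columns.
#' @return A `haplotype_panel`.
#' @export
read_panel_vcf <- function(path, ancestry_map) {
  if (is.character(ancestry_map)) {
    ancestry_map <- readr::read_tsv(ancestry_map, show_col_types = FALSE,
                                    progress = FALSE)
  }
  ancestry_map <- as_tibble(ancestry_map)
  if (!all(c("sample_id", "ancestry") %in% names(ancestry_map))) {
    abort("ancestry map needs columns sample_id, ancestry")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  miss <- setdiff(samples, ancestry_map$sample_id)
  if (length(miss) > 0) {
    abort(sprintf("samples without ancestry label: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }

  rows <- list()
  haps <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    g <- gt[i, ]
    alleles <- strsplit(g, "[|/]")
    a1 <- suppressWarnings(as.integer(vapply(alleles, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(alleles, `[`, "", 2L)))
    if (anyNA(a1) || anyNA(a2)) {
      abort(sprintf("missing or haploid GT at %s:%s; panels must be fully phased diploid",
                    fix$CHROM[i], fix$POS[i]))
    }
    for (k in seq_along(alts)) {  # decompose multi-allelics
      if (nchar(ref) != 1L || nchar(alts[k]) != 1L) next  # SNVs only
      rows[[length(rows) + 1L]] <- tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = ref, alt = alts[k]
      )
      haps[[length(haps) + 1L]] <-
        as.integer(rbind(a1 == k, a2 == k))
    }
  }
  if (length(rows) == 0) abort(sprintf("no biallelic SNV records in %s", path))
  h <- do.call(cbind, haps)
  ord <- match(samples, ancestry_map$sample_id)
  haplotype_panel(
    variants = bind_rows(rows),
    haplotypes = h,
    samples = tibble(sample_id = samples,
                     ancestry = ancestry_map$ancestry[ord])
  )
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- nrow(panel$samples)
  h <- panel$haplotypes
  gt <- vapply(seq_len(n), function(j) {
    paste0(h[2L * j - 1L, ], "|", h[2L * j, ])
  }, character(ncol(h)))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = ncol(h))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t")
  )
  body <- paste(
    panel$variants$chrom, panel$variants$pos, ".",
    panel$variants$ref, panel$variants$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an imputed callset from a VCF
#'
#' Extracts per-variant imputation quality and allele frequency from the
#' INFO field (keys `R2` and either `MAF` or `AF`, the dialect imputation
#' servers write) and diploid genotypes from GT into a genotype table
#' with `maf` and `r2` columns.
#'
#' @param path VCF file path.
#' @return A genotype table with per-variant `maf` and `r2` columns.
#' @export
read_imputed_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "R2")))
  maf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MAF")))
  if (all(is.na(maf))) {
    af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
    maf <- pmin(af, 1 - af)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  num <- apply(gt, 2, function(g) {
    parts <- strsplit(g, "[|/]")
    a1 <- suppressWarnings(as.integer(vapply(parts, function(p) p[1] %||% NA_character_, "")))
    a2 <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")))
    a1 + a2
  })
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(fix),
                                       dimnames = list(NULL, colnames(gt)))
  out <- bind_cols(
    tibble(chrom = normalize_chrom(fix$CHROM), pos = as.integer(fix$POS),
           ref = fix$REF, alt = fix$ALT, maf = maf, r2 = r2),
    as_tibble(num, .name_repair = "minimal")
  )
  out
}

#' Write a genotype table as a VCF
#'
#' Writes hard genotypes (`0/0`, `0/1`, `1/1`, `./.`) with optional `R2`
#' and `MAF` INFO keys when the table carries those columns, in the
#' dialect [read_imputed_vcf()] reads back.
#'
#' @param gt A genotype table (see [genotype_cols()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gt, path) {
  .check_gt(gt, "gt")
  scols <- genotype_cols(gt)
  g <- as.matrix(gt[scols])
  code <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  code[!is.na(g) & g == 0L] <- "0/0"
  code[!is.na(g) & g == 1L] <- "0/1"
  code[!is.na(g) & g == 2L] <- "1/1"
  info <- rep(".", nrow(gt))
  has_r2 <- "r2" %in% names(gt)
  has_maf <- "maf" %in% names(gt)
  if (has_r2 || has_maf) {
    info <- vapply(seq_len(nrow(gt)), function(i) {
      parts <- c(
        if (has_r2) sprintf("R2=%.6g", gt$r2[i]),
        if (has_maf) sprintf("MAF=%.6g", gt$maf[i])
      )
      paste(parts, collapse = ";")
    }, "")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", scols), collapse = "\t")
  )
  body <- paste(
    gt$chrom, gt$pos, ".", gt$ref, gt$alt, ".", "PASS", info, "GT",
    apply(code, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
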