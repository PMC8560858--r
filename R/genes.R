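#' Merge CDS intervals within genes
#'
#' Gene/CDS tables list one row per CDS exon (`gene, chrom, start, end`,
#' 1-based inclusive, optional `category`). Overlapping or book-ended
#' intervals within a gene are merged so membership tests and CDS lengths
#' are well defined.
#'
#' @param genes A data frame with columns `gene, chrom, start, end` and
#'   optionally `category`.
#' @return A tibble of merged intervals with the same columns.
#' @export
merge_gene_intervals <- function(genes) {
  genes <- as_tibble(genes)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(genes))) {
    abort("gene table needs columns gene, chrom, start, end")
  }
  if (!"category" %in% names(genes)) genes$category <- "other"
  genes$chrom <- normalize_chrom(genes$chrom)
  if (any(genes$start < 1) || any(genes$end < genes$start)) {
    abort("intervals must satisfy 1 <= start <= end")
  }
  genes |>
    arrange(.data$gene, .data$chrom, .data$start) |>
    group_by(.data$gene, .data$chrom, .data$category) |>
    mutate(.grp = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -1L) + 1L)) |>
    group_by(.data$gene, .data$chrom, .data$category, .data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select(-".grp") |>
    arrange(.data$gene, .data$chrom, .data$start)
}

.gene_lengths <- function(genes) {
  genes |>
    group_by(.data$gene, .data$category) |>
    summarise(cds_length = sum(.data$end - .data$start + 1L), .groups = "drop")
}

#' Count array variants per gene
#'
#' A variant counts for every gene whose merged CDS intervals contain its
#' position; a variant inside two overlapping genes counts for both.
#' Genes with no variants report zero.
#'
#' @param manifest An `array_manifest`.
#' @param genes A gene/CDS table (see [merge_gene_intervals()]).
#' @return A tibble `gene, category, n_variants`, one row per gene.
#' @export
count_gene_variants <- function(manifest, genes) {
  genes <- merge_gene_intervals(genes)
  hits <- inner_join(
    as_tibble(manifest)[c("chrom", "pos")], genes,
    by = join_by("chrom", between("pos", "start", "end"))
  )
  genes |>
    distinct(.data$gene, .data$category) |>
    left_join(count(hits, .data$gene, name = "n_variants"), by = "gene") |>
    mutate(n_variants = dplyr::coalesce(.data$n_variants, 0L)) |>
    arrange(.data$gene)
}

#' Count proxy-deleterious variants in a gene set
#'
#' A manifest variant is *proxy-deleterious* when its CADD phred score is
#' strictly greater than `threshold` (20 approximates the top 1% most
#' damaging variants genome-wide) and it falls inside one of the genes.
#' Variants are counted per gene, so one falling in two overlapping genes
#' appears twice in the per-gene counts; `total_distinct` counts each
#' variant once.
#'
#' @param manifest An `array_manifest`.
#' @param genes A gene/CDS table, e.g. the medically actionable gene list.
#' @param cadd A data frame `chrom, pos, ref, alt, cadd_phred` keyed by
#'   full allele identity.
#' @param threshold CADD phred cut-off (strict), default 20.
#' @return A list of class `proxy_deleterious`: `per_gene` (tibble
#'   `gene, n_deleterious` over every input gene, zeros included),
#'   `total`, `total_distinct`, `median`, `iqr` (length-2 vector).
#' @export
count_proxy_deleterious <- function(manifest, genes, cadd, threshold = 20) {
  cadd <- as_tibble(cadd)
  need <- c("chrom", "pos", "ref", "alt", "cadd_phred")
  if (!all(need %in% names(cadd))) {
    abort("CADD table needs columns chrom, pos, ref, alt, cadd_phred")
  }
  cadd$chrom <- normalize_chrom(cadd$chrom)
  dam <- as_tibble(manifest) |>
    inner_join(cadd, by = c("chrom", "pos", "ref", "alt")) |>
    filter(.data$cadd_phred > threshold)
  merged <- merge_gene_intervals(genes)
  hits <- inner_join(
    dam[c("chrom", "pos", "ref", "alt")], merged,
    by = join_by("chrom", between("pos", "start", "end"))
  )
  per_gene <- merged |>
    distinct(.data$gene) |>
    left_join(count(hits, .data$gene, name = "n_deleterious"), by = "gene") |>
    mutate(n_deleterious = dplyr::coalesce(.data$n_deleterious, 0L)) |>
    arrange(.data$gene)
  structure(
    list(
      per_gene = per_gene,
      total = sum(per_gene$n_deleterious),
      total_distinct = nrow(distinct(hits, .data$chrom, .data$pos, .data$ref, .data$alt)),
      median = median(per_gene$n_deleterious),
      iqr = unname(quantile(per_gene$n_deleterious, c(0.25, 0.75)))
    ),
    class = "proxy_deleterious"
  )
}

#' @export
print.proxy_deleterious <- function(x, ...) {
  cat(sprintf(
    "<proxy_deleterious> total %d (distinct %d) over %d genes; median %.1f, IQR [%.1f, %.1f]\n",
    x$total, x$total_distinct, nrow(x$per_gene), x$median, x$iqr[1], x$iqr[2]
  ))
  invisible(x)
}

#' @export
tidy.proxy_deleterious <- function(x, ...) x$per_gene

#' @export
glance.proxy_deleterious <- function(x, ...) {
  tibble(
    n_genes = nrow(x$per_gene), total = x$total,
    total_distinct = x$total_distinct, median = x$median,
    iqr_lower = x$iqr[1], iqr_upper = x$iqr[2]
  )
}

.star_cols <- c("gene", "allele", "ancestry", "chrom", "pos", "ref", "alt")

.star_check <- function(alleles) {
  alleles <- as_tibble(alleles)
  if (!all(c("gene", "allele") %in% names(alleles))) {
    abort("star-allele table needs `gene` and `allele` columns")
  }
  if (!"ancestry" %in% names(alleles)) alleles$ancestry <- "all"
  if (!"cnv_based" %in% names(alleles)) alleles$cnv_based <- FALSE
  if ("chrom" %in% names(alleles)) alleles$chrom <- normalize_chrom(alleles$chrom)
  alleles
}

#' Star-allele identifiability on an array
#'
#' A star allele (a named pharmacogene or HLA haplotype) is *callable*
#' only when its entire defining tag-SNV set is assayable: every tag must
#' be on the manifest (position and alleles matching after
#' normalisation), or -- when an imputed callset is supplied -- either on
#' the manifest or imputed with R-squared strictly above `r2_min`. One
#' missing tag makes the allele not callable. Alleles with no tag SNVs
#' (e.g. whole-gene deletion/duplication alleles, which require CNV
#' analysis) are not evaluable.
#'
#' @param alleles A star-allele definition table, one row per tag SNV:
#'   `gene, allele, ancestry, chrom, pos, ref, alt`, optional logical
#'   `cnv_based`. Rows with `NA` positions (or `cnv_based = TRUE`) mark
#'   alleles that cannot be evaluated from tag SNVs.
#' @param manifest An `array_manifest`.
#' @param imputed Optional data frame `chrom, pos, ref, alt, r2`; when
#'   given, tags imputable at high quality also count.
#' @param r2_min High-quality imputation threshold (strict), default 0.8.
#' @param match_alleles Require ref/alt identity in addition to position,
#'   default `TRUE`.
#' @return A tibble `gene, allele, ancestry, n_tags, n_present, status`
#'   with `status` in `callable, not_callable, not_evaluable`.
#' @export
star_allele_status <- function(alleles, manifest, imputed = NULL,
                               r2_min = 0.8, match_alleles = TRUE) {
  alleles <- .star_check(alleles)
  mk <- if (match_alleles) {
    paste(manifest$chrom, manifest$pos, manifest$ref, manifest$alt)
  } else {
    paste(manifest$chrom, manifest$pos)
  }
  ik <- character(0)
  if (!is.null(imputed) && nrow(as_tibble(imputed)) > 0) {
    imputed <- as_tibble(imputed)
    hi <- imputed[imputed$r2 > r2_min, ]
    ik <- if (match_alleles) {
      paste(normalize_chrom(hi$chrom), hi$pos, toupper(hi$ref), toupper(hi$alt))
    } else {
      paste(normalize_chrom(hi$chrom), hi$pos)
    }
  }
  alleles |>
    mutate(
      .evaluable = !.data$cnv_based & !is.na(.data$pos),
      .key = if (match_alleles) {
        paste(.data$chrom, .data$pos, toupper(.data$ref), toupper(.data$alt))
      } else {
        paste(.data$chrom, .data$pos)
      },
      .present = .data$.evaluable & (.data$.key %in% mk | .data$.key %in% ik)
    ) |>
    group_by(.data$gene, .data$allele, .data$ancestry) |>
    summarise(
      n_tags = sum(.data$.evaluable),
      n_present = sum(.data$.present),
      status = if (all(!.data$.evaluable)) "not_evaluable"
               else if (all(.data$.present[.data$.evaluable])) "callable"
               else "not_callable",
      .groups = "drop"
    )
}

#' @rdname star_allele_status
#' @details `star_allele_callable()` is the single-allele form: it takes
#'   the tag rows of one allele and returns just the status string.
#' @export
star_allele_callable <- function(alleles, manifest, imputed = NULL,
                                 r2_min = 0.8, match_alleles = TRUE) {
  st <- star_allele_status(alleles, manifest, imputed = imputed,
                           r2_min = r2_min, match_alleles = match_alleles)
  if (nrow(st) != 1) abort("`star_allele_callable()` expects the tag rows of exactly one allele")
  st$status
}

#' Percentage of callable star alleles per gene
#'
#' @inheritParams star_allele_status
#' @return A tibble `gene, ancestry, n_evaluable, n_callable,
#'   pct_callable` (percentage, `NA` when no allele is evaluable).
#' @export
percent_star_alleles <- function(alleles, manifest, imputed = NULL,
                                 r2_min = 0.8, match_alleles = TRUE) {
  star_allele_status(alleles, manifest, imputed = imputed,
                     r2_min = r2_min, match_alleles = match_alleles) |>
    group_by(.data$gene, .data$ancestry) |>
    summarise(
      n_evaluable = sum(.data$status != "not_evaluable"),
      n_callable = sum(.data$status == "callable"),
      pct_callable = if (sum(.data$status != "not_evaluable") > 0) {
        100 * sum(.data$status == "callable") / sum(.data$status != "not_evaluable")
      } else NA_real_,
      .groups = "drop"
    )
}

#' HLA star-allele identifiability per gene and ancestry
#'
#' HLA tag-SNV sets are ancestry-specific, so the callable percentage is
#' computed separately per ancestry, then summarised per gene as the mean
#' and SD across ancestries.
#'
#' @inheritParams star_allele_status
#' @param ancestries Ancestry labels expected in the table, default
#'   `c("EUR", "ASN", "AFR")`; missing gene-by-ancestry combinations are
#'   reported with a warning and left `NA`.
#' @return A list of class `hla_coverage`: `by_ancestry` (tibble `gene,
#'   ancestry, n_evaluable, n_callable, pct_callable`) and `per_gene`
#'   (tibble `gene, mean_pct, sd_pct`).
#' @export
hla_percent_by_ancestry <- function(alleles, manifest, imputed = NULL,
                                    r2_min = 0.8, match_alleles = TRUE,
                                    ancestries = c("EUR", "ASN", "AFR")) {
  alleles <- .star_check(alleles)
  bad <- setdiff(unique(alleles$ancestry), ancestries)
  if (length(bad) > 0) {
    abort(sprintf("unexpected ancestry label(s): %s", paste(bad, collapse = ", ")))
  }
  by_anc <- percent_star_alleles(alleles, manifest, imputed = imputed,
                                 r2_min = r2_min, match_alleles = match_alleles)
  full <- tidyr::expand_grid(gene = unique(alleles$gene), ancestry = ancestries) |>
    left_join(by_anc, by = c("gene", "ancestry"))
  missing_cells <- sum(is.na(full$pct_callable) & is.na(full$n_evaluable))
  if (missing_cells > 0) {
    warn(sprintf("%d gene-by-ancestry cell(s) have no defined alleles; left NA",
                 missing_cells))
  }
  per_gene <- full |>
    group_by(.data$gene) |>
    summarise(
      mean_pct = mean(.data$pct_callable, na.rm = TRUE),
      sd_pct = sd(.data$pct_callable, na.rm = TRUE),
      .groups = "drop"
    )
  structure(list(by_ancestry = full, per_gene = per_gene),
            class = "hla_coverage")
}

#' @export
print.hla_coverage <- function(x, ...) {
  cat("<hla_coverage> per-gene mean/SD of callable percentage across ancestries\n")
  print(x$per_gene)
  invisible(x)
}

#' @export
tidy.hla_coverage <- function(x, ...) x$by_ancestry

#' @export
glance.hla_coverage <- function(x, ...) {
  tibble(n_genes = nrow(x$per_gene),
         mean_pct = mean(x$per_gene$mean_pct, na.rm = TRUE))
}

#' Tally mitochondrial variants per functional locus
#'
#' Mitochondrial loci (genes plus other features such as binding sites)
#' overlap, so a variant counts in every locus containing it; the total
#' counts each distinct MT variant once.
#'
#' @param manifest An `array_manifest`.
#' @param loci A data frame `locus, start, end` (1-based inclusive on the
#'   mitochondrial genome, 16,569 bp).
#' @return A list of class `mtdna_tally`: `per_locus` (tibble
#'   `locus, start, end, n_variants`) and `total` (distinct MT variants).
#' @export
mtdna_tally <- function(manifest, loci) {
  loci <- as_tibble(loci)
  if (!all(c("locus", "start", "end") %in% names(loci))) {
    abort("locus table needs columns locus, start, end")
  }
  mt_len <- 16569L
  if (any(loci$start < 1L) || any(loci$end > mt_len) || any(loci$end < loci$start)) {
    abort("loci must satisfy 1 <= start <= end <= 16569")
  }
  mt <- as_tibble(manifest) |>
    filter(.data$chrom == "MT", .data$probe_class != "cnv_intensity")
  hits <- inner_join(mt[c("pos")], loci,
                     by = join_by(between("pos", "start", "end")))
  per_locus <- loci |>
    left_join(count(hits, .data$locus, name = "n_variants"), by = "locus") |>
    mutate(n_variants = dplyr::coalesce(.data$n_variants, 0L))
  structure(
    list(per_locus = per_locus,
         total = nrow(distinct(mt, .data$pos, .data$ref, .data$alt))),
    class = "mtdna_tally"
  )
}

#' @export
print.mtdna_tally <- function(x, ...) {
  cat(sprintf("<mtdna_tally> %d distinct MT variants over %d loci\n",
              x$total, nrow(x$per_locus)))
  invisible(x)
}

#' @export
tidy.mtdna_tally <- function(x, ...) x$per_locus

#' Mean inter-SNV distance within coding sequence
#'
#' For each gene, the total CDS length is divided by the number of array
#' SNVs falling inside the CDS plus one, giving the mean distance between
#' variants within the gene. With no SNVs the distance equals the CDS
#' length; it decreases toward 1 bp as the CDS saturates.
#'
#' @param manifest An `array_manifest`.
#' @param genes A gene/CDS table.
#' @return A tibble `gene, cds_length, n_snvs, mean_distance` satisfying
#'   `mean_distance * (n_snvs + 1) == cds_length` exactly.
#' @export
cds_density <- function(manifest, genes) {
  merged <- merge_gene_intervals(genes)
  lens <- .gene_lengths(merged)
  if (any(lens$cds_length <= 0)) abort("every gene must have positive CDS length")
  snvs <- as_tibble(manifest) |> filter(.data$probe_class == "snv")
  hits <- inner_join(snvs[c("chrom", "pos")], merged,
                     by = join_by("chrom", between("pos", "start", "end")))
  lens |>
    left_join(count(hits, .data$gene, name = "n_snvs"), by = "gene") |>
    mutate(
      n_snvs = dplyr::coalesce(.data$n_snvs, 0L),
      mean_distance = .data$cds_length / (.data$n_snvs + 1)
    ) |>
    select("gene", "cds_length", "n_snvs", "mean_distance") |>
    arrange(.data$gene)
}

#' SNV density in fixed genomic windows
#'
#' Counts array SNVs in non-overlapping windows of `window_bp` anchored
#' at position 1 on each chromosome, and summarises the density as the
#' mean and SD over all windows of the given chromosomes (empty windows
#' included). Variants on chromosomes absent from `chrom_lengths` are
#' dropped with a message; a variant beyond its stated chromosome length
#' is an error.
#'
#' @param manifest An `array_manifest`.
#' @param window_bp Window size in bp (e.g. 1e3 or 1e6).
#' @param chrom_lengths A data frame `chrom, length`.
#' @return A list of class `window_density`: `windows` (tibble `chrom,
#'   window_start, n`), `mean`, `sd`, `n_windows`, `n_variants` (mapped
#'   variants; equals `sum(windows$n)`).
#' @export
window_density <- function(manifest, window_bp, chrom_lengths) {
  chrom_lengths <- as_tibble(chrom_lengths)
  if (!all(c("chrom", "length") %in% names(chrom_lengths))) {
    abort("`chrom_lengths` needs columns chrom, length")
  }
  chrom_lengths$chrom <- normalize_chrom(chrom_lengths$chrom)
  if (window_bp < 1) abort("`window_bp` must be at least 1")
  v <- as_tibble(manifest) |>
    filter(.data$probe_class == "snv") |>
    select("chrom", "pos")
  unmapped <- !v$chrom %in% chrom_lengths$chrom
  if (any(unmapped)) {
    inform(sprintf("dropping %d variant(s) on chromosomes without a stated length",
                   sum(unmapped)))
    v <- v[!unmapped, ]
  }
  v <- left_join(v, chrom_lengths, by = "chrom")
  if (any(v$pos > v$length)) {
    abort("variant position beyond stated chromosome length")
  }
  grid <- chrom_lengths |>
    rowwise() |>
    reframe(chrom = .data$chrom,
            window_start = seq(1L, .data$length, by = as.integer(window_bp)))
  counts <- v |>
    mutate(window_start = ((.data$pos - 1L) %/% as.integer(window_bp)) *
             as.integer(window_bp) + 1L) |>
    count(.data$chrom, .data$window_start, name = "n")
  windows <- grid |>
    left_join(counts, by = c("chrom", "window_start")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(
    list(
      windows = windows,
      mean = mean(windows$n),
      sd = if (nrow(windows) > 1) sd(windows$n) else 0,
      n_windows = nrow(windows),
      n_variants = sum(windows$n)
    ),
    class = "window_density"
  )
}

#' @export
print.window_density <- function(x, ...) {
  cat(sprintf(
    "<window_density> %d variants in %d windows; mean %.3f, SD %.3f\n",
    x$n_variants, x$n_windows, x$mean, x$sd
  ))
  invisible(x)
}

#' @export
tidy.window_density <- function(x, ...) x$windows

#' @export
glance.window_density <- function(x, ...) {
  tibble(n_windows = x$n_windows, n_variants = x$n_variants,
         mean = x$mean, sd = x$sd)
}
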