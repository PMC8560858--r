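#' Construct an array manifest from a data frame
#'
#' An array manifest is a tibble of the variants/probes an array assays,
#' one row per probe, with attributes recording the array's short name and
#' genome build. Chromosome labels are normalised (see [normalize_chrom()]),
#' positions are 1-based, and duplicate `(chrom, pos, ref, alt)` rows are
#' collapsed to the first occurrence with a warning.
#'
#' @param x A data frame with columns `chrom` and `pos`; optional columns
#'   `ref`, `alt` (allele strings, `NA` for intensity-only probes),
#'   `probe_class` (`"snv"`, `"indel"` or `"cnv_intensity"`; inferred from
#'   allele lengths when absent) and `functional` (`"exonic"`,
#'   `"splice_site"` or `"other"`; defaults to `"other"`).
#' @param name Non-empty array short name.
#' @param genome_build Genome build label, default `"hg19"`.
#' @return A tibble of class `array_manifest` with columns
#'   `chrom, pos, ref, alt, probe_class, functional`.
#' @examples
#' as_manifest(data.frame(chrom = "1", pos = c(100, 200),
#'                        ref = "A", alt = "G"), name = "toy")
#' @export
as_manifest <- function(x, name, genome_build = "hg19") {
  if (missing(name) || !is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string")
  }
  x <- as_tibble(x)
  if (!all(c("chrom", "pos") %in% names(x))) {
    abort("manifest input needs at least `chrom` and `pos` columns")
  }
  x$chrom <- normalize_chrom(x$chrom)
  .check_chrom(x$chrom, context = sprintf("manifest '%s'", name))
  x$pos <- as.integer(x$pos)
  if (any(is.na(x$pos)) || any(x$pos < 1L)) {
    abort("`pos` must be a positive 1-based integer for every variant")
  }
  for (col in c("ref", "alt")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
    x[[col]] <- toupper(as.character(x[[col]]))
    x[[col]][x[[col]] %in% c("", ".", "-", "NA")] <- NA_character_
  }
  if (!"probe_class" %in% names(x)) {
    x$probe_class <- dplyr::case_when(
      is.na(x$ref) | is.na(x$alt) ~ "cnv_intensity",
      nchar(x$ref) == 1L & nchar(x$alt) == 1L ~ "snv",
      .default = "indel"
    )
  }
  bad_class <- setdiff(unique(x$probe_class), c("snv", "indel", "cnv_intensity"))
  if (length(bad_class) > 0) {
    abort(sprintf("unknown probe_class value(s): %s", paste(bad_class, collapse = ", ")))
  }
  # intensity-only probes carry no alleles
  x$ref[x$probe_class == "cnv_intensity"] <- NA_character_
  x$alt[x$probe_class == "cnv_intensity"] <- NA_character_
  if (!"functional" %in% names(x)) x$functional <- "other"
  x$functional[is.na(x$functional)] <- "other"
  bad_fun <- setdiff(unique(x$functional), c("exonic", "splice_site", "other"))
  if (length(bad_fun) > 0) {
    abort(sprintf("unknown functional value(s): %s", paste(bad_fun, collapse = ", ")))
  }
  x <- x[c("chrom", "pos", "ref", "alt", "probe_class", "functional")]

  dup <- duplicated(x[c("chrom", "pos", "ref", "alt")])
  if (any(dup)) {
    warn(sprintf(
      "manifest '%s': collapsed %d duplicated (chrom, pos, ref, alt) record(s), keeping first occurrence",
      name, sum(dup)
    ))
    x <- x[!dup, ]
  }
  new_manifest(x, name = name, genome_build = genome_build)
}

new_manifest <- function(x, name, genome_build) {
  structure(
    x,
    class = c("array_manifest", class(tibble())),
    array_name = name,
    genome_build = genome_build
  )
}

#' @export
print.array_manifest <- function(x, ...) {
  cat(sprintf(
    "<array_manifest> %s (%s): %d variants\n",
    attr(x, "array_name"), attr(x, "genome_build"), nrow(x)
  ))
  NextMethod()
}

#' Array name and genome build of a manifest
#' @param m An `array_manifest`.
#' @return A string.
#' @export
array_name <- function(m) attr(m, "array_name") %||% "array"

#' @rdname array_name
#' @export
genome_build <- function(m) attr(m, "genome_build") %||% "hg19"

#' Read an array manifest from BED or CSV
#'
#' BED input is 0-based half-open and converted to 1-based positions on
#' read; CSV input is 1-based. The BED dialect is
#' `chrom, start, end[, ref, alt, probe_class, functional]` (tab-separated,
#' no header); the CSV dialect has a header with at least
#' `chrom, pos` and optionally `ref, alt, probe_class, functional`.
#' Lines that fail to parse raise an error naming the line number.
#'
#' @param path File path.
#' @param name Array short name; defaults to the file stem.
#' @param format `"bed"` or `"csv"`.
#' @param genome_build Genome build label, default `"hg19"`.
#' @return An [as_manifest()] tibble.
#' @export
read_manifest <- function(path, name = NULL,
                          format = c("bed", "csv"),
                          genome_build = "hg19") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("manifest file not found: %s", path))
  name <- name %||% sub("\\.[^.]*$", "", basename(path))

  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(#|track|browser)", lines)]
    if (length(lines) == 0) abort(sprintf("no records in %s", path))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 3L)
    if (length(bad) > 0) {
      abort(sprintf("cannot parse BED line %d of %s: fewer than 3 fields", bad[1], path))
    }
    start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    if (anyNA(start)) {
      abort(sprintf("cannot parse BED line %d of %s: non-integer start",
                    which(is.na(start))[1], path))
    }
    get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
    df <- tibble(
      chrom = get(1L),
      pos = start + 1L,  # BED is 0-based half-open
      ref = get(4L),
      alt = get(5L),
      probe_class = get(6L),
      functional = get(7L)
    )
    if (all(is.na(df$probe_class))) df$probe_class <- NULL
    if (all(is.na(df$functional))) df$functional <- NULL
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("chrom", "pos") %in% names(df))) {
      abort(sprintf("CSV manifest %s needs `chrom` and `pos` columns", path))
    }
    pos_num <- suppressWarnings(as.numeric(df$pos))
    if (anyNA(pos_num)) {
      abort(sprintf("cannot parse CSV line %d of %s: non-numeric pos",
                    which(is.na(pos_num))[1] + 1L, path))
    }
  }
  as_manifest(df, name = name, genome_build = genome_build)
}

#' Write an array manifest to BED or CSV
#'
#' BED output converts the internal 1-based positions back to 0-based
#' half-open intervals, so `read_manifest()` round-trips exactly.
#'
#' @param m An `array_manifest`.
#' @param path Output file path.
#' @param format `"bed"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path, format = c("bed", "csv")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- tibble(
      chrom = m$chrom,
      start = m$pos - 1L,
      end = m$pos,
      ref = ifelse(is.na(m$ref), ".", m$ref),
      alt = ifelse(is.na(m$alt), ".", m$alt),
      probe_class = m$probe_class,
      functional = m$functional
    )
    readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  } else {
    readr::write_csv(as_tibble(m), path, progress = FALSE)
  }
  invisible(path)
}

#' Summarise array content
#'
#' Counts the probes of an array the way vendor comparison tables do:
#' total content, then autosomal / X / Y / mitochondrial SNV+indel probes,
#' intensity-only (CNV) probes, and exonic / splice-site variants from the
#' functional annotation.
#'
#' @param m An `array_manifest`.
#' @return A one-row tibble: `array, total, autosomal, x, y, mt, cnv,
#'   exonic, splice_site`.
#' @export
summarize_content <- function(m) {
  if (nrow(m) == 0) abort("manifest is empty")
  genotyped <- m$probe_class != "cnv_intensity"
  tibble(
    array = array_name(m),
    total = nrow(m),
    autosomal = sum(genotyped & m$chrom %in% .AUTOSOMES),
    x = sum(genotyped & m$chrom == "X"),
    y = sum(genotyped & m$chrom == "Y"),
    mt = sum(genotyped & m$chrom == "MT"),
    cnv = sum(!genotyped),
    exonic = sum(m$functional == "exonic"),
    splice_site = sum(m$functional == "splice_site")
  )
}

#' Pairwise overlap between arrays
#'
#' Overlap is counted on distinct `(chrom, pos)` pairs -- alleles are
#' ignored -- so two arrays assaying the same site with different probe
#' chemistries still count as shared content. With `strict_alleles = TRUE`
#' matching additionally requires identical `ref`/`alt`.
#'
#' @param manifests A list of `array_manifest` objects (all on the same
#'   genome build).
#' @param strict_alleles Match on `(chrom, pos, ref, alt)` instead of
#'   position only. Default `FALSE`.
#' @return An `overlap_matrix`: a symmetric integer matrix with array names
#'   as dimnames; the diagonal holds each array's distinct-key count.
#' @export
overlap_matrix <- function(manifests, strict_alleles = FALSE) {
  if (length(manifests) < 1) abort("need at least one manifest")
  builds <- unique(vapply(manifests, genome_build, ""))
  if (length(builds) > 1) {
    abort(sprintf("mixed genome builds: %s", paste(builds, collapse = ", ")))
  }
  nms <- vapply(manifests, array_name, "")
  keys <- lapply(manifests, function(m) {
    if (strict_alleles) {
      unique(paste(m$chrom, m$pos, m$ref, m$alt, sep = ":"))
    } else {
      unique(paste(m$chrom, m$pos, sep = ":"))
    }
  })
  k <- length(keys)
  counts <- matrix(0L, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    counts[i, i] <- length(keys[[i]])
    if (i < k) for (j in seq((i + 1L), k)) {
      n <- length(intersect(keys[[i]], keys[[j]]))
      counts[i, j] <- n
      counts[j, i] <- n
    }
  }
  structure(counts, class = c("overlap_matrix", class(counts)))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix> shared (chrom, pos) counts\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
tidy.overlap_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.table(m), .name_repair = "minimal") |>
    setNames(c("array_a", "array_b", "shared")) |>
    mutate(shared = as.integer(.data$shared))
}

#' Attach functional annotation to a manifest
#'
#' Sets the `functional` field from an annotation table keyed by full
#' allele identity `(chrom, pos, ref, alt)`; variants without a matching
#' key are classed `"other"`. The annotation itself (e.g. an
#' Annovar-style pipeline) is an input, not something this package runs.
#'
#' @param m An `array_manifest`.
#' @param annotation A data frame with columns
#'   `chrom, pos, ref, alt, functional`.
#' @return The manifest with `functional` updated.
#' @export
classify_functional <- function(m, annotation) {
  ann <- as_tibble(annotation)
  need <- c("chrom", "pos", "ref", "alt", "functional")
  if (!all(need %in% names(ann))) {
    abort(sprintf("annotation needs columns: %s", paste(need, collapse = ", ")))
  }
  ann$chrom <- normalize_chrom(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  ann <- ann |>
    mutate(ref = toupper(.data$ref), alt = toupper(.data$alt)) |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE)
  out <- as_tibble(m) |>
    left_join(ann |> select(dplyr::all_of(need)) |> rename(.fun_new = "functional"),
              by = c("chrom", "pos", "ref", "alt")) |>
    mutate(functional = dplyr::coalesce(.data$.fun_new, "other")) |>
    select(-".fun_new")
  new_manifest(out, name = array_name(m), genome_build = genome_build(m))
}
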