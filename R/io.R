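#' Read an ENCODE narrowPeak file into a peak tibble
#'
#' Parses the 10-column narrowPeak format emitted by MACS2 and similar peak
#' callers. The peak score used throughout this package is the -log10(p-value)
#' column (column 8), not the integer display score in column 5. Coordinates
#' are kept 0-based, half-open as in the file.
#'
#' @param path Path to a narrowPeak file (plain or gzip; `.gz` detected by
#'   suffix).
#' @param sample_id Sample label attached to every peak; defaults to the file
#'   name without extension.
#' @param drop_chrY Drop chromosome Y records at parse time (default `TRUE`;
#'   genomic comparisons in this workflow exclude chrY).
#' @return A tibble with one row per peak: `chrom`, `start`, `end`, `name`,
#'   `display_score` (column 5), `strand`, `signal`, `score` (-log10 p),
#'   `qvalue`, `summit` (absolute position) and `sample_id`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t1000\t1501\tp1\t0\t.\t5\t40\t35\t250", f)
#' read_narrowpeak(f, sample_id = "s1")
read_narrowpeak <- function(path, sample_id = NULL, drop_chrY = TRUE) {
  lines <- read_text_lines(path)
  sample_id <- sample_id %||% sub("\\.(narrowPeak|bed)(\\.gz)?$", "", basename(path))
  if (length(lines) == 0L) {
    return(empty_peaks(sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 10L)
  if (length(bad) > 0L) {
    abort(sprintf("narrowPeak format error in '%s': line %d has %d column(s), need >= 10",
                  path, bad[1], nf[bad[1]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:10))
  peaks <- tibble(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    name = m[, 4],
    display_score = as.numeric(m[, 5]),
    strand = m[, 6],
    signal = as.numeric(m[, 7]),
    score = as.numeric(m[, 8]),
    qvalue = as.numeric(m[, 9]),
    summit_offset = as.integer(m[, 10])
  )
  bad_num <- which(is.na(peaks$start) | is.na(peaks$end) | is.na(peaks$score))
  if (length(bad_num) > 0L) {
    abort(sprintf("narrowPeak format error in '%s': non-numeric field on line %d",
                  path, bad_num[1]))
  }
  bad_iv <- which(peaks$end <= peaks$start)
  if (length(bad_iv) > 0L) {
    abort(sprintf("narrowPeak validation error in '%s': end <= start on line %d",
                  path, bad_iv[1]))
  }
  no_summit <- which(peaks$summit_offset < 0L)
  if (length(no_summit) > 0L) {
    abort(sprintf(
      "narrowPeak validation error in '%s': summit offset -1 on line %d (a summit is required for fixed-width conversion)",
      path, no_summit[1]))
  }
  if (any(peaks$score < 0)) {
    abort(sprintf("narrowPeak validation error in '%s': negative -log10(p) score", path))
  }
  peaks <- peaks |>
    mutate(summit = .data$start + .data$summit_offset, sample_id = sample_id) |>
    select(-"summit_offset")
  if (drop_chrY) {
    peaks <- filter(peaks, !.data$chrom %in% c("chrY", "Y"))
  }
  peaks
}

empty_peaks <- function(sample_id = character(0)) {
  tibble(
    chrom = character(0), start = integer(0), end = integer(0),
    name = character(0), display_score = numeric(0), strand = character(0),
    signal = numeric(0), score = numeric(0), qvalue = numeric(0),
    summit = integer(0),
    sample_id = if (length(sample_id)) character(0) else character(0)
  )
}

#' Write a peak tibble as ENCODE narrowPeak
#'
#' Inverse of [read_narrowpeak()]: emits the 10 narrowPeak columns. Missing
#' optional columns are filled with narrowPeak conventions (`.` strand, `-1`
#' q-value). Numeric fields are rendered canonically (no scientific notation,
#' no trailing zeros), so reading and re-writing a canonically formatted file
#' reproduces it byte for byte.
#'
#' @param peaks A peak tibble with at least `chrom`, `start`, `end`, `score`
#'   and `summit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  check_interval_df(peaks, "peak table")
  n <- nrow(peaks)
  get_or <- function(col, default) {
    if (col %in% names(peaks)) peaks[[col]] else rep(default, n)
  }
  lines <- paste(
    peaks$chrom,
    peaks$start,
    peaks$end,
    get_or("name", "."),
    format_bed_num(get_or("display_score", 0)),
    get_or("strand", "."),
    format_bed_num(get_or("signal", 0)),
    format_bed_num(peaks$score),
    format_bed_num(get_or("qvalue", -1)),
    peaks$summit - peaks$start,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a fragment BED file
#'
#' Reads BED3-or-more records describing sequenced inserts (one fragment per
#' Tn5-cut pair). Fragment length is derived as `end - start`.
#'
#' @inheritParams read_narrowpeak
#' @return A tibble with `chrom`, `start`, `end`, `length`.
#' @export
read_fragments <- function(path, drop_chrY = TRUE) {
  lines <- read_text_lines(path)
  if (length(lines) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  length = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("fragment BED format error in '%s': line %d has %d column(s), need >= 3",
                  path, bad[1], nf[bad[1]]))
  }
  frags <- tibble(
    chrom = vapply(fields, `[`, character(1), 1L),
    start = as.integer(vapply(fields, `[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[`, character(1), 3L))
  )
  bad_iv <- which(is.na(frags$start) | is.na(frags$end) | frags$end <= frags$start)
  if (length(bad_iv) > 0L) {
    abort(sprintf("fragment validation error in '%s': end <= start (or non-numeric) on line %d",
                  path, bad_iv[1]))
  }
  if (drop_chrY) {
    frags <- filter(frags, !.data$chrom %in% c("chrY", "Y"))
  }
  mutate(frags, length = .data$end - .data$start)
}

#' Read one of the pipeline's typed tables
#'
#' A single entry point over the tabular inputs the workflow consumes. All TSV
#' kinds require a header row; the blacklist is headerless BED3+.
#'
#' @param path File path (plain or gzip).
#' @param kind One of `"tss"` (columns gene_id, chrom, pos, strand),
#'   `"features"` (chrom, start, end, label), `"blacklist"` (BED3+),
#'   `"counts"` (id, then one column per sample), `"motifs"` (motif_id,
#'   tf_gene, p_value, fdr), `"expression"` (gene_id, then one column per
#'   sample).
#' @param drop_chrY Drop chromosome Y records for the genomic kinds.
#' @return A validated tibble typed for `kind`.
#' @export
read_atac_table <- function(path,
                            kind = c("tss", "features", "blacklist", "counts",
                                     "motifs", "expression"),
                            drop_chrY = TRUE) {
  kind <- match.arg(kind)
  switch(kind,
    tss = read_tss(path, drop_chrY = drop_chrY),
    features = read_features(path, drop_chrY = drop_chrY),
    blacklist = read_blacklist(path, drop_chrY = drop_chrY),
    counts = read_counts(path),
    motifs = read_motifs(path),
    expression = read_expression(path)
  )
}

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_atac_table
#' @export
read_tss <- function(path, drop_chrY = TRUE) {
  tss <- read_tsv_quiet(path)
  required <- c("gene_id", "chrom", "pos", "strand")
  if (!all(required %in% names(tss))) {
    abort(sprintf("TSS table '%s' must have header columns: %s",
                  path, paste(required, collapse = ", ")))
  }
  tss <- as_tibble(tss[required])
  if (any(tss$pos < 0)) abort("TSS validation error: negative position")
  if (!all(tss$strand %in% c("+", "-"))) {
    abort("TSS validation error: strand must be '+' or '-'")
  }
  if (drop_chrY) tss <- filter(tss, !.data$chrom %in% c("chrY", "Y"))
  tss
}

#' @rdname read_atac_table
#' @export
read_features <- function(path, drop_chrY = TRUE) {
  feats <- read_tsv_quiet(path)
  required <- c("chrom", "start", "end", "label")
  if (!all(required %in% names(feats))) {
    abort(sprintf("feature table '%s' must have header columns: %s",
                  path, paste(required, collapse = ", ")))
  }
  feats <- as_tibble(feats[required])
  unknown <- setdiff(unique(feats$label), FEATURE_LEVELS)
  if (length(unknown) > 0L) {
    abort(sprintf("feature validation error: unknown label(s) %s (allowed: %s)",
                  paste(unknown, collapse = ", "),
                  paste(FEATURE_LEVELS, collapse = ", ")))
  }
  check_interval_df(feats, "feature table")
  if (drop_chrY) feats <- filter(feats, !.data$chrom %in% c("chrY", "Y"))
  feats
}

#' @rdname read_atac_table
#' @export
read_blacklist <- function(path, drop_chrY = TRUE) {
  lines <- read_text_lines(path)
  if (length(lines) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("blacklist BED format error in '%s': line %d has < 3 columns",
                  path, bad[1]))
  }
  bl <- tibble(
    chrom = vapply(fields, `[`, character(1), 1L),
    start = as.integer(vapply(fields, `[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[`, character(1), 3L))
  )
  check_interval_df(bl, "blacklist")
  if (drop_chrY) bl <- filter(bl, !.data$chrom %in% c("chrY", "Y"))
  bl
}

#' @rdname read_atac_table
#' @export
read_counts <- function(path) {
  counts <- read_tsv_quiet(path)
  if (ncol(counts) < 2L) {
    abort(sprintf("counts table '%s' needs an id column plus >= 1 sample column", path))
  }
  names(counts)[1] <- "id"
  if (anyDuplicated(counts$id)) {
    abort(sprintf("counts validation error in '%s': duplicated row id(s): %s",
                  path, paste(head(unique(counts$id[duplicated(counts$id)]), 3), collapse = ", ")))
  }
  if (any(vapply(counts[-1], function(x) any(x < 0), logical(1)))) {
    abort("counts validation error: negative counts")
  }
  as_tibble(counts)
}

#' @rdname read_atac_table
#' @export
read_motifs <- function(path) {
  motifs <- read_tsv_quiet(path)
  required <- c("motif_id", "tf_gene", "p_value", "fdr")
  if (!all(required %in% names(motifs))) {
    abort(sprintf("motif table '%s' must have header columns: %s",
                  path, paste(required, collapse = ", ")))
  }
  motifs <- as_tibble(motifs[required])
  if (any(motifs$fdr < 0 | motifs$fdr > 1, na.rm = TRUE)) {
    abort("motif validation error: fdr outside [0, 1]")
  }
  motifs
}

#' @rdname read_atac_table
#' @export
read_expression <- function(path) {
  expr <- read_tsv_quiet(path)
  if (ncol(expr) < 2L) {
    abort(sprintf("expression table '%s' needs gene_id plus >= 1 sample column", path))
  }
  names(expr)[1] <- "gene_id"
  if (anyDuplicated(expr$gene_id)) {
    abort(sprintf("expression validation error in '%s': duplicated gene id(s)", path))
  }
  as_tibble(expr)
}

# Read all lines of a plain or gzip text file (suffix-detected), skipping
# browser/track header lines and blank lines.
read_text_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
}
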