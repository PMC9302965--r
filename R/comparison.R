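#' Classify merged consensus peaks as shared or set-specific
#'
#' Given a merged consensus set carrying contributed-by provenance (see
#' [merge_consensus_sets()]), labels each peak `shared` when both input sets
#' contributed an overlapping peak, otherwise `a_only` / `b_only` for the sole
#' contributor, and computes the percentage accounting of the merged set.
#'
#' @param merged A tibble with a `sources` list-column of contributing set
#'   labels (an `atac_merged` object, or any tibble of the same shape).
#' @param set_labels Character vector of the two set labels, `c(a, b)`.
#'   Defaults to the attribute recorded by [merge_consensus_sets()].
#' @return An object of class `atac_comparison`: a list with `peaks` (the
#'   input plus a `category` column) and `summary` (tibble with `category`,
#'   `n`, `pct`). Counts partition the merged set; percentages sum to 100.
#' @export
classify_peaks <- function(merged, set_labels = NULL) {
  if (!"sources" %in% names(merged)) {
    abort("classify_peaks: merged set lacks 'sources' provenance (use merge_consensus_sets)")
  }
  set_labels <- set_labels %||% attr(merged, "set_labels")
  if (is.null(set_labels)) {
    set_labels <- sort(unique(unlist(merged$sources)))
  }
  if (length(set_labels) != 2L) {
    abort("classify_peaks: exactly two set labels are required")
  }
  a <- set_labels[1]
  b <- set_labels[2]
  src <- merged$sources
  if (any(lengths(src) == 0L)) {
    abort("classify_peaks: peak with empty provenance")
  }
  unknown <- setdiff(unique(unlist(src)), set_labels)
  if (length(unknown) > 0L) {
    abort(sprintf("classify_peaks: provenance label(s) not in set_labels: %s",
                  paste(unknown, collapse = ", ")))
  }
  has_a <- vapply(src, function(s) a %in% s, logical(1))
  has_b <- vapply(src, function(s) b %in% s, logical(1))
  category <- ifelse(has_a & has_b, "shared", ifelse(has_a, "a_only", "b_only"))
  peaks <- mutate(as_tibble(unclass_tbl(merged)),
                  category = factor(category, levels = c("shared", "a_only", "b_only")))
  total <- nrow(peaks)
  counts <- table(peaks$category)
  summary <- tibble(
    category = factor(names(counts), levels = c("shared", "a_only", "b_only")),
    n = as.integer(counts),
    pct = round(100 * as.integer(counts) / total, 2)
  )
  structure(
    list(peaks = peaks, summary = summary, total = total, set_labels = set_labels),
    class = "atac_comparison"
  )
}

#' @export
print.atac_comparison <- function(x, ...) {
  cat(sprintf("Peak-set comparison: %s vs %s (%d merged peaks)\n",
              x$set_labels[1], x$set_labels[2], x$total))
  print(x$summary)
  invisible(x)
}

#' @rdname classify_peaks
#' @param x An `atac_comparison` object.
#' @param ... Unused.
#' @method tidy atac_comparison
#' @export
tidy.atac_comparison <- function(x, ...) {
  x$summary
}

#' @rdname classify_peaks
#' @method glance atac_comparison
#' @export
glance.atac_comparison <- function(x, ...) {
  s <- x$summary
  tibble(
    total = x$total,
    shared = s$n[s$category == "shared"],
    a_only = s$n[s$category == "a_only"],
    b_only = s$n[s$category == "b_only"],
    pct_shared = s$pct[s$category == "shared"],
    pct_a_only = s$pct[s$category == "a_only"],
    pct_b_only = s$pct[s$category == "b_only"]
  )
}

#' Assign genomic-feature context under the 40% overlap rule
#'
#' An interval is considered to overlap a genomic feature when at least
#' `min_frac` of the interval falls within a single feature record. When
#' several labels qualify the highest-precedence one wins
#' (promoter > 5'UTR > 3'UTR > exon > intron); intervals qualifying for no
#' feature are `distal`.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`) — typically
#'   fragments or peaks.
#' @param features Feature tibble (`chrom`, `start`, `end`, `label`) with
#'   labels from the fixed vocabulary.
#' @param min_frac Minimal overlap fraction of the interval's own length
#'   (default 0.4).
#' @return `intervals` with an added `feature` factor column.
#' @export
annotate_features <- function(intervals, features, min_frac = 0.4) {
  check_interval_df(intervals, "interval table")
  lab <- rep("distal", nrow(intervals))
  if (nrow(intervals) > 0L && nrow(features) > 0L) {
    unknown <- setdiff(unique(features$label), FEATURE_LEVELS)
    if (length(unknown) > 0L) {
      abort(sprintf("annotate_features: unknown feature label(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    gr_i <- as_granges0(intervals)
    gr_f <- as_granges0(features)
    hits <- GenomicRanges::findOverlaps(gr_i, gr_f)
    if (length(hits) > 0L) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      inter <- GenomicRanges::width(IRanges::pintersect(gr_i[qi], gr_f[si]))
      len <- intervals$end[qi] - intervals$start[qi]
      ok <- inter >= min_frac * len
      if (any(ok)) {
        prec <- match(features$label[si[ok]], FEATURE_LEVELS)
        best <- tapply(prec, qi[ok], min)
        lab[as.integer(names(best))] <- FEATURE_LEVELS[as.integer(best)]
      }
    }
  }
  mutate(intervals, feature = factor(lab, levels = FEATURE_LEVELS))
}

#' Peak shape metrics from fragment coverage
#'
#' Computes per-bp fragment coverage within one peak window: `summit_height`
#' is the maximum coverage, and `base_width` is the length of the maximal
#' contiguous run of positions containing the coverage maximum with coverage
#' at least half the summit height (width at half maximum). Sharper peaks —
#' e.g. from libraries richer in sub-nucleosomal fragments — have narrower
#' bases.
#'
#' @param fragments Fragment tibble.
#' @param peak A single-row peak tibble (`chrom`, `start`, `end`).
#' @return A tibble with `summit_height` and `base_width`.
#' @export
shape_metrics <- function(fragments, peak) {
  if (nrow(peak) != 1L) abort("shape_metrics: exactly one peak expected")
  check_interval_df(peak, "peak")
  cov <- peak_coverage(fragments, peak)
  if (max(cov) == 0) {
    abort("shape_metrics: no fragment overlaps the peak")
  }
  height <- max(cov)
  apex <- which.max(cov)
  above <- cov >= height / 2
  left <- apex
  while (left > 1L && above[left - 1L]) left <- left - 1L
  right <- apex
  while (right < length(above) && above[right + 1L]) right <- right + 1L
  tibble(summit_height = height, base_width = right - left + 1L)
}

peak_coverage <- function(fragments, peak) {
  width <- peak$end - peak$start
  if (nrow(fragments) == 0L) return(rep(0, width))
  frags <- filter(fragments, .data$chrom == peak$chrom,
                  .data$start < peak$end, .data$end > peak$start)
  if (nrow(frags) == 0L) return(rep(0, width))
  ir <- IRanges::IRanges(
    start = pmax(frags$start, peak$start) - peak$start + 1L,
    end = pmin(frags$end, peak$end) - peak$start
  )
  as.numeric(IRanges::coverage(ir, width = width))
}

#' Euclidean distance between samples from peak counts
#'
#' Distances over per-sample count vectors of a peak-by-sample table; used for
#' unsupervised clustering of libraries (replicates of the same condition
#' should be mutual nearest neighbours regardless of sequencing platform).
#'
#' @param counts Tibble with a peak `id` column followed by one numeric column
#'   per sample.
#' @param log_scale Apply `log2(x + 1)` before computing distances (default
#'   `FALSE`).
#' @return A symmetric numeric matrix with zero diagonal, sample names on both
#'   dimensions.
#' @export
sample_distance_matrix <- function(counts, log_scale = FALSE) {
  if (ncol(counts) < 3L) abort("sample_distance_matrix: need >= 2 sample columns")
  ids <- counts[[1]]
  if (anyDuplicated(ids)) abort("sample_distance_matrix: duplicated peak ids")
  mat <- as.matrix(counts[-1])
  if (any(mat < 0)) abort("sample_distance_matrix: counts must be non-negative")
  if (log_scale) mat <- log2(mat + 1)
  as.matrix(dist(t(mat)))
}

#' Rank peaks by log2 fold-change of mean CPM
#'
#' A simple library-size-normalized fold-change ranking (no dispersion
#' modelling, no p-values): per-peak
#' `log2((mean CPM in a + c) / (mean CPM in b + c))` with pseudocount `c = 1`,
#' sorted descending so the top rows are most accessible in `a`.
#'
#' @param counts_a,counts_b Count tibbles over the same peak universe (id
#'   column first, then one column per sample).
#' @param pseudocount Stabilising constant added to mean CPM (default 1).
#' @return A tibble with `id`, `mean_cpm_a`, `mean_cpm_b`, `lfc`, ordered by
#'   descending `lfc`.
#' @export
differential_rank <- function(counts_a, counts_b, pseudocount = 1) {
  cpm_mean <- function(counts) {
    mat <- as.matrix(counts[-1])
    totals <- colSums(mat)
    if (any(totals <= 0)) abort("differential_rank: sample with zero total counts")
    cpm <- sweep(mat, 2, totals / 1e6, "/")
    tibble(id = counts[[1]], mean_cpm = rowMeans(cpm))
  }
  a <- cpm_mean(counts_a)
  b <- cpm_mean(counts_b)
  if (!setequal(a$id, b$id) || anyDuplicated(a$id) || anyDuplicated(b$id)) {
    abort("differential_rank: peak ids must match one-to-one between the tables")
  }
  a |>
    inner_join(b, by = "id", suffix = c("_a", "_b")) |>
    mutate(lfc = log2((.data$mean_cpm_a + pseudocount) / (.data$mean_cpm_b + pseudocount))) |>
    arrange(desc(.data$lfc))
}
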