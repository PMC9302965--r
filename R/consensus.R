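#' Parameters of the consensus peak workflow
#'
#' Defaults reproduce the published workflow: summits extended by 250 bp per
#' side to a fixed width of 501 bp; reproducible peaks require a
#' score-per-million >= 3 observed in at least two samples with a minimal
#' overlap of 50% of the fixed width.
#'
#' @param extension Summit extension per side (bp).
#' @param min_spm Minimum score-per-million a supporting sample's peak must
#'   reach.
#' @param min_samples Minimum number of qualifying samples.
#' @param min_overlap_frac Minimal overlap between a survivor and a supporting
#'   peak, as a fraction of the fixed width.
#' @return A list of class `consensus_params` (includes the derived `width`).
#' @export
consensus_params <- function(extension = 250, min_spm = 3, min_samples = 2,
                             min_overlap_frac = 0.5) {
  if (min_overlap_frac <= 0 || min_overlap_frac > 1) {
    abort("consensus_params: min_overlap_frac must be in (0, 1]")
  }
  if (min_samples < 1) abort("consensus_params: min_samples must be >= 1")
  structure(
    list(extension = extension, width = 2L * as.integer(extension) + 1L,
         min_spm = min_spm, min_samples = min_samples,
         min_overlap_frac = min_overlap_frac),
    class = "consensus_params"
  )
}

#' Convert called peaks to fixed-width summit-centred peaks
#'
#' Each peak is replaced by the interval `[summit - extension,
#' summit + extension + 1)`, i.e. a fixed width of `2 * extension + 1` bp
#' centred on the summit. Peaks whose window would cross a chromosome boundary
#' are dropped (a count is reported), preserving the fixed-width invariant the
#' later 50%-overlap arithmetic relies on.
#'
#' @param peaks Peak tibble with a `summit` column.
#' @param chrom_sizes Tibble with `chrom` and `length` (bp).
#' @param extension Extension per side (bp, default 250 giving 501 bp peaks).
#' @return A peak tibble with fixed-width `start`/`end`.
#' @export
to_fixed_width <- function(peaks, chrom_sizes, extension = 250) {
  if (nrow(peaks) == 0L) return(peaks)
  if (!"summit" %in% names(peaks) || anyNA(peaks$summit)) {
    abort("to_fixed_width: every peak needs a summit")
  }
  sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  unknown <- setdiff(unique(peaks$chrom), names(sizes))
  if (length(unknown) > 0L) {
    abort(sprintf("to_fixed_width: chromosome size unknown for %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- peaks |>
    mutate(start = as.integer(.data$summit - extension),
           end = as.integer(.data$summit + extension + 1L))
  keep <- out$start >= 0L & out$end <= sizes[out$chrom]
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    inform(sprintf("to_fixed_width: dropped %d peak(s) crossing a chromosome boundary", n_drop))
  }
  out[keep, , drop = FALSE]
}

#' Remove peaks overlapping blacklisted regions
#'
#' Drops any peak intersecting a blacklist interval by >= 1 bp.
#'
#' @param peaks Peak tibble.
#' @param blacklist Interval tibble (`chrom`, `start`, `end`).
#' @return The filtered peak tibble.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (nrow(peaks) == 0L || nrow(blacklist) == 0L) return(peaks)
  check_interval_df(blacklist, "blacklist")
  peaks[!overlaps_any0(peaks, blacklist), , drop = FALSE]
}

#' Iterative removal of overlapping peaks
#'
#' Greedy resolution of overlapping peaks by significance: the most
#' significant remaining peak is kept and every peak overlapping it (>= 1 bp)
#' is discarded; this repeats until no overlaps remain. Equal scores are
#' broken deterministically by (chrom, start, sample_id), smallest kept. The
#' result is pairwise non-overlapping and the operation is idempotent.
#'
#' @param peaks Peak tibble.
#' @param score_col Column used as the significance score (default `"score"`;
#'   use `"spm"` for pooled cross-sample removal).
#' @return The surviving peaks, in genomic order.
#' @export
iterative_removal <- function(peaks, score_col = "score") {
  if (nrow(peaks) <= 1L) return(peaks)
  if (!score_col %in% names(peaks)) {
    abort(sprintf("iterative_removal: no '%s' column", score_col))
  }
  score <- peaks[[score_col]]
  sample_id <- if ("sample_id" %in% names(peaks)) peaks$sample_id else rep("", nrow(peaks))
  ord <- order(-score, peaks$chrom, peaks$start, sample_id)

  gr <- as_granges0(peaks)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  nbr <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  alive <- rep(TRUE, nrow(peaks))
  kept <- logical(nrow(peaks))
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    ni <- nbr[[as.character(i)]]
    if (!is.null(ni)) alive[ni] <- FALSE
  }
  out <- peaks[kept, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Score-per-million normalization
#'
#' Converts raw -log10(p-value) peak scores to score-per-million (SPM) values
#' by dividing each score by the sample's total score divided by one million;
#' the SPM values of a sample therefore sum to exactly 1e6. SPM corrects peak
#' scores for sequencing depth and overall sample quality so that scores are
#' comparable across replicates.
#'
#' @param x Either a numeric score vector, or a peak tibble (SPM is computed
#'   per `sample_id` when that column is present and added as an `spm`
#'   column).
#' @param score_col Score column when `x` is a tibble.
#' @return Same shape as the input: a numeric vector, or the tibble with an
#'   `spm` column.
#' @export
#' @examples
#' spm_normalize(c(10, 30, 60))
spm_normalize <- function(x, score_col = "score") {
  if (is.numeric(x)) {
    return(spm_values(x))
  }
  if (!score_col %in% names(x)) {
    abort(sprintf("spm_normalize: no '%s' column", score_col))
  }
  if ("sample_id" %in% names(x)) {
    x |>
      group_by(.data$sample_id) |>
      mutate(spm = spm_values(.data[[score_col]])) |>
      ungroup()
  } else {
    mutate(x, spm = spm_values(.data[[score_col]]))
  }
}

spm_values <- function(scores) {
  if (any(scores < 0)) abort("spm_normalize: scores must be >= 0")
  total <- sum(scores)
  if (total <= 0) abort("spm_normalize: sum of scores must be > 0")
  scores / (total / 1e6)
}

#' Consensus of reproducible peaks across replicates
#'
#' Implements the two-step consensus construction: all per-sample fixed-width,
#' SPM-normalized peak sets are pooled and overlapping peaks are resolved by
#' iterative removal so only the peak with the highest SPM survives at each
#' locus. A survivor is retained only if peaks with SPM >= `min_spm` from at
#' least `min_samples` distinct samples overlap it by at least
#' `min_overlap_frac` of the fixed width (the survivor itself counts when it
#' qualifies).
#'
#' @param samples A list of per-sample peak tibbles (each fixed-width,
#'   blacklist-filtered, internally non-overlapping, with `spm` and
#'   `sample_id` columns), or a single long tibble carrying `sample_id`.
#' @param params A [consensus_params()].
#' @param label Optional label for the resulting set (e.g. cell type x
#'   platform).
#' @return A tibble of class `atac_consensus`: non-overlapping fixed-width
#'   peaks with `spm` (the maximal supporting SPM) and `support` (number of
#'   qualifying samples). Parameters and label are attached as attributes.
#' @export
replicate_consensus <- function(samples, params = consensus_params(), label = NULL) {
  pooled <- if (is.data.frame(samples)) as_tibble(samples) else bind_rows(samples)
  if (!all(c("spm", "sample_id") %in% names(pooled))) {
    abort("replicate_consensus: peaks need 'spm' and 'sample_id' columns (run spm_normalize first)")
  }
  n_samples <- length(unique(pooled$sample_id))
  if (n_samples < params$min_samples) {
    abort(sprintf(
      "replicate_consensus: %d sample(s) supplied but reproducibility requires min_samples = %d",
      n_samples, params$min_samples))
  }
  survivors <- iterative_removal(pooled, score_col = "spm")
  min_bp <- as.integer(ceiling(params$min_overlap_frac * params$width))
  qualifying <- pooled[pooled$spm >= params$min_spm, , drop = FALSE]
  support <- count_supporting_samples(survivors, qualifying, min_bp)
  out <- survivors |>
    mutate(support = support) |>
    filter(.data$support >= params$min_samples)
  structure(out, class = c("atac_consensus", class(out)),
            params = params, label = label)
}

count_supporting_samples <- function(survivors, qualifying, min_bp) {
  if (nrow(survivors) == 0L || nrow(qualifying) == 0L) {
    return(integer(nrow(survivors)))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(survivors), as_granges0(qualifying),
                                      minoverlap = min_bp)
  sup <- integer(nrow(survivors))
  if (length(hits) > 0L) {
    by_q <- tapply(qualifying$sample_id[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits),
                   function(s) length(unique(s)))
    sup[as.integer(names(by_q))] <- as.integer(by_q)
  }
  sup
}

#' Merge consensus peak sets across platforms or conditions
#'
#' Re-normalizes the SPM vector of each input set to sum to 1e6 (so that no
#' set dominates through depth or quality), pools all sets, and applies
#' iterative removal by re-normalized SPM. Each surviving peak records which
#' input sets contributed a peak overlapping it by at least
#' `min_overlap_frac` of the fixed width, enabling shared / set-specific
#' classification downstream.
#'
#' @param sets A named list of consensus peak tibbles (names are the set
#'   labels, e.g. platforms), each internally non-overlapping with an `spm`
#'   column.
#' @param params A [consensus_params()].
#' @return A tibble of class `atac_merged` with `set_label` (the surviving
#'   peak's origin), `sources` (list-column of contributing set labels) and
#'   `n_sources`. The vector of set labels is attached as an attribute.
#' @export
merge_consensus_sets <- function(sets, params = consensus_params()) {
  if (length(sets) < 2L) abort("merge_consensus_sets: need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  empty <- vapply(sets, function(s) nrow(s) == 0L, logical(1))
  if (any(empty)) {
    abort(sprintf("merge_consensus_sets: empty input set '%s'",
                  names(sets)[which(empty)[1]]))
  }
  pooled <- imap(sets, function(s, lab) {
    s <- as_tibble(s)
    s$spm <- spm_values(s$spm)  # re-normalization
    s$set_label <- lab
    s
  })
  pooled <- bind_rows(pooled)
  survivors <- iterative_removal(pooled, score_col = "spm")
  min_bp <- as.integer(ceiling(params$min_overlap_frac * params$width))
  hits <- GenomicRanges::findOverlaps(as_granges0(survivors), as_granges0(pooled),
                                      minoverlap = min_bp)
  sources <- vector("list", nrow(survivors))
  for (i in seq_len(nrow(survivors))) sources[[i]] <- character(0)
  if (length(hits) > 0L) {
    by_q <- split(pooled$set_label[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
    for (q in names(by_q)) sources[[as.integer(q)]] <- sort(unique(by_q[[q]]))
  }
  out <- survivors |>
    mutate(sources = sources, n_sources = lengths(sources))
  structure(out, class = c("atac_merged", class(out)),
            params = params, set_labels = names(sets))
}

#' @rdname replicate_consensus
#' @param x An `atac_consensus` object.
#' @param ... Unused.
#' @method tidy atac_consensus
#' @export
tidy.atac_consensus <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' @rdname replicate_consensus
#' @method glance atac_consensus
#' @export
glance.atac_consensus <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    label = attr(x, "label") %||% NA_character_,
    n_peaks = nrow(x),
    width = p$width,
    min_spm = p$min_spm,
    min_samples = p$min_samples,
    mean_spm = mean(x$spm),
    mean_support = mean(x$support)
  )
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("atac_consensus", "atac_merged"))
  x
}
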