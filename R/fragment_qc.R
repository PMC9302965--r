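#' Nucleosomal size-class scheme
#'
#' Boundaries of the canonical ATAC-seq insert-size classes: nucleosome-free /
#' sub-nucleosomal fragments are shorter than 147 bp (the DNA wrapped by one
#' nucleosome), mono-nucleosomal fragments span 180-247 bp and di-nucleosomal
#' fragments 315-473 bp. Lengths in the gaps (147-179, 248-314, > 473 bp) are
#' an explicit `other` class so that the reported proportions always
#' partition.
#'
#' @param sub_max Exclusive upper bound of the sub-nucleosomal class (bp).
#' @param mono_lo,mono_hi Inclusive bounds of the mono-nucleosomal class (bp).
#' @param di_lo,di_hi Inclusive bounds of the di-nucleosomal class (bp).
#' @return A named list of class `size_class_scheme`.
#' @export
size_class_scheme <- function(sub_max = 147, mono_lo = 180, mono_hi = 247,
                              di_lo = 315, di_hi = 473) {
  if (!(sub_max <= mono_lo && mono_lo <= mono_hi && mono_hi < di_lo && di_lo <= di_hi)) {
    abort("size_class_scheme: need sub_max <= mono_lo <= mono_hi < di_lo <= di_hi")
  }
  structure(
    list(sub_max = sub_max, mono_lo = mono_lo, mono_hi = mono_hi,
         di_lo = di_lo, di_hi = di_hi),
    class = "size_class_scheme"
  )
}

#' Classify fragment lengths into nucleosomal size classes
#'
#' @param length Vector of fragment lengths (bp, >= 1).
#' @param scheme A [size_class_scheme()].
#' @return A factor with levels `sub`, `mono`, `di`, `other`.
#' @export
#' @examples
#' classify_fragment_length(c(100, 200, 400, 150))
classify_fragment_length <- function(length, scheme = size_class_scheme()) {
  if (any(length <= 0)) {
    abort("classify_fragment_length: lengths must be >= 1")
  }
  cls <- rep("other", length(length))
  cls[length < scheme$sub_max] <- "sub"
  cls[length >= scheme$mono_lo & length <= scheme$mono_hi] <- "mono"
  cls[length >= scheme$di_lo & length <= scheme$di_hi] <- "di"
  factor(cls, levels = SIZE_CLASSES)
}

#' Fragment size distribution and class proportions
#'
#' @param fragments A fragment tibble (needs a `length` column, or `start`/
#'   `end` from which lengths are derived).
#' @param scheme A [size_class_scheme()].
#' @return A list with `histogram` (tibble: `length`, `n`) and `proportions`
#'   (tibble: `class`, `n`, `proportion`; proportions sum to 1).
#' @export
size_distribution <- function(fragments, scheme = size_class_scheme()) {
  len <- fragment_lengths(fragments)
  if (length(len) == 0L) {
    abort("size_distribution: needs at least one fragment")
  }
  cls <- classify_fragment_length(len, scheme)
  histogram <- tibble(length = len) |>
    count(.data$length, name = "n") |>
    arrange(.data$length)
  tab <- table(cls)
  proportions <- tibble(
    class = factor(SIZE_CLASSES, levels = SIZE_CLASSES),
    n = as.integer(tab[SIZE_CLASSES]),
    proportion = as.numeric(tab[SIZE_CLASSES]) / length(len)
  )
  list(histogram = histogram, proportions = proportions)
}

fragment_lengths <- function(fragments) {
  if ("length" %in% names(fragments)) {
    fragments$length
  } else {
    check_interval_df(fragments, "fragment table")
    fragments$end - fragments$start
  }
}

#' Fraction of fragments overlapping transcription start sites (FROT)
#'
#' Signal-to-background QC metric: the fraction of fragments whose interval
#' intersects any TSS +/- `window` region by at least 1 bp.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`).
#' @param tss TSS tibble (`gene_id`, `chrom`, `pos`, `strand`).
#' @param window Half-width of the TSS window (bp, default 1000).
#' @return A single fraction in `[0, 1]`.
#' @export
frot <- function(fragments, tss, window = 1000) {
  check_interval_df(fragments, "fragment table")
  if (nrow(fragments) == 0L) abort("frot: needs at least one fragment")
  if (nrow(tss) == 0L) {
    warn("frot: empty TSS set, returning 0")
    return(0)
  }
  mean(overlaps_any0(fragments, tss_windows0(tss, window)))
}

#' Mean fragment coverage profile around transcription start sites
#'
#' Computes the strand-oriented mean per-bin fragment coverage in TSS windows
#' of +/- `window` bp, binned at `bin` bp. Minus-strand windows are reversed so
#' upstream is always on the left.
#'
#' @inheritParams frot
#' @param bin Bin width in bp; `window` must be divisible by `bin`.
#' @return A tibble with `bin_start` (position of the bin's left edge relative
#'   to the TSS) and `coverage` (mean per-bp fragment coverage in the bin,
#'   averaged over TSS windows); `2 * window / bin` rows.
#' @export
tss_profile <- function(fragments, tss, window = 1000, bin = 10) {
  if (window %% bin != 0) abort("tss_profile: window must be divisible by bin")
  n_bins <- as.integer(2 * window / bin)
  rel <- seq(-window, window - bin, by = bin)
  if (nrow(tss) == 0L) {
    return(tibble(bin_start = rel, coverage = rep(0, n_bins)))
  }
  total <- rep(0, 2 * window)
  if (nrow(fragments) > 0L) {
    check_interval_df(fragments, "fragment table")
    gr <- as_granges0(fragments)
    cov <- GenomicRanges::coverage(gr)
    for (i in seq_len(nrow(tss))) {
      chrom <- tss$chrom[i]
      if (!chrom %in% names(cov)) next
      rle <- cov[[chrom]]
      # 1-based window over positions pos-window .. pos+window-1 (0-based)
      s1 <- tss$pos[i] - window + 1L
      e1 <- tss$pos[i] + window
      v <- rep(0, 2 * window)
      lo <- max(1L, s1)
      hi <- min(length(rle), e1)
      if (hi >= lo) {
        v[(lo - s1 + 1L):(hi - s1 + 1L)] <- as.numeric(rle[lo:hi])
      }
      if (tss$strand[i] == "-") v <- rev(v)
      total <- total + v
    }
  }
  per_bp <- total / nrow(tss)
  coverage <- colMeans(matrix(per_bp, nrow = bin))
  tibble(bin_start = rel, coverage = coverage)
}

#' Fraction of fragments in peaks (FRiP), split by TSS proximity
#'
#' Peaks are first labelled proximal (overlapping any TSS +/- `window` by >= 1
#' bp) or distal. Each fragment is then assigned to exactly one category,
#' checking proximal peaks first: `tss_peaks`, `distal_peaks`, or
#' `not_in_peaks`. The three fractions sum to 1.
#'
#' @inheritParams frot
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @return A tibble with `category`, `n`, `fraction`.
#' @export
frip <- function(fragments, peaks, tss, window = 1000) {
  check_interval_df(fragments, "fragment table")
  check_interval_df(peaks, "peak table")
  if (nrow(peaks) == 0L) abort("frip: peak set must be non-empty")
  wins <- tss_windows0(tss, window)
  proximal <- overlaps_any0(peaks, wins)
  in_prox <- overlaps_any0(fragments, peaks[proximal, , drop = FALSE])
  in_dist <- !in_prox & overlaps_any0(fragments, peaks[!proximal, , drop = FALSE])
  n_total <- nrow(fragments)
  counts <- c(
    tss_peaks = sum(in_prox),
    distal_peaks = sum(in_dist),
    not_in_peaks = n_total - sum(in_prox) - sum(in_dist)
  )
  tibble(
    category = factor(names(counts), levels = names(counts)),
    n = as.integer(counts),
    fraction = as.numeric(counts) / n_total
  )
}

#' Count fragments in non-overlapping peaks
#'
#' @inheritParams frip
#' @param peaks Consensus peak tibble; must be pairwise non-overlapping.
#' @return `peaks` with an added `count` column (fragments intersecting the
#'   peak by >= 1 bp).
#' @export
count_in_peaks <- function(fragments, peaks) {
  check_interval_df(peaks, "peak table")
  gr_p <- as_granges0(peaks)
  if (nrow(peaks) > 1L) {
    self <- GenomicRanges::findOverlaps(gr_p, drop.self = TRUE)
    if (length(self) > 0L) {
      abort("count_in_peaks: peaks overlap each other, fragment assignment would be ambiguous")
    }
  }
  if (nrow(fragments) == 0L) {
    return(mutate(peaks, count = 0L))
  }
  check_interval_df(fragments, "fragment table")
  mutate(peaks, count = GenomicRanges::countOverlaps(gr_p, as_granges0(fragments)))
}

#' Down-sample fragments to a fixed depth
#'
#' Uniform random subset of exactly `n` fragments, reproducible for a fixed
#' seed. Mirrors depth equalisation before cross-library comparison.
#'
#' @param fragments Fragment tibble.
#' @param n Target number of fragments (`0 <= n <= nrow(fragments)`).
#' @param seed Integer seed.
#' @return A fragment tibble with `n` rows.
#' @export
subsample_fragments <- function(fragments, n, seed) {
  if (n > nrow(fragments)) {
    abort(sprintf("subsample_fragments: n (%d) exceeds available fragments (%d)",
                  n, nrow(fragments)))
  }
  if (n < 0) abort("subsample_fragments: n must be >= 0")
  idx <- with_seed(seed, sample.int(nrow(fragments), n))
  fragments[sort(idx), , drop = FALSE]
}

#' One-stop library QC report
#'
#' Bundles fragment count, size-class proportions, FROT, FRiP and the TSS
#' enrichment profile for one library.
#'
#' @inheritParams frip
#' @param scheme A [size_class_scheme()].
#' @param bin Bin width for the TSS profile (bp).
#' @return An object of class `atac_qc`: a list with elements `n_fragments`,
#'   `class_proportions`, `frot`, `frip` and `tss_profile`.
#' @export
qc_report <- function(fragments, peaks, tss, window = 1000, bin = 10,
                      scheme = size_class_scheme()) {
  structure(
    list(
      n_fragments = nrow(fragments),
      class_proportions = size_distribution(fragments, scheme)$proportions,
      frot = frot(fragments, tss, window),
      frip = frip(fragments, peaks, tss, window),
      tss_profile = tss_profile(fragments, tss, window, bin)
    ),
    class = "atac_qc"
  )
}

#' @export
print.atac_qc <- function(x, ...) {
  cat("ATAC library QC report\n")
  cat(sprintf("  fragments: %d\n", x$n_fragments))
  cat(sprintf("  FROT: %.4f\n", x$frot))
  cat("  size classes:",
      paste(sprintf("%s=%.3f", x$class_proportions$class, x$class_proportions$proportion),
            collapse = " "), "\n")
  cat("  FRiP:",
      paste(sprintf("%s=%.3f", x$frip$category, x$frip$fraction), collapse = " "), "\n")
  invisible(x)
}

#' @rdname qc_report
#' @param x An `atac_qc` object.
#' @param ... Unused.
#' @method glance atac_qc
#' @export
glance.atac_qc <- function(x, ...) {
  prop <- setNames(x$class_proportions$proportion, paste0("prop_", x$class_proportions$class))
  fr <- setNames(x$frip$fraction, paste0("frip_", x$frip$category))
  as_tibble(c(list(n_fragments = x$n_fragments, frot = x$frot),
              as.list(prop), as.list(fr)))
}
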