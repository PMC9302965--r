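# Independent oracles and small builders shared across tests.

# Naive iterative-removal oracle: literal repeated scan — find the most
# significant remaining peak, keep it, discard everything overlapping it,
# rescan. Same tie-break contract as the implementation, nothing shared with
# it.
oracle_iterative_removal <- function(peaks, score_col = "score") {
  kept <- peaks[0, , drop = FALSE]
  remaining <- peaks
  while (nrow(remaining) > 0) {
    sid <- if ("sample_id" %in% names(remaining)) remaining$sample_id else rep("", nrow(remaining))
    ord <- order(-remaining[[score_col]], remaining$chrom, remaining$start, sid)
    best <- remaining[ord[1], , drop = FALSE]
    kept <- rbind(kept, best)
    overlaps <- remaining$chrom == best$chrom &
      remaining$start < best$end & remaining$end > best$start
    remaining <- remaining[!overlaps, , drop = FALSE]
  }
  kept[order(kept$chrom, kept$start), , drop = FALSE]
}

# Brute-force Poisson upper-tail: direct summation of the mass function.
oracle_poisson_tail <- function(k, lambda, jmax = 200) {
  sum(exp(-lambda) * lambda^(k:jmax) / factorial(k:jmax))
}

# Random small peak instances for oracle comparisons (ties included on
# purpose to exercise the deterministic tie-break).
random_peak_instance <- function(n, seed) {
  withr::with_seed(seed, {
    start <- sample(0:1200, n, replace = TRUE)
    width <- sample(50:500, n, replace = TRUE)
    tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = start,
      end = start + width,
      score = sample(1:6, n, replace = TRUE) / 2,
      sample_id = sample(letters[1:3], n, replace = TRUE)
    )
  })
}

# A fixed-width peak row for consensus tests.
peak_row <- function(chrom, start, spm, sample_id, width = 501L) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(start + width),
    summit = as.integer(start + width %/% 2L),
    score = spm, spm = spm, sample_id = sample_id
  )
}

# Merged-set stand-in with explicit provenance, for classify_peaks tests:
# builds `n` rows per category at distinct loci.
merged_with_provenance <- function(n_shared, n_a_only, n_b_only,
                                   labels = c("a", "b")) {
  n <- n_shared + n_a_only + n_b_only
  sources <- c(
    rep(list(labels), n_shared),
    rep(list(labels[1]), n_a_only),
    rep(list(labels[2]), n_b_only)
  )
  out <- tibble::tibble(
    chrom = "chr1",
    start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 501L,
    spm = 10,
    sources = sources,
    n_sources = lengths(sources)
  )
  attr(out, "set_labels") <- labels
  out
}

# Small, fast simulator configuration for functional tests.
tiny_config <- function(...) {
  defaults <- list(
    genome = tibble::tibble(chrom = c("chr1", "chr2"), length = c(1e6, 1e6)),
    n_regions = 60, depth = 8000, n_replicates = 2, seed = 11
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
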