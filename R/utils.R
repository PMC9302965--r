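# Internal helpers shared across modules. All public coordinates in this
# package are 0-based, half-open (BED native); GRanges used internally are
# 1-based closed, so conversion happens only inside these two functions.

as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# TSS +/- window as 0-based half-open intervals covering positions
# pos - window .. pos + window inclusive.
tss_windows0 <- function(tss, window) {
  tibble(
    chrom = tss$chrom,
    start = pmax(tss$pos - window, 0),
    end = tss$pos + window + 1
  )
}

# Logical: does each interval in `x` overlap any interval in `y` by >= 1 bp?
overlaps_any0 <- function(x, y) {
  if (nrow(y) == 0L) {
    return(rep(FALSE, nrow(x)))
  }
  IRanges::overlapsAny(as_granges0(x), as_granges0(y))
}

check_interval_df <- function(df, what = "interval table") {
  required <- c("chrom", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s lacks column(s): %s", what, paste(missing, collapse = ", ")))
  }
  bad <- which(df$end <= df$start | df$start < 0)
  if (length(bad) > 0L) {
    abort(sprintf("%s has invalid interval(s) at row(s) %s (need 0 <= start < end)",
                  what, paste(head(bad, 5L), collapse = ", ")))
  }
  invisible(df)
}

# Deterministic seeded evaluation that never touches the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

# Canonical numeric rendering for BED-family output (no scientific notation,
# trailing zeros dropped; integers render without a decimal point).
format_bed_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("-1")
    format(v, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  }, character(1))
}
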