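#' High-confidence consensus peaks from per-sample peak calls
#'
#' Runs the full per-sample preparation and the replicate-reproducibility
#' consensus in one call: fixed-width summit extension, blacklist filtering,
#' within-sample iterative overlap removal, score-per-million normalization,
#' then [replicate_consensus()] across the samples.
#'
#' @param peak_sets Named list of per-sample peak tibbles (as returned by
#'   [read_narrowpeak()] or [simulate_peak_calls()]); names default to the
#'   `sample_id` column.
#' @param chrom_sizes Tibble with `chrom` and `length`.
#' @param blacklist Optional interval tibble of regions to exclude.
#' @param params A [consensus_params()].
#' @param label Label for the resulting consensus set.
#' @return An `atac_consensus` tibble (see [replicate_consensus()]), with a
#'   per-stage peak-count accounting attached as attribute `stage_counts`.
#' @export
build_consensus <- function(peak_sets, chrom_sizes, blacklist = NULL,
                            params = consensus_params(), label = NULL) {
  if (is.data.frame(peak_sets)) {
    peak_sets <- split(peak_sets, peak_sets$sample_id)
  }
  stage <- list()
  prepared <- imap(peak_sets, function(pk, nm) {
    if (!"sample_id" %in% names(pk)) pk$sample_id <- nm
    n0 <- nrow(pk)
    pk <- to_fixed_width(pk, chrom_sizes, extension = params$extension)
    n1 <- nrow(pk)
    if (!is.null(blacklist)) pk <- filter_blacklist(pk, blacklist)
    n2 <- nrow(pk)
    pk <- iterative_removal(pk, score_col = "score")
    n3 <- nrow(pk)
    stage[[nm]] <<- tibble(sample_id = nm, n_called = n0, n_fixed_width = n1,
                           n_blacklisted = n2, n_after_removal = n3)
    spm_normalize(pk, score_col = "score")
  })
  consensus <- replicate_consensus(prepared, params = params, label = label)
  attr(consensus, "stage_counts") <- bind_rows(stage)
  consensus
}
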