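#' Log2 counts-per-million transformation
#'
#' Per sample: `CPM = 1e6 * count / library size`, reported as
#' `log2(CPM + 1)`. The pseudocount of 1 keeps zero counts at exactly 0 and
#' makes the "robustly expressed" threshold of 2 log2CPM meaningful.
#'
#' @param counts Tibble with `gene_id` (or any id column first) followed by
#'   one numeric count column per sample.
#' @return A tibble of the same shape with log2CPM values.
#' @export
#' @examples
#' log2cpm(tibble::tibble(gene_id = c("a", "b"), s1 = c(1000, 999000)))
log2cpm <- function(counts) {
  if (ncol(counts) < 2L) abort("log2cpm: need an id column plus >= 1 sample column")
  mat <- as.matrix(counts[-1])
  if (any(mat < 0)) abort("log2cpm: negative counts")
  totals <- colSums(mat)
  if (any(totals <= 0)) abort("log2cpm: sample with zero library size")
  cpm <- sweep(mat, 2, totals / 1e6, "/")
  out <- as_tibble(log2(cpm + 1))
  bind_cols_id(counts[1], out)
}

bind_cols_id <- function(id_col, rest) {
  out <- as_tibble(c(as.list(id_col), as.list(rest)))
  out
}

#' Average per-replicate log2CPM into condition-level expression
#'
#' @param l2c A log2CPM tibble from [log2cpm()].
#' @param conditions Named character vector mapping sample column names to
#'   condition labels.
#' @return A tibble with the id column plus one column per condition
#'   (arithmetic mean of that condition's replicate log2CPM values).
#' @export
condition_means <- function(l2c, conditions) {
  samples <- names(l2c)[-1]
  missing <- setdiff(samples, names(conditions))
  if (length(missing) > 0L) {
    abort(sprintf("condition_means: no condition for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- l2c[1]
  for (cond in unique(conditions[samples])) {
    cols <- samples[conditions[samples] == cond]
    out[[cond]] <- rowMeans(as.matrix(l2c[cols]))
  }
  out
}

#' Collapse motif hits to one record per transcription factor
#'
#' Keeps, for each TF gene, the motif with the lowest enrichment FDR (ties by
#' motif id), preserving enrichment order among survivors and assigning
#' `enrichment_rank`. Records without a TF gene mapping are skipped with a
#' warning.
#'
#' @param motifs Motif tibble (`motif_id`, `tf_gene`, `fdr`, optionally
#'   `p_value`).
#' @return The non-redundant motif tibble with an `enrichment_rank` column.
#' @export
deduplicate_motifs <- function(motifs) {
  if (nrow(motifs) == 0L) {
    return(mutate(motifs, enrichment_rank = integer(0)))
  }
  unmapped <- is.na(motifs$tf_gene) | !nzchar(motifs$tf_gene)
  if (any(unmapped)) {
    warn(sprintf("deduplicate_motifs: skipped %d motif(s) without a TF gene mapping",
                 sum(unmapped)))
    motifs <- motifs[!unmapped, , drop = FALSE]
  }
  motifs |>
    arrange(.data$fdr, .data$motif_id) |>
    distinct(.data$tf_gene, .keep_all = TRUE) |>
    mutate(enrichment_rank = row_number())
}

#' Re-rank enriched motifs by cross-condition expression difference
#'
#' The motif-expression integration used to nominate candidate master TFs:
#' take the `top_k` non-redundant motifs by enrichment FDR, keep only TFs
#' robustly expressed in the target condition (log2CPM strictly above
#' `expr_min`), and re-rank the survivors by the expression difference
#' `expr_target - expr_background`, descending. The first `n_top_report`
#' entries are the nominated factors.
#'
#' @param motifs Motif tibble; deduplicated with [deduplicate_motifs()] if an
#'   `enrichment_rank` column is absent.
#' @param expr Condition-level expression tibble: `gene_id` plus one log2CPM
#'   column per condition (see [condition_means()]).
#' @param target,background Condition column names in `expr`.
#' @param top_k Number of top enriched motifs considered (default 25; use 40
#'   for footprinting-tool outputs).
#' @param expr_min Minimum target-condition expression (log2CPM, default 2).
#' @param n_top_report Number of nominated factors (default 5).
#' @return A tibble of class `atac_tf_ranking` with `tf_gene`, `motif_id`,
#'   `fdr`, `enrichment_rank`, `expr_target`, `expr_background`, `expr_diff`,
#'   `final_rank` and `nominated` (`final_rank <= n_top_report`).
#' @export
rank_tfs_by_expression <- function(motifs, expr, target, background,
                                   top_k = 25, expr_min = 2, n_top_report = 5) {
  if (n_top_report > top_k) abort("rank_tfs_by_expression: n_top_report must be <= top_k")
  if (!all(c(target, background) %in% names(expr))) {
    abort(sprintf("rank_tfs_by_expression: expression table lacks condition column(s) '%s'/'%s'",
                  target, background))
  }
  if (!"enrichment_rank" %in% names(motifs)) {
    motifs <- deduplicate_motifs(motifs)
  }
  top <- motifs |>
    arrange(.data$enrichment_rank) |>
    head(top_k)
  id_col <- names(expr)[1]
  matched <- match(top$tf_gene, expr[[id_col]])
  absent <- is.na(matched)
  if (any(absent)) {
    warn(sprintf("rank_tfs_by_expression: %d TF(s) absent from the expression table: %s",
                 sum(absent), paste(head(top$tf_gene[absent], 5), collapse = ", ")))
  }
  top <- top[!absent, , drop = FALSE]
  matched <- matched[!absent]
  ranked <- top |>
    mutate(
      expr_target = expr[[target]][matched],
      expr_background = expr[[background]][matched],
      expr_diff = .data$expr_target - .data$expr_background
    ) |>
    filter(.data$expr_target > expr_min) |>
    arrange(desc(.data$expr_diff), .data$fdr, .data$tf_gene) |>
    mutate(final_rank = row_number(),
           nominated = .data$final_rank <= n_top_report)
  if (nrow(ranked) == 0L) {
    warn("rank_tfs_by_expression: no TF passes the expression filter")
  }
  structure(ranked, class = c("atac_tf_ranking", class(ranked)),
            target = target, background = background,
            n_top_report = n_top_report)
}

#' Nominated top factors of a TF ranking
#'
#' @param ranking An `atac_tf_ranking` from [rank_tfs_by_expression()].
#' @return The nominated rows as a plain tibble.
#' @export
top_tfs <- function(ranking) {
  as_tibble(ranking[ranking$nominated, , drop = FALSE])
}

#' @rdname rank_tfs_by_expression
#' @param x An `atac_tf_ranking` object.
#' @param ... Unused.
#' @method glance atac_tf_ranking
#' @export
glance.atac_tf_ranking <- function(x, ...) {
  tibble(
    target = attr(x, "target"),
    background = attr(x, "background"),
    n_ranked = nrow(x),
    n_nominated = sum(x$nominated),
    top_tf = if (nrow(x) > 0L) x$tf_gene[1] else NA_character_
  )
}
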