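#' Filter EST alignments on length and identity
#'
#' Keeps alignments whose EST is at least `min_length` bp long and whose
#' aligned region reaches at least `min_identity`, with identity computed
#' over aligned columns as `matches / (matches + mismatches)`. Both bounds
#' are inclusive. Records with no aligned columns are skipped with a
#' warning.
#'
#' @param alignments EST alignment tibble (see [read_psl()]).
#' @param min_length Minimum EST length in bp (default 100).
#' @param min_identity Minimum alignment-region identity as a fraction
#'   (default 0.95).
#' @return The surviving alignments with an `identity` column appended.
#' @export
filter_alignments <- function(alignments, min_length = 100,
                              min_identity = 0.95) {
  span <- alignments$matches + alignments$mismatches
  if (any(span == 0)) {
    warning(sprintf("%d alignment(s) with no aligned columns skipped",
                    sum(span == 0)), call. = FALSE)
    alignments <- alignments[span > 0, , drop = FALSE]
    span <- span[span > 0]
  }
  alignments |>
    dplyr::mutate(identity = .data$matches / (.data$matches + .data$mismatches)) |>
    dplyr::filter(.data$est_length >= min_length,
                  .data$identity >= min_identity)
}

#' Assign each EST to its best-matching isoform
#'
#' Per EST, the alignment with maximal identity wins; ties are broken by
#' maximal match count, then by the lexicographically smallest isoform id
#' — a deterministic stand-in for an arbitrary choice among equal best
#' matches. Each surviving EST is assigned to exactly one isoform.
#'
#' @param filtered Output of [filter_alignments()].
#' @return Tibble `est_id`, `isoform_id`, `identity`, `matches`, one row
#'   per distinct EST.
#' @export
assign_best_match <- function(filtered) {
  filtered |>
    dplyr::arrange(.data$est_id, dplyr::desc(.data$identity),
                   dplyr::desc(.data$matches), .data$isoform_id) |>
    dplyr::distinct(.data$est_id, .keep_all = TRUE) |>
    dplyr::select("est_id", "isoform_id", "identity", "matches")
}

#' Average EST hits per transcript, per group and criterion
#'
#' For every group at every criterion: the number of assigned ESTs
#' hitting any transcript of the group's genes, divided by the number of
#' transcripts those genes have. Transcripts with zero hits count in the
#' denominator, so the quantity is a per-transcript expression average
#' comparable across groups.
#'
#' @param assignments Output of [assign_best_match()].
#' @param isoform_to_gene Tibble `isoform_id`, `gene_id` covering every
#'   transcript of the analyzed genes.
#' @param groups Group tibble from [classify_groups()] (swept).
#' @return Tibble per (criterion, group): `n_genes`, `n_transcripts`,
#'   `n_est_hits`, `avg_est_per_transcript`.
#' @export
est_profile <- function(assignments, isoform_to_gene, groups) {
  unmapped <- setdiff(assignments$isoform_id, isoform_to_gene$isoform_id)
  if (length(unmapped)) {
    stop(sprintf("assigned isoform has no gene mapping: %s", unmapped[1]),
         call. = FALSE)
  }
  hits_per_isoform <- assignments |>
    dplyr::count(.data$isoform_id, name = "hits")
  per_gene <- isoform_to_gene |>
    dplyr::left_join(hits_per_isoform, by = "isoform_id") |>
    dplyr::mutate(hits = dplyr::coalesce(.data$hits, 0L)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_transcripts = dplyr::n(), n_est_hits = sum(.data$hits),
                     .groups = "drop")
  groups |>
    dplyr::inner_join(per_gene, by = "gene_id") |>
    dplyr::group_by(.data$criterion, .data$group) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_transcripts = sum(.data$n_transcripts),
      n_est_hits = sum(.data$n_est_hits),
      avg_est_per_transcript = .data$n_est_hits / .data$n_transcripts,
      .groups = "drop"
    )
}
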