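#' Call alternative-splicing status per gene
#'
#' A gene has alternative splicing when it has more than one counted
#' protein product: known peptides under `known_only` mode, all peptides
#' under `all` mode. AS status is a property of the gene itself and does
#' not vary with the identity criterion.
#'
#' @param genes Gene-record tibble (see [read_gene_tables()]).
#' @param config A [run_config()]; `peptide_status_mode` selects the count.
#' @return Tibble `gene_id`, `isoform_count` (the counted peptide number),
#'   `as_status` (logical).
#' @export
classify_as <- function(genes, config = run_config()) {
  stopifnot(inherits(config, "dupsplice_config"))
  counts <- if (config$peptide_status_mode == "known_only") {
    genes$known_peptide_count
  } else {
    genes$all_peptide_count
  }
  if (any(counts < 1)) {
    g <- genes$gene_id[counts < 1][1]
    stop(sprintf(
      "gene %s has no counted peptide under mode '%s'; exclude it upstream (see analyzed_genes())",
      g, config$peptide_status_mode), call. = FALSE)
  }
  tibble::tibble(
    gene_id = genes$gene_id,
    isoform_count = as.integer(counts),
    as_status = counts > 1L
  )
}

#' Restrict gene records to the analyzable set
#'
#' Genes with zero counted peptides under the configured mode have
#' undefined AS status and are excluded from every downstream statistic.
#'
#' @inheritParams classify_as
#' @return List with `genes` (the retained records) and `excluded`
#'   (character vector of dropped gene ids).
#' @export
analyzed_genes <- function(genes, config = run_config()) {
  counts <- if (config$peptide_status_mode == "known_only") {
    genes$known_peptide_count
  } else {
    genes$all_peptide_count
  }
  keep <- counts >= 1L
  list(genes = genes[keep, , drop = FALSE], excluded = genes$gene_id[!keep])
}

GROUP_LEVELS <- c("A_F", "N_F", "MIXED_F", "A_S", "N_S")

#' Assign the five-way duplication-by-AS group label
#'
#' Per criterion, singletons become `A_S` (AS) or `N_S` (no AS); families
#' whose members all have AS become `A_F`, families with no AS member
#' become `N_F`, and families with both kinds become `MIXED_F` (the
#' "others" class, excluded from four-group feature comparisons).
#'
#' @param partition Partition tibble from [build_families()] or
#'   [sweep_partitions()] (a `criterion` column is carried through if
#'   present).
#' @param as_calls Tibble from [classify_as()] (`gene_id`, `as_status`,
#'   optionally `isoform_count`).
#' @return The partition tibble with `as_status`, `isoform_count` and
#'   `group` (factor with levels A_F, N_F, MIXED_F, A_S, N_S) appended.
#' @export
classify_groups <- function(partition, as_calls) {
  missing <- setdiff(partition$gene_id, as_calls$gene_id)
  if (length(missing)) {
    stop(sprintf("no AS status for gene: %s", missing[1]), call. = FALSE)
  }
  keys <- intersect(c("criterion", "family_id"), names(partition))
  joined <- partition |>
    dplyr::left_join(as_calls, by = "gene_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      group = dplyr::case_when(
        !.data$is_duplicate & .data$as_status ~ "A_S",
        !.data$is_duplicate ~ "N_S",
        all(.data$as_status) ~ "A_F",
        !any(.data$as_status) ~ "N_F",
        TRUE ~ "MIXED_F"
      )
    ) |>
    dplyr::ungroup()
  joined$group <- factor(joined$group, levels = GROUP_LEVELS)
  joined
}
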