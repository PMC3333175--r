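#' Proportion of genes with alternative splicing
#'
#' @param as_status Logical vector (one element per gene).
#' @return The fraction of `TRUE` values.
#' @export
as_proportion <- function(as_status) {
  if (!length(as_status)) stop("empty gene set", call. = FALSE)
  mean(as_status)
}

#' Mean isoform count over a gene set
#'
#' Arithmetic mean of the counted peptide number over all genes in the
#' set; genes without AS contribute their single isoform.
#'
#' @param isoform_count Positive integer vector of per-gene counted
#'   peptide numbers.
#' @param as_only Average only over genes with more than one isoform
#'   (default `FALSE`: all genes in the stratum are averaged).
#' @return Mean isoform count.
#' @export
mean_isoform_count <- function(isoform_count, as_only = FALSE) {
  if (!length(isoform_count)) stop("empty gene set", call. = FALSE)
  if (as_only) {
    isoform_count <- isoform_count[isoform_count > 1]
    if (!length(isoform_count)) return(NA_real_)
  }
  mean(isoform_count)
}

#' Pearson chi-squared test on a 2x2 duplication-by-AS table
#'
#' Rows are duplicate/singleton, columns AS/no-AS. With `correction` the
#' Yates continuity correction (|O-E| reduced by 0.5, floored at 0) is
#' applied, which can only shrink the statistic.
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @param correction Apply the Yates correction (default `TRUE`).
#' @return Tibble `statistic`, `df`, `p_value`, `correction`.
#' @export
#' @examples
#' pearson_chisq(matrix(c(30, 10, 10, 30), 2), correction = FALSE)
pearson_chisq <- function(counts, correction = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0)) {
    stop("`counts` must be a 2x2 matrix of non-negative counts", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = correction))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    correction = correction
  )
}

#' @noRd
quartile_cols <- function(x) {
  if (!length(x)) {
    return(tibble::tibble(min = NA_real_, q1 = NA_real_, median = NA_real_,
                          q3 = NA_real_, max = NA_real_, mean = NA_real_))
  }
  q <- stats::quantile(x, probs = c(0, .25, .5, .75, 1), type = 7, names = FALSE)
  tibble::tibble(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
                 mean = mean(x))
}

#' AS proportions and isoform counts stratified by family size
#'
#' For every identity criterion and family-size bin, computes the number
#' of genes, the AS proportion and the mean isoform count; additionally
#' collapses each criterion into a duplicate-vs-singleton 2x2 table and
#' applies the Pearson chi-squared test. Empty bins are emitted with
#' `n_genes = 0` and `NA` statistics.
#'
#' @param partitions Sweep tibble from [sweep_partitions()].
#' @param as_calls Tibble from [classify_as()].
#' @param config A [run_config()].
#' @param isoform_mean_as_only Passed to [mean_isoform_count()].
#' @return Object of class `dupsplice_proportions`: a list with
#'   `by_bin` (criterion x size_bin rows) and `overall` (one row per
#'   criterion with the duplicate/singleton proportions and test).
#' @export
proportion_sweep <- function(partitions, as_calls, config = run_config(),
                             isoform_mean_as_only = FALSE) {
  stopifnot(inherits(config, "dupsplice_config"))
  d <- partitions |>
    dplyr::inner_join(as_calls, by = "gene_id")

  by_bin <- d |>
    dplyr::group_by(.data$criterion, .data$size_bin) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_as = sum(.data$as_status),
      as_proportion = as_proportion(.data$as_status),
      mean_isoform_count = mean_isoform_count(.data$isoform_count,
                                              as_only = isoform_mean_as_only),
      .groups = "drop"
    ) |>
    tidyr::complete(criterion = config$identity_criteria,
                    size_bin = factor(size_bin_labels(config),
                                      levels = size_bin_labels(config)),
                    fill = list(n_genes = 0L, n_as = 0L)) |>
    dplyr::arrange(.data$criterion, .data$size_bin)

  overall <- d |>
    dplyr::group_by(.data$criterion) |>
    dplyr::summarise(
      n_duplicate = sum(.data$is_duplicate),
      n_singleton = sum(!.data$is_duplicate),
      as_prop_duplicate = if (any(.data$is_duplicate))
        as_proportion(.data$as_status[.data$is_duplicate]) else NA_real_,
      as_prop_singleton = if (any(!.data$is_duplicate))
        as_proportion(.data$as_status[!.data$is_duplicate]) else NA_real_,
      mean_isoforms_duplicate = if (any(.data$is_duplicate))
        mean_isoform_count(.data$isoform_count[.data$is_duplicate],
                           isoform_mean_as_only) else NA_real_,
      mean_isoforms_singleton = if (any(!.data$is_duplicate))
        mean_isoform_count(.data$isoform_count[!.data$is_duplicate],
                           isoform_mean_as_only) else NA_real_,
      test = list(tryCatch(
        pearson_chisq(
          matrix(c(sum(.data$is_duplicate & .data$as_status),
                   sum(!.data$is_duplicate & .data$as_status),
                   sum(.data$is_duplicate & !.data$as_status),
                   sum(!.data$is_duplicate & !.data$as_status)),
                 nrow = 2,
                 dimnames = list(c("duplicate", "singleton"), c("AS", "noAS"))),
          correction = config$chisq_continuity_correction),
        error = function(e) tibble::tibble(statistic = NA_real_, df = NA_real_,
                                           p_value = NA_real_,
                                           correction = config$chisq_continuity_correction))),
      .groups = "drop"
    ) |>
    tidyr::unnest("test")

  structure(list(by_bin = by_bin, overall = overall, config = config),
            class = "dupsplice_proportions")
}

#' @export
print.dupsplice_proportions <- function(x, ...) {
  cat("<dupsplice_proportions>\n")
  cat("Duplicate vs singleton AS proportion per criterion:\n")
  print(dplyr::select(x$overall, "criterion", "n_duplicate", "n_singleton",
                      "as_prop_duplicate", "as_prop_singleton", "p_value"))
  invisible(x)
}

#' Ka/Ks summaries per group and criterion
#'
#' The per-gene ratio Ka/Ks (nonsynonymous over synonymous substitution
#' rate) is summarised per four-group label and criterion; lower values
#' indicate stronger purifying selection. Genes with missing Ka or Ks, or
#' `ks <= 0`, are excluded and counted, never silently dropped. `MIXED_F`
#' genes are excluded to match the four-group framing.
#'
#' @param groups Group tibble from [classify_groups()] (swept).
#' @param genes Gene-record tibble carrying `ka`, `ks`.
#' @return Tibble per (criterion, group): `n`, quartiles (type-7), `mean`
#'   and `excluded_kaks_count`.
#' @export
ka_ks_summary <- function(groups, genes) {
  groups |>
    dplyr::filter(.data$group != "MIXED_F") |>
    dplyr::inner_join(genes[, c("gene_id", "ka", "ks")], by = "gene_id") |>
    dplyr::mutate(usable = !is.na(.data$ka) & !is.na(.data$ks) & .data$ks > 0,
                  ka_ks = ifelse(.data$usable, .data$ka / .data$ks, NA_real_)) |>
    dplyr::group_by(.data$criterion, .data$group) |>
    dplyr::summarise(
      n = sum(.data$usable),
      excluded_kaks_count = sum(!.data$usable),
      quartile_cols(.data$ka_ks[.data$usable]),
      .groups = "drop"
    )
}

#' Protein-length quartiles and domain-count histogram per group
#'
#' Lengths use the longest known peptide per gene; the domain histogram
#' reports per-group frequencies (and their log10, for plotting parity
#' with log-frequency figures). Genes missing a domain count are excluded
#' from the histogram only. `MIXED_F` is excluded from both.
#'
#' @inheritParams ka_ks_summary
#' @return List with `length` (per criterion x group quartile rows) and
#'   `domains` (per criterion x group x domain_count frequencies).
#' @export
feature_summary <- function(groups, genes) {
  g <- groups |>
    dplyr::filter(.data$group != "MIXED_F") |>
    dplyr::inner_join(
      genes[, c("gene_id", "longest_known_peptide_length", "domain_count")],
      by = "gene_id")

  len <- g |>
    dplyr::filter(!is.na(.data$longest_known_peptide_length)) |>
    dplyr::group_by(.data$criterion, .data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     quartile_cols(.data$longest_known_peptide_length),
                     .groups = "drop")

  dom <- g |>
    dplyr::filter(!is.na(.data$domain_count)) |>
    dplyr::count(.data$criterion, .data$group, .data$domain_count, name = "n") |>
    dplyr::group_by(.data$criterion, .data$group) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n),
                  log10_frequency = log10(.data$frequency)) |>
    dplyr::ungroup()

  list(length = len, domains = dom)
}

#' GO category distribution per group
#'
#' Counts gene-category incidences per group (a gene annotated with k
#' categories contributes k incidences) and reports each category's share
#' of the group's incidences; categories whose share is not larger than
#' `others_threshold` are tallied together as `"others"`, so the reported
#' proportions still sum to 1. With `per_gene = TRUE` the denominator is
#' instead the number of annotated genes in the group (shares then need
#' not sum to 1).
#'
#' @inheritParams ka_ks_summary
#' @param go GO tibble (`gene_id`, `ontology`, `category`).
#' @param ontology `"MF"` or `"BP"`.
#' @param others_threshold Proportion at or below which a category is
#'   merged into `"others"` (default 0.01: only categories larger than 1%
#'   are kept).
#' @param per_gene Use per-gene rather than per-annotation denominators.
#' @return Tibble per (criterion, group, category): `n_incidences`,
#'   `proportion`.
#' @export
go_distribution <- function(groups, go, ontology = c("MF", "BP"),
                            others_threshold = 0.01, per_gene = FALSE) {
  ontology <- match.arg(ontology)
  go <- dplyr::filter(go, .data$ontology == .env$ontology)
  g4 <- dplyr::filter(groups, .data$group != "MIXED_F")
  annotated <- g4 |>
    dplyr::inner_join(go, by = "gene_id", relationship = "many-to-many") |>
    dplyr::distinct(.data$criterion, .data$group, .data$gene_id, .data$category)

  empty <- g4 |>
    dplyr::distinct(.data$criterion, .data$group) |>
    dplyr::anti_join(dplyr::distinct(annotated, .data$criterion, .data$group),
                     by = c("criterion", "group"))
  if (nrow(empty)) {
    warning(sprintf("%d group(s) have no %s-annotated genes", nrow(empty),
                    ontology), call. = FALSE)
  }

  counts <- annotated |>
    dplyr::count(.data$criterion, .data$group, .data$category,
                 name = "n_incidences") |>
    dplyr::group_by(.data$criterion, .data$group)
  counts <- if (per_gene) {
    denom <- annotated |>
      dplyr::distinct(.data$criterion, .data$group, .data$gene_id) |>
      dplyr::count(.data$criterion, .data$group, name = "n_genes")
    counts |>
      dplyr::ungroup() |>
      dplyr::left_join(denom, by = c("criterion", "group")) |>
      dplyr::mutate(proportion = .data$n_incidences / .data$n_genes) |>
      dplyr::select(-"n_genes") |>
      dplyr::group_by(.data$criterion, .data$group)
  } else {
    dplyr::mutate(counts,
                  proportion = .data$n_incidences / sum(.data$n_incidences))
  }
  counts |>
    dplyr::mutate(category = ifelse(.data$proportion > others_threshold,
                                    .data$category, "others")) |>
    dplyr::group_by(.data$criterion, .data$group, .data$category) |>
    dplyr::summarise(n_incidences = sum(.data$n_incidences),
                     proportion = sum(.data$proportion), .groups = "drop") |>
    dplyr::arrange(.data$criterion, .data$group, dplyr::desc(.data$proportion))
}
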