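#' @importFrom ggplot2 ggplot aes geom_col geom_boxplot geom_line geom_point
#'   facet_wrap labs scale_y_continuous position_dodge autoplot label_both
NULL

#' Bar chart of AS proportion by family-size bin and criterion
#'
#' Mirrors the stratified AS-proportion view: one bar per size bin
#' (singletons included) per identity criterion.
#'
#' @param report A `dupsplice_report`.
#' @return A ggplot object.
#' @export
plot_as_proportion <- function(report) {
  d <- dplyr::filter(report$proportions$by_bin, .data$n_genes > 0)
  ggplot(d, aes(x = .data$size_bin, y = .data$as_proportion,
                fill = factor(.data$criterion))) +
    geom_col(position = position_dodge()) +
    labs(x = "family size", y = "proportion of genes with AS",
         fill = "identity >") +
    scale_y_continuous(limits = c(0, 1))
}

#' Bar chart of mean isoform count by family-size bin and criterion
#'
#' @inheritParams plot_as_proportion
#' @return A ggplot object.
#' @export
plot_isoform_counts <- function(report) {
  d <- dplyr::filter(report$proportions$by_bin, .data$n_genes > 0)
  ggplot(d, aes(x = .data$size_bin, y = .data$mean_isoform_count,
                fill = factor(.data$criterion))) +
    geom_col(position = position_dodge()) +
    labs(x = "family size", y = "mean isoform count", fill = "identity >")
}

#' Stacked group composition per criterion
#'
#' Shows how the analyzed genes split into A_F, N_F, MIXED_F, A_S and N_S
#' as the identity criterion varies.
#'
#' @inheritParams plot_as_proportion
#' @return A ggplot object.
#' @export
plot_group_counts <- function(report) {
  ggplot(report$group_counts,
         aes(x = factor(.data$criterion), y = .data$n_genes,
             fill = .data$group)) +
    geom_col() +
    labs(x = "identity criterion (>)", y = "genes", fill = "group")
}

#' @noRd
boxplot_from_quartiles <- function(d, y_lab) {
  ggplot(d, aes(x = .data$group, ymin = .data$min, lower = .data$q1,
                middle = .data$median, upper = .data$q3, ymax = .data$max)) +
    geom_boxplot(stat = "identity") +
    facet_wrap(~criterion, labeller = ggplot2::label_both) +
    labs(x = "group", y = y_lab)
}

#' Ka/Ks boxplots per group, faceted by criterion
#'
#' Drawn from the reported quartiles (type-7), so the figure is exactly
#' the summary the report carries.
#'
#' @inheritParams plot_as_proportion
#' @return A ggplot object.
#' @export
plot_kaks <- function(report) {
  if (is.null(report$kaks)) stop("report has no Ka/Ks summary", call. = FALSE)
  boxplot_from_quartiles(dplyr::filter(report$kaks, .data$n > 0), "Ka/Ks")
}

#' Protein-length boxplots per group, faceted by criterion
#'
#' @inheritParams plot_as_proportion
#' @return A ggplot object.
#' @export
plot_lengths <- function(report) {
  if (is.null(report$features)) stop("report has no feature summary", call. = FALSE)
  boxplot_from_quartiles(report$features$length, "longest known peptide (aa)")
}

#' Log-frequency domain-count distribution per group
#'
#' @inheritParams plot_as_proportion
#' @param criterion Which identity criterion to show (default: lowest).
#' @return A ggplot object.
#' @export
plot_domains <- function(report, criterion = NULL) {
  if (is.null(report$features)) stop("report has no feature summary", call. = FALSE)
  d <- report$features$domains
  criterion <- criterion %||% min(d$criterion)
  d <- dplyr::filter(d, .data$criterion == .env$criterion)
  ggplot(d, aes(x = .data$domain_count, y = .data$log10_frequency,
                colour = .data$group)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "number of domains", y = "log10 frequency",
         title = sprintf("identity > %s", criterion))
}

#' Stacked GO category distribution per group
#'
#' @inheritParams plot_as_proportion
#' @param ontology `"MF"` or `"BP"`.
#' @param criterion Which identity criterion to show (default: lowest).
#' @return A ggplot object.
#' @export
plot_go <- function(report, ontology = c("MF", "BP"), criterion = NULL) {
  ontology <- match.arg(ontology)
  d <- if (ontology == "MF") report$go_mf else report$go_bp
  if (is.null(d)) stop("report has no GO distribution", call. = FALSE)
  criterion <- criterion %||% min(d$criterion)
  d <- dplyr::filter(d, .data$criterion == .env$criterion)
  ggplot(d, aes(x = .data$group, y = .data$proportion, fill = .data$category)) +
    geom_col() +
    labs(x = "group", y = "proportion of annotations",
         title = sprintf("%s, identity > %s", ontology, criterion))
}

#' Autoplot method for reports
#'
#' @param object A `dupsplice_report`.
#' @param type One of `"as_proportion"`, `"isoforms"`, `"groups"`,
#'   `"kaks"`, `"lengths"`, `"domains"`, `"go"`.
#' @param ... Passed to the underlying `plot_*` function.
#' @return A ggplot object.
#' @export
autoplot.dupsplice_report <- function(object,
                                      type = c("as_proportion", "isoforms",
                                               "groups", "kaks", "lengths",
                                               "domains", "go"),
                                      ...) {
  type <- match.arg(type)
  switch(type,
         as_proportion = plot_as_proportion(object),
         isoforms = plot_isoform_counts(object),
         groups = plot_group_counts(object),
         kaks = plot_kaks(object),
         lengths = plot_lengths(object),
         domains = plot_domains(object, ...),
         go = plot_go(object, ...))
}
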