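#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a duplication/AS report into one table
#'
#' @param x A `dupsplice_report`.
#' @param table Which component to return: `"proportions"` (per criterion
#'   x size bin; default), `"overall"` (duplicate vs singleton with the
#'   chi-squared test), `"groups"` (per-gene labels), `"group_counts"`,
#'   `"kaks"`, `"length"`, `"domains"`, `"go_mf"`, `"go_bp"`, `"est"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dupsplice_report <- function(x, table = c("proportions", "overall",
                                               "groups", "group_counts",
                                               "kaks", "length", "domains",
                                               "go_mf", "go_bp", "est"),
                                  ...) {
  table <- match.arg(table)
  out <- switch(table,
    proportions = x$proportions$by_bin,
    overall = x$proportions$overall,
    groups = x$groups,
    group_counts = x$group_counts,
    kaks = x$kaks,
    length = if (!is.null(x$features)) x$features$length,
    domains = if (!is.null(x$features)) x$features$domains,
    go_mf = x$go_mf,
    go_bp = x$go_bp,
    est = x$est
  )
  if (is.null(out)) {
    stop(sprintf("report has no '%s' table (input not supplied)", table),
         call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' One-row summary of a duplication/AS report
#'
#' @param x A `dupsplice_report`.
#' @param ... Unused.
#' @return A one-row tibble: gene counts, criterion count, and the range
#'   of duplicate-vs-singleton chi-squared p-values across the sweep.
#' @export
glance.dupsplice_report <- function(x, ...) {
  tibble::tibble(
    n_genes_analyzed = x$n_genes_analyzed,
    n_excluded = length(x$excluded_genes),
    n_criteria = length(x$config$identity_criteria),
    min_chisq_p = suppressWarnings(min(x$proportions$overall$p_value, na.rm = TRUE)),
    max_chisq_p = suppressWarnings(max(x$proportions$overall$p_value, na.rm = TRUE)),
    n_warnings = length(x$warnings)
  )
}

#' @export
tidy.dupsplice_proportions <- function(x, ...) x$by_bin

#' @export
glance.dupsplice_proportions <- function(x, ...) {
  dplyr::select(x$overall, "criterion", "as_prop_duplicate",
                "as_prop_singleton", "statistic", "p_value")
}
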