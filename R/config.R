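#' Run configuration for a duplication/AS sweep
#'
#' Bundles the analysis knobs shared by every pipeline stage: the sweep of
#' protein-identity criteria defining paralog age strata, how peptides are
#' counted when calling alternative splicing, the family-size bins used for
#' stratified summaries, and whether the 2x2 chi-squared test applies the
#' Yates continuity correction.
#'
#' @param identity_criteria Numeric vector of percent-identity thresholds,
#'   each strictly between 0 and 100 and strictly increasing. A paralog pair
#'   qualifies at a criterion when at least one of its two directional
#'   identities is strictly larger than the threshold, so higher criteria
#'   select younger duplications. Default `c(10, 20, 30, 50, 70, 90)`.
#' @param peptide_status_mode `"known_only"` (default) counts only peptides
#'   flagged `known` when deciding AS status and isoform numbers;
#'   `"all"` also counts `novel` peptides.
#' @param family_size_breaks Lower edges of the duplicate family-size bins
#'   (integers, strictly increasing, first `>= 2`). The default `c(2, 5, 8)`
#'   yields bins `2-4`, `5-7` and `8+`; size 1 is always the `singleton` bin,
#'   so the bins partition all positive integers.
#' @param chisq_continuity_correction Apply the Yates correction in the
#'   duplicate-vs-singleton 2x2 test. Default `TRUE`.
#' @param random_seed Optional integer seed echoed into reports.
#'
#' @return An object of class `dupsplice_config` (a named list).
#' @export
#' @examples
#' cfg <- run_config(identity_criteria = c(10, 50, 90))
#' bin_family_size(c(1, 3, 7, 20), cfg)
run_config <- function(identity_criteria = c(10, 20, 30, 50, 70, 90),
                       peptide_status_mode = c("known_only", "all"),
                       family_size_breaks = c(2, 5, 8),
                       chisq_continuity_correction = TRUE,
                       random_seed = NULL) {
  peptide_status_mode <- match.arg(peptide_status_mode)
  if (length(identity_criteria) < 1 || anyNA(identity_criteria)) {
    stop("`identity_criteria` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(identity_criteria <= 0) || any(identity_criteria >= 100)) {
    stop("identity criteria must lie strictly between 0 and 100", call. = FALSE)
  }
  if (is.unsorted(identity_criteria, strictly = TRUE)) {
    stop("identity criteria must be strictly increasing", call. = FALSE)
  }
  family_size_breaks <- as.integer(family_size_breaks)
  if (length(family_size_breaks) < 1 || anyNA(family_size_breaks) ||
      family_size_breaks[1] < 2 ||
      is.unsorted(family_size_breaks, strictly = TRUE)) {
    stop("`family_size_breaks` must be strictly increasing integers with first >= 2",
         call. = FALSE)
  }
  structure(
    list(
      identity_criteria = as.numeric(identity_criteria),
      peptide_status_mode = peptide_status_mode,
      family_size_breaks = family_size_breaks,
      chisq_continuity_correction = isTRUE(chisq_continuity_correction),
      random_seed = if (is.null(random_seed)) NULL else as.integer(random_seed)
    ),
    class = "dupsplice_config"
  )
}

#' @export
print.dupsplice_config <- function(x, ...) {
  cat("<dupsplice_config>\n")
  cat("  identity criteria: >", paste(x$identity_criteria, collapse = ", >"), "\n", sep = "")
  cat("  peptide status mode:", x$peptide_status_mode, "\n")
  cat("  family size bins:", paste(size_bin_labels(x), collapse = ", "), "\n")
  cat("  chi-squared continuity correction:", x$chisq_continuity_correction, "\n")
  invisible(x)
}

#' Family-size bin labels implied by a configuration
#'
#' @param config A [run_config()] object.
#' @return Character vector of bin labels, `"singleton"` first, in increasing
#'   size order (ordered-factor levels used throughout the package).
#' @export
size_bin_labels <- function(config = run_config()) {
  stopifnot(inherits(config, "dupsplice_config"))
  br <- config$family_size_breaks
  upper <- c(br[-1] - 1L, NA_integer_)
  lab <- ifelse(is.na(upper), paste0(br, "+"),
                ifelse(br == upper, as.character(br), paste0(br, "-", upper)))
  c("singleton", lab)
}

#' Map family sizes to configured size bins
#'
#' Size 1 maps to `"singleton"`; larger sizes map to the duplicate bins
#' defined by `family_size_breaks` (default `2-4`, `5-7`, `8+`).
#'
#' @param size Integer vector of family sizes (each `>= 1`).
#' @inheritParams size_bin_labels
#' @return Factor of bin labels with levels in increasing size order.
#' @export
bin_family_size <- function(size, config = run_config()) {
  stopifnot(inherits(config, "dupsplice_config"))
  if (anyNA(size) || any(size < 1)) {
    stop("family sizes must be >= 1", call. = FALSE)
  }
  labs <- size_bin_labels(config)
  idx <- findInterval(size, c(1L, config$family_size_breaks))
  factor(labs[idx], levels = labs)
}
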