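#' Run the full duplication-by-AS analysis
#'
#' Orchestrates the sweep end to end: exclude genes with no counted
#' peptide, qualify paralog pairs and build single-linkage families at
#' every identity criterion, call AS status, assign the five-way group
#' labels, and compute the stratified summaries. Ka/Ks, feature, GO and
#' EST sections are produced only when their inputs are present; skipped
#' analyses are listed in the report's warnings.
#'
#' @param genes Gene-record tibble ([read_gene_tables()]).
#' @param pairs Paralog-pair tibble ([read_paralog_pairs()]).
#' @param go Optional GO tibble ([read_go_table()]).
#' @param est_alignments Optional EST alignment tibble ([read_psl()]).
#' @param isoform_to_gene Optional isoform map (required with
#'   `est_alignments`).
#' @param config A [run_config()].
#' @return Object of class `dupsplice_report`.
#' @export
#' @examples
#' sim <- simulate_dataset(synth_params(n_genes = 300, seed = 42))
#' genes <- peptides_to_records(sim$genes, sim$peptides,
#'                              kaks = sim$kaks, domains = sim$domains)
#' rep <- run_pipeline(genes, sim$pairs, go = sim$go,
#'                     config = run_config(identity_criteria = c(10, 90)))
#' rep$proportions$overall
run_pipeline <- function(genes, pairs, go = NULL, est_alignments = NULL,
                         isoform_to_gene = NULL, config = run_config()) {
  stopifnot(inherits(config, "dupsplice_config"))
  if (is.null(genes) || is.null(pairs)) {
    stop("gene records and paralog pairs are required inputs", call. = FALSE)
  }
  if (!is.null(est_alignments) && is.null(isoform_to_gene)) {
    stop("`isoform_to_gene` is required when EST alignments are supplied",
         call. = FALSE)
  }
  warnings <- character(0)

  kept <- analyzed_genes(genes, config)
  if (length(kept$excluded)) {
    warnings <- c(warnings, sprintf(
      "%d gene(s) with no counted peptide excluded from the analysis",
      length(kept$excluded)))
  }
  genes <- kept$genes
  universe <- genes$gene_id

  # pairs touching excluded genes cannot link analyzed genes
  pairs <- validate_pairs(pairs)
  pairs_kept <- dplyr::filter(pairs, .data$gene_a %in% universe,
                              .data$gene_b %in% universe)
  if (nrow(pairs_kept) < nrow(pairs)) {
    warnings <- c(warnings, sprintf(
      "%d paralog pair(s) touching excluded genes dropped",
      nrow(pairs) - nrow(pairs_kept)))
  }

  partitions <- sweep_partitions(pairs_kept, universe, config)
  as_calls <- classify_as(genes, config)
  groups <- classify_groups(partitions, as_calls)
  group_counts <- groups |>
    dplyr::count(.data$criterion, .data$group, name = "n_genes", .drop = FALSE)

  proportions <- proportion_sweep(partitions, as_calls, config)

  kaks <- NULL
  if (any(!is.na(genes$ka) & !is.na(genes$ks))) {
    kaks <- ka_ks_summary(groups, genes)
  } else {
    warnings <- c(warnings, "no Ka/Ks values supplied; Ka/Ks summary skipped")
  }

  features <- NULL
  if (any(!is.na(genes$longest_known_peptide_length))) {
    features <- feature_summary(groups, genes)
  } else {
    warnings <- c(warnings, "no peptide lengths available; feature summary skipped")
  }

  go_mf <- go_bp <- NULL
  if (!is.null(go)) {
    go_mf <- go_distribution(groups, go, "MF")
    go_bp <- go_distribution(groups, go, "BP")
  } else {
    warnings <- c(warnings, "no GO table supplied; GO distributions skipped")
  }

  est <- est_assignments <- NULL
  if (!is.null(est_alignments)) {
    filtered <- filter_alignments(est_alignments)
    est_assignments <- assign_best_match(filtered)
    map_kept <- dplyr::filter(isoform_to_gene, .data$gene_id %in% universe)
    est_assignments <- dplyr::semi_join(est_assignments, map_kept,
                                        by = "isoform_id")
    est <- est_profile(est_assignments, map_kept, groups)
  } else {
    warnings <- c(warnings, "no EST alignments supplied; EST profile skipped")
  }

  structure(list(
    config = config,
    n_genes_input = nrow(genes) + length(kept$excluded),
    n_genes_analyzed = length(universe),
    excluded_genes = kept$excluded,
    partitions = partitions,
    groups = groups,
    group_counts = group_counts,
    proportions = proportions,
    kaks = kaks,
    features = features,
    go_mf = go_mf,
    go_bp = go_bp,
    est = est,
    est_assignments = est_assignments,
    warnings = warnings,
    version = as.character(utils::packageVersion("dupsplice"))
  ), class = "dupsplice_report")
}

#' Aggregate a gene table and peptide table into gene records
#'
#' In-memory counterpart of [read_gene_tables()] for tables that are
#' already tibbles (e.g. from [simulate_dataset()]).
#'
#' @param genes Tibble `gene_id`, `species`.
#' @param peptides Tibble `gene_id`, `peptide_id`, `status`,
#'   `peptide_length`.
#' @param kaks Optional tibble `gene_id`, `ka`, `ks`.
#' @param domains Optional tibble `gene_id`, `domain_count`.
#' @return Gene-record tibble in the [read_gene_tables()] layout.
#' @export
peptides_to_records <- function(genes, peptides, kaks = NULL, domains = NULL) {
  tmp <- tempfile(fileext = ".d")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  readr::write_tsv(genes, file.path(tmp, "genes.tsv"))
  readr::write_tsv(peptides, file.path(tmp, "peptides.tsv"))
  kp <- dp <- NULL
  if (!is.null(kaks)) {
    kp <- file.path(tmp, "kaks.tsv"); readr::write_tsv(kaks, kp)
  }
  if (!is.null(domains)) {
    dp <- file.path(tmp, "domains.tsv"); readr::write_tsv(domains, dp)
  }
  read_gene_tables(file.path(tmp, "genes.tsv"), file.path(tmp, "peptides.tsv"),
                   kaks_path = kp, domain_path = dp)
}

#' File-based front door for [run_pipeline()]
#'
#' @param gene_path,peptide_path,pair_path Required TSV inputs.
#' @param kaks_path,domain_path,go_path,est_path,isoform_map_path Optional
#'   inputs; `est_path` may be PSL (`.psl`) or the TSV dialect.
#' @param config A [run_config()].
#' @return A `dupsplice_report`.
#' @export
run_pipeline_files <- function(gene_path, peptide_path, pair_path,
                               kaks_path = NULL, domain_path = NULL,
                               go_path = NULL, est_path = NULL,
                               isoform_map_path = NULL,
                               config = run_config()) {
  for (p in c(gene_path, peptide_path, pair_path)) {
    if (!file.exists(p)) stop(sprintf("required input not found: %s", p),
                              call. = FALSE)
  }
  genes <- read_gene_tables(gene_path, peptide_path, kaks_path, domain_path)
  pairs <- read_paralog_pairs(pair_path)
  go <- if (!is.null(go_path)) read_go_table(go_path)
  est <- if (!is.null(est_path)) {
    if (grepl("\\.psl$", est_path)) read_psl(est_path) else read_est_tsv(est_path)
  }
  map <- if (!is.null(isoform_map_path)) read_isoform_map(isoform_map_path)
  run_pipeline(genes, pairs, go = go, est_alignments = est,
               isoform_to_gene = map, config = config)
}

#' @export
print.dupsplice_report <- function(x, ...) {
  cat("<dupsplice_report>\n")
  cat(sprintf("  %d genes analyzed (%d excluded) across %d identity criteria\n",
              x$n_genes_analyzed, length(x$excluded_genes),
              length(x$config$identity_criteria)))
  print(dplyr::select(x$proportions$overall, "criterion", "n_duplicate",
                      "n_singleton", "as_prop_duplicate", "as_prop_singleton",
                      "p_value"))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Write a report as TSV tables plus a JSON run summary
#'
#' Emits `proportions.tsv` (per criterion x size bin), `chisq.tsv`,
#' `groups.tsv`, `group_counts.tsv` and, when computed, `kaks.tsv`,
#' `features.tsv`, `domains.tsv`, `go_mf.tsv`, `go_bp.tsv`,
#' `est_profile.tsv`, plus `report.json` echoing the configuration,
#' counts and warnings. Output is a pure function of the report, so
#' re-running an identical analysis reproduces the files byte for byte.
#'
#' @param report A `dupsplice_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dupsplice_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(report$proportions$by_bin, p("proportions.tsv"))
  readr::write_tsv(dplyr::select(report$proportions$overall, -dplyr::any_of("test")),
                   p("chisq.tsv"))
  readr::write_tsv(report$groups, p("groups.tsv"))
  readr::write_tsv(report$group_counts, p("group_counts.tsv"))
  if (!is.null(report$kaks)) readr::write_tsv(report$kaks, p("kaks.tsv"))
  if (!is.null(report$features)) {
    readr::write_tsv(report$features$length, p("features.tsv"))
    readr::write_tsv(report$features$domains, p("domains.tsv"))
  }
  if (!is.null(report$go_mf)) readr::write_tsv(report$go_mf, p("go_mf.tsv"))
  if (!is.null(report$go_bp)) readr::write_tsv(report$go_bp, p("go_bp.tsv"))
  if (!is.null(report$est)) readr::write_tsv(report$est, p("est_profile.tsv"))
  summary <- list(
    config = list(
      identity_criteria = report$config$identity_criteria,
      peptide_status_mode = report$config$peptide_status_mode,
      family_size_breaks = report$config$family_size_breaks,
      chisq_continuity_correction = report$config$chisq_continuity_correction,
      random_seed = report$config$random_seed
    ),
    n_genes_input = report$n_genes_input,
    n_genes_analyzed = report$n_genes_analyzed,
    n_excluded = length(report$excluded_genes),
    warnings = report$warnings,
    version = report$version
  )
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}
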