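#' @keywords internal
#' @noRd
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = c("", "NA"))
}

#' Read gene, peptide, Ka/Ks and domain tables into gene records
#'
#' Aggregates a per-peptide table into one record per gene: how many
#' peptides it has (known-status only and in total), the length of its
#' longest known peptide, and optional per-gene Ka, Ks and domain counts
#' joined from side tables. Genes present in the gene table but absent from
#' the peptide table get zero peptide counts.
#'
#' @param gene_path TSV with columns `gene_id`, `species`.
#' @param peptide_path TSV with columns `gene_id`, `peptide_id`, `status`
#'   (`known` or `novel`), `peptide_length` (amino acids).
#' @param kaks_path Optional TSV with columns `gene_id`, `ka`, `ks`
#'   (substitutions per site, from an ortholog comparison).
#' @param domain_path Optional TSV with columns `gene_id`, `domain_count`.
#' @return A tibble with one row per gene: `gene_id`, `species`,
#'   `known_peptide_count`, `all_peptide_count`,
#'   `longest_known_peptide_length` (NA when no known peptide),
#'   `domain_count`, `ka`, `ks` (NA when not supplied).
#' @export
read_gene_tables <- function(gene_path, peptide_path,
                             kaks_path = NULL, domain_path = NULL) {
  genes <- read_tsv_quiet(gene_path, readr::cols(.default = readr::col_character()))
  check_columns(genes, c("gene_id", "species"), "gene table")
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1]
    stop(sprintf("duplicate gene_id in gene table: %s", dup), call. = FALSE)
  }

  pep <- read_tsv_quiet(peptide_path, readr::cols(
    gene_id = readr::col_character(),
    peptide_id = readr::col_character(),
    status = readr::col_character(),
    peptide_length = readr::col_double()
  ))
  check_columns(pep, c("gene_id", "peptide_id", "status", "peptide_length"),
                "peptide table")
  if (anyDuplicated(pep$peptide_id)) {
    dup <- pep$peptide_id[duplicated(pep$peptide_id)][1]
    stop(sprintf("duplicate peptide_id: %s", dup), call. = FALSE)
  }
  bad <- setdiff(unique(pep$status), c("known", "novel"))
  if (length(bad)) {
    stop(sprintf("unknown peptide status token(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(pep$peptide_length <= 0 | is.na(pep$peptide_length))) {
    stop("peptide_length must be a positive number", call. = FALSE)
  }
  orphans <- setdiff(unique(pep$gene_id), genes$gene_id)
  if (length(orphans)) {
    warning(sprintf("%d peptide gene_id(s) absent from the gene table were dropped",
                    length(orphans)), call. = FALSE)
    pep <- dplyr::filter(pep, .data$gene_id %in% genes$gene_id)
  }

  agg <- pep |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      known_peptide_count = sum(.data$status == "known"),
      all_peptide_count = dplyr::n(),
      longest_known_peptide_length = if (any(.data$status == "known")) {
        max(.data$peptide_length[.data$status == "known"])
      } else NA_real_,
      .groups = "drop"
    )

  out <- genes |>
    dplyr::left_join(agg, by = "gene_id") |>
    dplyr::mutate(
      known_peptide_count = dplyr::coalesce(.data$known_peptide_count, 0L),
      all_peptide_count = dplyr::coalesce(.data$all_peptide_count, 0L)
    )

  if (!is.null(kaks_path)) {
    kaks <- read_tsv_quiet(kaks_path, readr::cols(
      gene_id = readr::col_character(),
      ka = readr::col_double(), ks = readr::col_double()
    ))
    check_columns(kaks, c("gene_id", "ka", "ks"), "Ka/Ks table")
    out <- dplyr::left_join(out, kaks, by = "gene_id")
  } else {
    out$ka <- NA_real_
    out$ks <- NA_real_
  }
  if (!is.null(domain_path)) {
    dom <- read_tsv_quiet(domain_path, readr::cols(
      gene_id = readr::col_character(),
      domain_count = readr::col_integer()
    ))
    check_columns(dom, c("gene_id", "domain_count"), "domain table")
    out <- dplyr::left_join(out, dom, by = "gene_id")
  } else {
    out$domain_count <- NA_integer_
  }

  out |>
    dplyr::select("gene_id", "species", "known_peptide_count",
                  "all_peptide_count", "longest_known_peptide_length",
                  "domain_count", "ka", "ks") |>
    dplyr::arrange(.data$gene_id)
}

#' Read a flat GO category table
#'
#' @param path TSV with columns `gene_id`, `ontology` (`MF` or `BP`),
#'   `category` (top-level category label).
#' @return Tibble `gene_id`, `ontology`, `category`, deduplicated on the
#'   triple and sorted.
#' @export
read_go_table <- function(path) {
  go <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  check_columns(go, c("gene_id", "ontology", "category"), "GO table")
  bad <- setdiff(unique(go$ontology), c("MF", "BP"))
  if (length(bad)) {
    stop(sprintf("unknown ontology token(s): %s (expected MF or BP)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  go |>
    dplyr::distinct(.data$gene_id, .data$ontology, .data$category) |>
    dplyr::arrange(.data$gene_id, .data$ontology, .data$category)
}

#' Canonicalise a paralog-pair table
#'
#' Orders each pair so `gene_a < gene_b` (swapping the two directional
#' identities along with the ids), drops exact mirrored duplicates, and
#' validates identities and self-pairs.
#'
#' @keywords internal
#' @noRd
canonicalise_pairs <- function(pairs) {
  swap <- pairs$gene_a > pairs$gene_b
  out <- pairs
  out$gene_a <- ifelse(swap, pairs$gene_b, pairs$gene_a)
  out$gene_b <- ifelse(swap, pairs$gene_a, pairs$gene_b)
  out$identity_a <- ifelse(swap, pairs$identity_b, pairs$identity_a)
  out$identity_b <- ifelse(swap, pairs$identity_a, pairs$identity_b)
  out <- dplyr::distinct(out)
  key <- paste(out$gene_a, out$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("conflicting duplicate rows for pair (%s)",
                 gsub("\r", ", ", dup)), call. = FALSE)
  }
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

#' Read a paralog-pair table
#'
#' Each row is an undirected gene pair with the two directional percent
#' identities Ensembl-style paralog exports carry (identity of the aligned
#' region relative to each gene's own sequence). Mirrored rows are collapsed;
#' pairs are returned in canonical `gene_a < gene_b` order.
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `identity_a`,
#'   `identity_b` (percent, in \[0, 100\]).
#' @return Tibble of unique unordered pairs.
#' @export
read_paralog_pairs <- function(path) {
  pairs <- read_tsv_quiet(path, readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    identity_a = readr::col_double(),
    identity_b = readr::col_double()
  ))
  check_columns(pairs, c("gene_a", "gene_b", "identity_a", "identity_b"),
                "paralog-pair table")
  validate_pairs(pairs)
}

#' Validate an in-memory paralog-pair tibble
#'
#' @param pairs Tibble with `gene_a`, `gene_b`, `identity_a`, `identity_b`.
#' @return The canonicalised pair tibble.
#' @export
validate_pairs <- function(pairs) {
  check_columns(pairs, c("gene_a", "gene_b", "identity_a", "identity_b"),
                "paralog-pair table")
  ident <- c(pairs$identity_a, pairs$identity_b)
  if (anyNA(ident) || any(ident < 0) || any(ident > 100)) {
    stop("percent identities must lie in [0, 100]", call. = FALSE)
  }
  if (any(pairs$gene_a == pairs$gene_b)) {
    g <- pairs$gene_a[pairs$gene_a == pairs$gene_b][1]
    stop(sprintf("self-pair not allowed: %s", g), call. = FALSE)
  }
  canonicalise_pairs(tibble::as_tibble(pairs))
}

# PSL column order (BLAT, 21 columns)
PSL_COLS <- c("matches", "misMatches", "repMatches", "nCount",
              "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
              "strand", "qName", "qSize", "qStart", "qEnd",
              "tName", "tSize", "tStart", "tEnd",
              "blockCount", "blockSizes", "qStarts", "tStarts")

#' Read BLAT PSL alignments of ESTs against transcript isoforms
#'
#' Standard 21-column PSL, with or without the 5-line `psLayout` header.
#' Only the fields the EST pipeline uses are kept: `matches`, `misMatches`,
#' query name/size and target name.
#'
#' @param path Path to a PSL file.
#' @return Tibble `est_id`, `isoform_id`, `est_length`, `matches`,
#'   `mismatches`, one row per alignment.
#' @export
read_psl <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  offset <- 0L
  if (length(lines) && startsWith(lines[1], "psLayout")) {
    # 5-line header: psLayout line, blank, two column-name lines, dashes
    offset <- 5L
    lines <- lines[-seq_len(min(5L, length(lines)))]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(est_id = character(), isoform_id = character(),
                          est_length = integer(), matches = integer(),
                          mismatches = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    i <- which(nf != 21L)[1]
    stop(sprintf("PSL line %d has %d columns (expected 21)",
                 i + offset, nf[i]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric %s field on PSL line %d: '%s'",
                   name, i + offset, m[i, col]), call. = FALSE)
    }
    v
  }
  tibble::tibble(
    est_id = m[, 10],
    isoform_id = m[, 14],
    est_length = as.integer(num(11, "qSize")),
    matches = as.integer(num(1, "matches")),
    mismatches = as.integer(num(2, "misMatches"))
  )
}

#' Read EST alignments from a simple TSV dialect
#'
#' Column-named equivalent of the PSL fields the pipeline consumes.
#'
#' @param path TSV with columns `est_id`, `isoform_id`, `est_length`,
#'   `matches`, `mismatches`.
#' @return Tibble with those columns.
#' @export
read_est_tsv <- function(path) {
  est <- read_tsv_quiet(path, readr::cols(
    est_id = readr::col_character(),
    isoform_id = readr::col_character(),
    est_length = readr::col_integer(),
    matches = readr::col_integer(),
    mismatches = readr::col_integer()
  ))
  check_columns(est, c("est_id", "isoform_id", "est_length",
                       "matches", "mismatches"), "EST alignment table")
  est
}

#' Write EST alignments as a 21-column PSL file
#'
#' Fields the pipeline does not model (inserts, strand, block structure)
#' are written as canonical single-block values, so [read_psl()] round-trips
#' the modelled fields exactly.
#'
#' @param alignments Tibble as returned by [read_psl()].
#' @param path Output path.
#' @param header Write the 5-line `psLayout` header. Default `FALSE`.
#' @export
write_psl <- function(alignments, path, header = FALSE) {
  a <- alignments
  span <- a$matches + a$mismatches
  rows <- paste(a$matches, a$mismatches, 0L, 0L, 0L, 0L, 0L, 0L, "+",
                a$est_id, a$est_length, 0L, span,
                a$isoform_id, span, 0L, span,
                1L, paste0(span, ","), "0,", "0,",
                sep = "\t")
  if (header) {
    hdr <- c("psLayout version 3", "",
             paste(PSL_COLS[1:9], collapse = "\t"),
             paste(PSL_COLS[10:21], collapse = "\t"),
             strrep("-", 80))
    rows <- c(hdr, rows)
  }
  readr::write_lines(rows, path)
  invisible(path)
}

#' Read an isoform-to-gene map
#'
#' @param path TSV with columns `isoform_id`, `gene_id`.
#' @return Tibble `isoform_id`, `gene_id`.
#' @export
read_isoform_map <- function(path) {
  map <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  check_columns(map, c("isoform_id", "gene_id"), "isoform map")
  if (anyDuplicated(map$isoform_id)) {
    dup <- map$isoform_id[duplicated(map$isoform_id)][1]
    stop(sprintf("isoform_id mapped to more than one gene: %s", dup),
         call. = FALSE)
  }
  dplyr::arrange(map, .data$isoform_id)
}

#' Write a simulated dataset as the package's TSV/PSL input dialects
#'
#' Emits `genes.tsv`, `peptides.tsv`, `pairs.tsv`, `kaks.tsv`,
#' `domains.tsv`, `go.tsv`, `est.psl`, `isoform_to_gene.tsv` and a
#' `truth.json` sidecar into `dir`, such that the `read_*` readers
#' reproduce the in-memory tables exactly.
#'
#' @param sim A `dupsplice_sim` object from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "dupsplice_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(sim$genes[, c("gene_id", "species")], p("genes.tsv"))
  readr::write_tsv(sim$peptides, p("peptides.tsv"))
  readr::write_tsv(sim$pairs, p("pairs.tsv"))
  readr::write_tsv(sim$kaks, p("kaks.tsv"))
  readr::write_tsv(sim$domains, p("domains.tsv"))
  readr::write_tsv(sim$go, p("go.tsv"))
  write_psl(sim$est, p("est.psl"))
  readr::write_tsv(sim$isoform_to_gene, p("isoform_to_gene.tsv"))
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
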