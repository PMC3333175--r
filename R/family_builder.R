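#' Qualify paralog pairs at an identity criterion
#'
#' A pair qualifies when at least one gene aligns to the other above the
#' criterion: `max(identity_a, identity_b) > criterion`, strictly. Boundary
#' values equal to the criterion do not qualify.
#'
#' @param pairs Tibble of paralog pairs (see [read_paralog_pairs()]).
#' @param criterion Percent identity threshold in (0, 100).
#' @return Tibble `gene_a`, `gene_b` of qualified unordered pairs in
#'   canonical order.
#' @export
#' @examples
#' pairs <- tibble::tibble(gene_a = c("g1", "g1"), gene_b = c("g2", "g3"),
#'                         identity_a = c(95, 45), identity_b = c(91, 50))
#' qualify_pairs(pairs, 90)
qualify_pairs <- function(pairs, criterion) {
  stopifnot(is.numeric(criterion), length(criterion) == 1,
            criterion > 0, criterion < 100)
  pairs <- validate_pairs(pairs)
  pairs |>
    dplyr::filter(pmax(.data$identity_a, .data$identity_b) > criterion) |>
    dplyr::select("gene_a", "gene_b")
}

# Union-find with path halving; ids are indices into `universe`.
#' @noRd
uf_components <- function(edges_a, edges_b, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster qualified pairs into gene families by single linkage
#'
#' Families are the connected components (size at least 2) of the graph
#' whose vertices are the gene universe and whose edges are the qualified
#' pairs: two pairs belong to one family as soon as they share a gene.
#' Genes touching no qualified pair are singletons.
#'
#' @param qualified Tibble `gene_a`, `gene_b` from [qualify_pairs()].
#' @param universe Character vector of analyzed gene ids.
#' @return Tibble, one row per gene in `universe`, sorted by `gene_id`:
#'   `gene_id`, `family_id` (lexicographically smallest member; `NA` for
#'   singletons), `family_size` (1 for singletons), `is_duplicate`.
#' @export
build_families <- function(qualified, universe) {
  universe <- sort(unique(as.character(universe)))
  n <- length(universe)
  ia <- match(qualified$gene_a, universe)
  ib <- match(qualified$gene_b, universe)
  if (anyNA(ia) || anyNA(ib)) {
    g <- c(qualified$gene_a[is.na(ia)], qualified$gene_b[is.na(ib)])[1]
    stop(sprintf("qualified pair references gene outside the universe: %s", g),
         call. = FALSE)
  }
  root <- uf_components(ia, ib, n)
  # smallest member id per component: universe is sorted, so min index wins
  comp_min <- stats::ave(seq_len(n), root, FUN = min)
  size <- stats::ave(rep(1L, n), root, FUN = sum)
  tibble::tibble(
    gene_id = universe,
    family_id = ifelse(size >= 2L, universe[comp_min], NA_character_),
    family_size = as.integer(size),
    is_duplicate = size >= 2L
  )
}

#' Sweep family partitions across all identity criteria
#'
#' Runs [qualify_pairs()] + [build_families()] once per configured
#' criterion. Because qualification is monotone in the threshold, the
#' duplicate set at a higher criterion is always a subset of the duplicate
#' set at a lower one, and each high-criterion family lies inside a single
#' low-criterion family.
#'
#' @param pairs Paralog-pair tibble.
#' @param universe Character vector of analyzed gene ids.
#' @param config A [run_config()].
#' @return Tibble: `criterion`, `gene_id`, `family_id`, `family_size`,
#'   `size_bin`, `is_duplicate`.
#' @export
sweep_partitions <- function(pairs, universe, config = run_config()) {
  stopifnot(inherits(config, "dupsplice_config"))
  pairs <- validate_pairs(pairs)
  purrr::map_dfr(config$identity_criteria, function(crit) {
    q <- qualify_pairs(pairs, crit)
    build_families(q, universe) |>
      dplyr::mutate(criterion = crit, .before = 1) |>
      dplyr::mutate(size_bin = bin_family_size(.data$family_size, config),
                    .after = "family_size")
  })
}
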