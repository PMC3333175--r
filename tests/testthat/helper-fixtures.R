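# Shared fixtures and independent oracles, built in code.

group_levels <- c("A_F", "N_F", "MIXED_F", "A_S", "N_S")

# Eight-gene toy: two families + four singletons with hand-assigned AS.
# At criterion 50: family {a1,a2} (both AS -> A_F), family {b1,b2}
# (b1 AS, b2 not -> MIXED_F); singletons s1 (AS), s2, s3, s4 (no AS).
toy8_records <- function() {
  tibble::tibble(
    gene_id = c("a1", "a2", "b1", "b2", "s1", "s2", "s3", "s4"),
    species = "toy",
    known_peptide_count = c(3L, 2L, 2L, 1L, 4L, 1L, 1L, 1L),
    all_peptide_count = c(3L, 2L, 3L, 1L, 4L, 1L, 2L, 1L),
    longest_known_peptide_length = c(300, 250, 410, 120, 520, 90, 210, 310),
    domain_count = c(4L, 2L, 1L, 0L, 6L, 0L, 1L, 2L),
    ka = c(0.10, 0.05, 0.30, 0.24, 0.02, 0.40, NA, 0.10),
    ks = c(0.20, 0.25, 0.50, 0.40, 0.10, 0, 0.30, 0.50)
  )
}

toy8_pairs <- function() {
  tibble::tibble(
    gene_a = c("a1", "b1"),
    gene_b = c("a2", "b2"),
    identity_a = c(80, 65),
    identity_b = c(76, 70)
  )
}

# Brute-force single-linkage oracle: repeated pairwise merging to fixpoint.
oracle_families <- function(edges, universe) {
  groups <- as.list(universe)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      ia <- which(vapply(groups, function(g) edges$gene_a[i] %in% g, logical(1)))
      ib <- which(vapply(groups, function(g) edges$gene_b[i] %in% g, logical(1)))
      if (ia != ib) {
        groups[[ia]] <- union(groups[[ia]], groups[[ib]])
        groups[[ib]] <- NULL
      }
    }
  }
  out <- lapply(groups, sort)
  out[order(vapply(out, `[`, character(1), 1))]
}

partition_as_sets <- function(partition) {
  fams <- split(partition$gene_id, partition$family_id)
  singles <- partition$gene_id[!partition$is_duplicate]
  all <- c(unname(lapply(fams, sort)), as.list(sort(singles)))
  all[order(vapply(all, `[`, character(1), 1))]
}

random_edge_table <- function(n, p) {
  universe <- sprintf("g%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p
  tibble::tibble(gene_a = universe[idx[keep, 1]],
                 gene_b = universe[idx[keep, 2]])
}

# Textbook Pearson statistic, written independently of pearson_chisq().
oracle_chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Hand-built EST alignment fixture: exactly records 1-4 pass the
# length >= 100 / identity >= 0.95 filter.
est_fixture <- function() {
  tibble::tibble(
    est_id     = sprintf("E%02d", 1:10),
    isoform_id = c("T1", "T2", "T1", "T3", "T2", "T1", "T4", "T2", "T3", "T1"),
    est_length = c(100L, 250L, 400L, 150L, 99L, 100L, 500L, 120L, 300L, 101L),
    matches    = c(95L, 240L, 380L, 145L, 95L, 90L, 450L, 100L, 270L, 0L),
    mismatches = c(5L, 8L, 20L, 5L, 3L, 10L, 50L, 13L, 32L, 0L)
  )
  # pass: E01 (0.95 exactly, len 100), E02 (0.968), E03 (0.95), E04 (0.967)
  # fail: E05 (len 99), E06 (0.90), E07 (0.90), E08 (0.885), E09 (0.894),
  #       E10 (no aligned columns -> skipped with warning)
}

small_params <- function(n_genes = 600, seed = 11, ...) {
  synth_params(n_genes = n_genes, seed = seed, ...)
}

sim_records <- function(sim) {
  peptides_to_records(sim$genes, sim$peptides, kaks = sim$kaks,
                      domains = sim$domains)
}
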