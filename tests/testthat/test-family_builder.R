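test_that("pair qualification uses the max directional identity, strictly", {
  pairs <- tibble::tibble(
    gene_a = c("g1", "g1", "g4"), gene_b = c("g2", "g3", "g5"),
    identity_a = c(95, 45, 10), identity_b = c(91, 50, 11))
  q90 <- qualify_pairs(pairs, 90)
  expect_equal(nrow(q90), 1L)
  expect_equal(q90$gene_a, "g1"); expect_equal(q90$gene_b, "g2")
  # max(45, 50) = 50 > 44 qualifies
  expect_equal(nrow(qualify_pairs(pairs, 44)), 2L)
  # boundary: 50 is not > 50
  expect_equal(nrow(qualify_pairs(pairs, 50)), 1L)
})

test_that("single-linkage families are the connected components", {
  q <- tibble::tibble(gene_a = c("a", "b", "d"), gene_b = c("b", "c", "e"))
  part <- build_families(q, letters[1:6])
  expect_equal(part$family_id[part$gene_id %in% c("a", "b", "c")],
               rep("a", 3))
  expect_equal(part$family_id[part$gene_id %in% c("d", "e")], rep("d", 2))
  expect_false(part$is_duplicate[part$gene_id == "f"])
  expect_equal(part$family_size, c(3L, 3L, 3L, 2L, 2L, 1L))

  empty <- build_families(q[0, ], letters[1:6])
  expect_true(all(!empty$is_duplicate))
  expect_true(all(is.na(empty$family_id)))

  expect_error(build_families(tibble::tibble(gene_a = "a", gene_b = "z"),
                              letters[1:6]), "z")
})

test_that("clustering matches independent oracles on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(401)
  for (i in 1:60) {
    n <- sample(3:50, 1)
    edges <- random_edge_table(n, 0.1)
    universe <- sprintf("g%02d", seq_len(n))
    part <- build_families(edges, universe)
    expect_identical(partition_as_sets(part), oracle_families(edges, universe))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = universe)
    comp <- igraph::components(g)
    expect_equal(sort(as.integer(table(part$family_id[part$is_duplicate]))),
                 sort(unname(comp$csize[comp$csize >= 2])))
  }
})

test_that("partitions are deterministic and row-order independent", {
  sim <- simulate_dataset(small_params(n_genes = 200, seed = 9))
  universe <- sim$genes$gene_id
  cfg <- run_config()
  p1 <- sweep_partitions(sim$pairs, universe, cfg)
  p2 <- sweep_partitions(sim$pairs[sample.int(nrow(sim$pairs)), ], universe, cfg)
  expect_identical(p1, p2)
  expect_identical(p1, sweep_partitions(sim$pairs, sample(universe), cfg))
})

test_that("criterion sweep is monotone: nesting and coarsening", {
  sim <- simulate_dataset(small_params(n_genes = 400, seed = 13))
  universe <- sim$genes$gene_id
  cfg <- run_config()
  sw <- sweep_partitions(sim$pairs, universe, cfg)
  crits <- cfg$identity_criteria
  for (i in seq_along(crits)[-1]) {
    lo <- sw[sw$criterion == crits[i - 1], ]
    hi <- sw[sw$criterion == crits[i], ]
    # duplicates at the higher criterion are a subset of those at the lower
    expect_true(all(hi$gene_id[hi$is_duplicate] %in% lo$gene_id[lo$is_duplicate]))
    # each high-criterion family lies inside one low-criterion family
    joined <- merge(hi[hi$is_duplicate, c("gene_id", "family_id")],
                    lo[, c("gene_id", "family_id")], by = "gene_id")
    n_lo_per_hi <- tapply(joined$family_id.y, joined$family_id.x,
                          function(x) length(unique(x)))
    expect_true(all(n_lo_per_hi == 1L))
  }
  # every gene appears exactly once per criterion
  expect_true(all(table(sw$criterion) == length(universe)))
  expect_equal(anyDuplicated(sw[, c("criterion", "gene_id")]), 0L)
})

test_that("family sizes map to the documented bins", {
  cfg <- run_config()
  expect_equal(as.character(bin_family_size(c(1, 4, 5, 7, 8, 100), cfg)),
               c("singleton", "2-4", "5-7", "5-7", "8+", "8+"))
  expect_error(bin_family_size(0, cfg), ">= 1")
  custom <- run_config(family_size_breaks = c(2, 3))
  expect_equal(size_bin_labels(custom), c("singleton", "2", "3+"))
})
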