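test_that("generation is deterministic under the seed", {
  s1 <- simulate_dataset(small_params(n_genes = 300, seed = 7))
  s2 <- simulate_dataset(small_params(n_genes = 300, seed = 7))
  expect_identical(s1[names(s1) != "truth"], s2[names(s2) != "truth"])
  expect_identical(s1$truth$genes, s2$truth$genes)
  s3 <- simulate_dataset(small_params(n_genes = 300, seed = 8))
  expect_false(identical(s1$pairs, s3$pairs))
})

test_that("generated tables satisfy the reader invariants", {
  sim <- simulate_dataset(small_params(n_genes = 500, seed = 17))
  # paralog pairs: canonical, unique, no self-pairs, identities in range
  expect_identical(validate_pairs(sim$pairs), sim$pairs)
  expect_true(all(sim$pairs$gene_a < sim$pairs$gene_b))
  expect_true(all(sim$pairs$identity_a >= 0 & sim$pairs$identity_a <= 100))
  # peptides unique, statuses legal, counts consistent with truth
  expect_equal(anyDuplicated(sim$peptides$peptide_id), 0L)
  expect_true(all(sim$peptides$status %in% c("known", "novel")))
  rec <- sim_records(sim)
  truth <- sim$truth$genes
  expect_equal(rec$known_peptide_count[match(truth$gene_id, rec$gene_id)],
               as.integer(truth$known_peptide_count))
  # every gene has at least one known peptide (AS status defined everywhere)
  expect_true(all(rec$known_peptide_count >= 1))
})

test_that("degenerate planting yields the extreme AS split", {
  params <- small_params(n_genes = 400, seed = 19, p_singleton_as = 1,
                         beta0 = -30, beta1 = 0, beta2 = 0)
  sim <- simulate_dataset(params)
  genes <- sim_records(sim)
  rep <- run_pipeline(genes, sim$pairs,
                      config = run_config(identity_criteria = c(10, 50, 90)))
  ov <- tidy(rep, "overall")
  expect_true(all(ov$as_prop_duplicate == 0))
  # singletons at high criteria include invisible family members (AS prob ~ 0),
  # so only the fully inclusive low criterion is guaranteed pure
  expect_equal(ov$as_prop_singleton[ov$criterion == 10],
               as_proportion(tidy(rep, "groups") |>
                               dplyr::filter(criterion == 10, !is_duplicate) |>
                               dplyr::pull(as_status)))
  sing10 <- tidy(rep, "groups") |>
    dplyr::filter(criterion == 10, family_size == 1,
                  gene_id %in% sim$truth$genes$gene_id[sim$truth$genes$family_size == 1])
  expect_true(all(sing10$as_status))
})

test_that("a flat AS model gives equal expectations across bins and criteria", {
  params <- small_params(p_singleton_as = 0.5, beta0 = 0, beta1 = 0, beta2 = 0)
  # logistic(0) = 0.5 for every family, matching the singleton rate
  exp <- planted_expectations(params, run_config(identity_criteria = c(10, 50, 90)),
                              n_age_grid = 60)
  expect_true(all(abs(exp$expected_as_proportion - 0.5) < 1e-10))
})

test_that("pair visibility matches a Monte-Carlo oracle", {
  params <- small_params()
  set.seed(61)
  for (case in list(list(a = 0.05, t = 90), list(a = 0.3, t = 50),
                    list(a = 0.85, t = 10))) {
    n <- 40000
    base <- 100 * (1 - case$a) + rnorm(n, 0, params$sigma_id)
    ia <- base + rnorm(n, 0, params$sigma_dir)
    ib <- base + rnorm(n, 0, params$sigma_dir)
    mc <- mean(pmax(ia, ib) > case$t)
    closed <- pair_visibility(case$a, case$t, params)
    expect_lt(abs(mc - closed), 3 * sqrt(closed * (1 - closed) / n) + 1e-6)
  }
})

test_that("component-size distributions are exact for partially visible cliques", {
  # closed form vs enumeration over all edge subsets of a 4-clique
  k <- 4; p <- 0.3
  idx <- utils::combn(k, 2)
  m <- ncol(idx)
  sizes <- numeric(k)
  for (code in 0:(2^m - 1)) {
    present <- as.logical(bitwAnd(code, 2^(0:(m - 1))))
    prob <- prod(ifelse(present, p, 1 - p))
    edges <- tibble::tibble(gene_a = sprintf("v%d", idx[1, present]),
                            gene_b = sprintf("v%d", idx[2, present]))
    part <- build_families(edges, sprintf("v%d", 1:k))
    s <- part$family_size[part$gene_id == "v1"]
    sizes[s] <- sizes[s] + prob
  }
  expect_equal(component_size_dist(k, p), sizes, tolerance = 1e-12)
  expect_equal(sum(component_size_dist(9, 0.62)), 1, tolerance = 1e-12)
})

test_that("Monte-Carlo AS proportions agree with the closed-form expectations", {
  params <- small_params(n_genes = 10000, seed = 23)
  cfg <- run_config(identity_criteria = c(10, 90))
  sim <- simulate_dataset(params)
  genes <- sim_records(sim)
  rep <- run_pipeline(genes, sim$pairs, config = cfg)
  exp <- planted_expectations(params, cfg)
  obs <- tidy(rep, "proportions") |>
    dplyr::mutate(size_bin = as.character(size_bin)) |>
    dplyr::inner_join(exp, by = c("criterion", "size_bin"))
  z <- (obs$as_proportion - obs$expected_as_proportion) /
    sqrt(obs$expected_as_proportion * (1 - obs$expected_as_proportion) / obs$n_genes)
  expect_true(all(abs(z) < 3))
})
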