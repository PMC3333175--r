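test_that("AS proportion and isoform means are plain count ratios", {
  expect_equal(as_proportion(c(TRUE, TRUE, TRUE, FALSE)), 0.75)
  expect_equal(as_proportion(rep(TRUE, 5)), 1)
  expect_equal(as_proportion(rep(FALSE, 5)), 0)
  expect_error(as_proportion(logical(0)), "empty")

  expect_equal(mean_isoform_count(c(1L, 2L, 5L)), 8 / 3)
  expect_equal(mean_isoform_count(rep(1L, 4)), 1)
  expect_equal(mean_isoform_count(c(1L, 2L, 5L), as_only = TRUE), 3.5)
  expect_error(mean_isoform_count(integer(0)), "empty")
})

test_that("sampled AS proportion recovers a planted binomial rate", {
  set.seed(71)
  n <- 5000; p <- 0.65
  draws <- stats::runif(n) < p
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(as_proportion(draws) - p), 3 * se)
})

test_that("chi-squared matches the textbook formula and behaves at the null", {
  flat <- pearson_chisq(matrix(10, 2, 2), correction = FALSE)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  set.seed(29)
  for (i in 1:200) {
    tab <- matrix(stats::rpois(4, 30) + 1, 2, 2)
    got <- pearson_chisq(tab, correction = FALSE)
    expect_equal(got$statistic, oracle_chisq_stat(tab), tolerance = 1e-12)
    # the continuity correction can only shrink the statistic
    expect_lte(pearson_chisq(tab, correction = TRUE)$statistic, got$statistic)
    expect_gte(pearson_chisq(tab, correction = TRUE)$p_value, got$p_value)
  }

  expect_error(pearson_chisq(matrix(c(0, 0, 5, 5), 2, 2)), "degenerate")
})

test_that("the proportion sweep reproduces a hand-computed toy", {
  # one family {a,b} both AS at criterion 50; singletons c (AS), d, e, f
  pairs <- tibble::tibble(gene_a = "a", gene_b = "b",
                          identity_a = 80, identity_b = 70)
  universe <- letters[1:6]
  cfg <- run_config(identity_criteria = 50)
  sw <- sweep_partitions(pairs, universe, cfg)
  as_calls <- tibble::tibble(gene_id = universe,
                             isoform_count = c(2L, 3L, 2L, 1L, 1L, 1L),
                             as_status = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ps <- proportion_sweep(sw, as_calls, cfg)
  expect_equal(ps$overall$as_prop_duplicate, 1)
  expect_equal(ps$overall$as_prop_singleton, 0.25)
  by_bin <- ps$by_bin
  expect_equal(by_bin$n_genes[by_bin$size_bin == "2-4"], 2L)
  # empty bins are emitted with zero counts and NA statistics
  expect_equal(by_bin$n_genes[by_bin$size_bin == "8+"], 0L)
  expect_true(is.na(by_bin$as_proportion[by_bin$size_bin == "8+"]))
})

test_that("duplicate AS proportion is the size-weighted mean of bin proportions", {
  sim <- simulate_dataset(small_params(n_genes = 800, seed = 31))
  genes <- sim_records(sim)
  cfg <- run_config()
  sw <- sweep_partitions(sim$pairs, genes$gene_id, cfg)
  ps <- proportion_sweep(sw, classify_as(genes, cfg), cfg)
  for (crit in cfg$identity_criteria) {
    bins <- ps$by_bin[ps$by_bin$criterion == crit &
                        ps$by_bin$size_bin != "singleton" &
                        ps$by_bin$n_genes > 0, ]
    ov <- ps$overall[ps$overall$criterion == crit, ]
    expect_equal(sum(bins$as_proportion * bins$n_genes) / sum(bins$n_genes),
                 ov$as_prop_duplicate)
    # count conservation across bins
    expect_equal(sum(ps$by_bin$n_genes[ps$by_bin$criterion == crit]),
                 nrow(genes))
  }
})

test_that("adding an AS gene never decreases a group's AS proportion", {
  set.seed(37)
  for (i in 1:50) {
    status <- stats::runif(sample(2:30, 1)) < stats::runif(1)
    expect_gte(as_proportion(c(status, TRUE)), as_proportion(status))
  }
})

test_that("Ka/Ks ratios, exclusions and quartiles follow the conventions", {
  rec <- toy8_records()
  pairs <- toy8_pairs()
  cfg <- run_config(identity_criteria = 50)
  sw <- sweep_partitions(pairs, rec$gene_id, cfg)
  groups <- classify_groups(sw, classify_as(rec, cfg))
  kk <- ka_ks_summary(groups, rec)
  # A_F = {a1, a2}: ratios 0.5 and 0.2
  af <- kk[kk$group == "A_F", ]
  expect_equal(af$n, 2L)
  expect_equal(af$mean, mean(c(0.5, 0.2)))
  # s2 has ks = 0 (excluded), s3 has missing ka (excluded)
  ns <- kk[kk$group == "N_S", ]
  expect_equal(ns$excluded_kaks_count, 2L)
  expect_equal(ns$n, 1L)
  # type-7 quartiles on a 5-point ratio vector
  q <- stats::quantile(c(0.1, 0.2, 0.3, 0.4, 0.5), c(.25, .5, .75), type = 7)
  expect_equal(unname(q), c(0.2, 0.3, 0.4))
})

test_that("feature summaries recover a planted length ordering", {
  rec <- toy8_records()
  cfg <- run_config(identity_criteria = 50)
  sw <- sweep_partitions(toy8_pairs(), rec$gene_id, cfg)
  groups <- classify_groups(sw, classify_as(rec, cfg))
  fs <- feature_summary(groups, rec)
  af <- fs$length[fs$length$group == "A_F", ]
  expect_equal(af$mean, 275)
  expect_equal(af$n, 2L)
  # MIXED_F excluded from four-group comparisons
  expect_false("MIXED_F" %in% fs$length$group)
  # domain histogram frequencies sum to 1 per group
  sums <- tapply(fs$domains$frequency,
                 paste(fs$domains$criterion, fs$domains$group), sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # planted model: AS duplicated genes longest on average
  sim <- simulate_dataset(small_params(n_genes = 1500, seed = 41))
  genes <- sim_records(sim)
  cfg10 <- run_config(identity_criteria = 10)
  sw10 <- sweep_partitions(sim$pairs, genes$gene_id, cfg10)
  g10 <- classify_groups(sw10, classify_as(genes, cfg10))
  len <- feature_summary(g10, genes)$length
  expect_gt(len$mean[len$group == "A_F"], len$mean[len$group == "N_S"])
})

test_that("GO distributions normalise and apply the 1% 'others' rule", {
  # counts A:50, B:49, C:1 -> C sits exactly at 1% and is tallied as others
  groups <- tibble::tibble(
    criterion = 10, gene_id = sprintf("g%03d", 1:100),
    is_duplicate = FALSE, as_status = TRUE, group = factor("A_S", group_levels))
  go <- tibble::tibble(
    gene_id = groups$gene_id, ontology = "MF",
    category = rep(c("A", "B", "C"), c(50, 49, 1)))
  d <- go_distribution(groups, go, "MF")
  expect_setequal(d$category, c("A", "B", "others"))
  expect_equal(d$proportion[d$category == "others"], 0.01)
  expect_equal(sum(d$proportion), 1)

  # single category degenerates to proportion 1
  d1 <- go_distribution(groups, dplyr::mutate(go, category = "only"), "MF")
  expect_equal(d1$proportion, 1)

  # randomized inputs: proportions sum to 1 per group
  sim <- simulate_dataset(small_params(n_genes = 400, seed = 43))
  genes <- sim_records(sim)
  cfg <- run_config(identity_criteria = c(10, 90))
  sw <- sweep_partitions(sim$pairs, genes$gene_id, cfg)
  gg <- classify_groups(sw, classify_as(genes, cfg))
  for (ont in c("MF", "BP")) {
    dist <- go_distribution(gg, sim$go, ont)
    sums <- tapply(dist$proportion, paste(dist$criterion, dist$group), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("GO per-gene mode divides by annotated genes instead", {
  groups <- tibble::tibble(
    criterion = 10, gene_id = c("g1", "g2"),
    is_duplicate = FALSE, as_status = TRUE, group = factor("A_S", group_levels))
  go <- tibble::tibble(gene_id = c("g1", "g1", "g2"), ontology = "MF",
                       category = c("A", "B", "A"))
  d <- go_distribution(groups, go, "MF", per_gene = TRUE)
  expect_equal(d$proportion[d$category == "A"], 1)
  expect_equal(d$proportion[d$category == "B"], 0.5)
})
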