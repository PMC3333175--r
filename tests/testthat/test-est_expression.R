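test_that("the length and identity filters keep exactly the constructed set", {
  aln <- est_fixture()
  expect_warning(kept <- filter_alignments(aln), "no aligned columns")
  expect_equal(sort(kept$est_id), c("E01", "E02", "E03", "E04"))
  # inclusive bounds: identity 0.95 exactly and length 100 exactly survive
  expect_true("E01" %in% kept$est_id)
  expect_true("E03" %in% kept$est_id)
  # length 99 rejected despite high identity
  expect_false("E05" %in% kept$est_id)
  # filtering is idempotent
  expect_equal(filter_alignments(kept), kept)
})

test_that("best-match assignment is deterministic with documented tie-breaks", {
  aln <- tibble::tibble(
    est_id = c("E1", "E1", "E2", "E2"),
    isoform_id = c("T1", "T2", "T3", "T1"),
    est_length = 200L,
    matches = c(192L, 196L, 194L, 194L),
    mismatches = c(8L, 4L, 6L, 6L))
  got <- assign_best_match(filter_alignments(aln))
  expect_equal(got$isoform_id[got$est_id == "E1"], "T2")  # higher identity
  expect_equal(got$isoform_id[got$est_id == "E2"], "T1")  # tie -> smaller id
})

test_that("each surviving EST is assigned exactly once", {
  set.seed(53)
  n <- 300
  aln <- tibble::tibble(
    est_id = sprintf("E%03d", sample.int(80, n, replace = TRUE)),
    isoform_id = sprintf("T%02d", sample.int(25, n, replace = TRUE)),
    est_length = sample(80:400, n, replace = TRUE),
    matches = sample(60:380, n, replace = TRUE),
    mismatches = sample(0:30, n, replace = TRUE)) |>
    dplyr::distinct(est_id, isoform_id, .keep_all = TRUE)
  kept <- filter_alignments(aln)
  got <- assign_best_match(kept)
  expect_equal(anyDuplicated(got$est_id), 0L)
  expect_equal(nrow(got), length(unique(kept$est_id)))
  # total conservation: per-isoform hit counts sum to the assignment count
  expect_equal(sum(table(got$isoform_id)), nrow(got))
})

test_that("per-transcript EST averages count zero-hit transcripts", {
  groups <- tibble::tibble(
    criterion = 50, gene_id = c("g1", "g2"),
    is_duplicate = FALSE, as_status = c(TRUE, FALSE),
    group = factor(c("A_S", "N_S"), group_levels))
  map <- tibble::tibble(isoform_id = c("T1", "T2", "T3"),
                        gene_id = c("g1", "g1", "g2"))
  asg <- tibble::tibble(est_id = sprintf("E%d", 1:3),
                        isoform_id = c("T1", "T1", "T1"),
                        identity = 0.99, matches = 100L)
  prof <- est_profile(asg, map, groups)
  expect_equal(prof$avg_est_per_transcript[prof$group == "A_S"], 1.5)
  expect_equal(prof$avg_est_per_transcript[prof$group == "N_S"], 0)

  bad <- dplyr::mutate(asg, isoform_id = "T9")
  expect_error(est_profile(bad, map, groups), "T9")
})

test_that("planted expression ordering is recovered: no-AS families lowest", {
  sim <- simulate_dataset(small_params(n_genes = 1200, seed = 59))
  genes <- sim_records(sim)
  cfg <- run_config(identity_criteria = 10)
  rep <- run_pipeline(genes, sim$pairs, est_alignments = sim$est,
                      isoform_to_gene = sim$isoform_to_gene, config = cfg)
  prof <- rep$est
  nf <- prof$avg_est_per_transcript[prof$group == "N_F"]
  others <- prof$avg_est_per_transcript[prof$group %in% c("A_F", "A_S", "N_S")]
  expect_true(all(nf < others))
})
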