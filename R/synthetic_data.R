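#' Parameters for the synthetic duplication/AS dataset generator
#'
#' The generator plants the statistical structure the real analysis is
#' designed to detect, so that every pipeline stage is testable without
#' external downloads:
#'
#' * Genes are allocated to "units" drawn from `family_size_probs` —
#'   size-1 units are true singletons, larger units become paralog
#'   families generated as cliques of pairs.
#' * Each family has an age `a` in (0, 1] drawn from Beta(`age_shape1`,
#'   `age_shape2`) (age 0 = newest). Pairwise identities are
#'   `100 * (1 - a)` with per-pair Gaussian jitter (`sigma_id`) plus a
#'   small directional jitter (`sigma_dir`) on each of the two reported
#'   identities, clipped to \[0, 100\]. Per-pair jitter means a family can
#'   be only partially visible at a criterion, exercising single-linkage
#'   clustering on realistically ragged similarity.
#' * AS status: singletons have probability `p_singleton_as`; a member of
#'   a size-k family of age a has probability
#'   `plogis(beta0 + beta1 * a + beta2 * [k >= large_family_min])`.
#'   The defaults encode an age-positive AS gain (young duplicates are
#'   AS-poor, ancient ones AS-rich) and a large-family AS penalty.
#' * AS genes carry `2 + Poisson(isoform_lambda)` known peptides,
#'   non-AS genes exactly one; every gene also gets
#'   `Poisson(novel_lambda)` novel peptides.
#' * Ka/Ks, protein length, domain counts, GO categories and per-isoform
#'   EST hit rates are drawn from group-tilted models (see the individual
#'   parameters), planting the orderings the feature summaries recover.
#'
#' @param n_genes Number of genes (default 10000).
#' @param family_size_probs Named probability vector over unit sizes; names
#'   are the sizes. The default puts ~40% of genes in singletons and ~19%
#'   of family genes in families of size >= 8.
#' @param age_shape1,age_shape2 Beta parameters of the family-age
#'   distribution (default Beta(2, 1): most duplications ancient).
#' @param sigma_id Per-pair identity jitter sd in percent (default 5).
#' @param sigma_dir Directional identity jitter sd in percent (default 1.5).
#' @param p_singleton_as P(AS | singleton) (default 0.45).
#' @param beta0,beta1,beta2 Logistic AS model coefficients; defaults
#'   `qlogis(0.32)`, `qlogis(0.80) - qlogis(0.32)`, `-1.3`.
#' @param large_family_min Family size at which `beta2` applies (default 8).
#' @param isoform_lambda Poisson mean of extra known isoforms beyond 2 for
#'   AS genes (default 1.2).
#' @param novel_lambda Poisson mean of novel peptides per gene (default 0.3).
#' @param length_meanlog,length_sdlog Log-normal protein length baseline
#'   (defaults `log(350)`, 0.35).
#' @param length_as_mult,length_dup_mult Multiplicative length effects for
#'   AS and duplicated genes (defaults 1.35, 1.15).
#' @param ks_meanlog,ks_sdlog Log-normal Ks model (defaults `log(0.6)`, 0.35).
#' @param kaks_base Baseline Ka/Ks ratio (default 0.12).
#' @param kaks_young_dup_effect Log-scale Ka/Ks increase for a duplicate of
#'   age 0, decaying linearly with age (default 0.9).
#' @param kaks_as_effect Log-scale Ka/Ks effect of AS (default -0.35:
#'   AS genes under tighter purifying selection).
#' @param kaks_sdlog Residual log-sd of the ratio (default 0.3).
#' @param kaks_missing_rate Fraction of genes without Ka/Ks (default 0.1).
#' @param kaks_zero_ks_rate Fraction of genes given ks = 0 to exercise
#'   the undefined-ratio exclusion path (default 0.01).
#' @param domain_mu_base,domain_as_effect,domain_dup_effect,domain_size
#'   Negative-binomial domain-count model: mean
#'   `mu_base + as_effect * AS + dup_effect * dup`, dispersion
#'   `domain_size` (defaults 1.5, 1.5, 0.8, 2).
#' @param domain_missing_rate Fraction of genes without a domain count
#'   (default 0.05).
#' @param go_mf_transducer_boost Weight multiplier for the
#'   "molecular transducer activity" category in duplicated no-AS genes
#'   (default 8), planting the enrichment the GO summary recovers.
#' @param est_base_rate Poisson mean EST hits per transcript (default 1.2).
#' @param est_as_mult,est_noas_dup_mult EST-rate multipliers for AS genes
#'   and for duplicated no-AS genes (defaults 1.5, 0.5: no-AS families
#'   are the lowest-expressed group).
#' @param est_noise_rate Fraction of extra EST alignments constructed to
#'   fail the length/identity filters (default 0.05).
#' @param seed Integer seed; the dataset is a deterministic function of
#'   the parameters.
#' @return Object of class `dupsplice_params` (named list).
#' @export
synth_params <- function(n_genes = 10000,
                         family_size_probs = c(
                           "1" = 0.700, "2" = 0.135, "3" = 0.060,
                           "4" = 0.036, "5" = 0.024, "6" = 0.015,
                           "7" = 0.009, "8" = 0.009, "10" = 0.006,
                           "12" = 0.006),
                         age_shape1 = 2, age_shape2 = 1,
                         sigma_id = 5, sigma_dir = 1.5,
                         p_singleton_as = 0.45,
                         beta0 = qlogis(0.32),
                         beta1 = qlogis(0.80) - qlogis(0.32),
                         beta2 = -1.3,
                         large_family_min = 8L,
                         isoform_lambda = 1.2,
                         novel_lambda = 0.3,
                         length_meanlog = log(350), length_sdlog = 0.35,
                         length_as_mult = 1.35, length_dup_mult = 1.15,
                         ks_meanlog = log(0.6), ks_sdlog = 0.35,
                         kaks_base = 0.12,
                         kaks_young_dup_effect = 0.9,
                         kaks_as_effect = -0.35,
                         kaks_sdlog = 0.3,
                         kaks_missing_rate = 0.1,
                         kaks_zero_ks_rate = 0.01,
                         domain_mu_base = 1.5, domain_as_effect = 1.5,
                         domain_dup_effect = 0.8, domain_size = 2,
                         domain_missing_rate = 0.05,
                         go_mf_transducer_boost = 8,
                         est_base_rate = 1.2,
                         est_as_mult = 1.5, est_noas_dup_mult = 0.5,
                         est_noise_rate = 0.05,
                         seed = 1L) {
  sizes <- as.integer(names(family_size_probs))
  if (anyNA(sizes) || any(sizes < 1)) {
    stop("`family_size_probs` names must be integer sizes >= 1", call. = FALSE)
  }
  if (abs(sum(family_size_probs) - 1) > 1e-8 || any(family_size_probs < 0)) {
    stop("`family_size_probs` must be a probability vector", call. = FALSE)
  }
  if (n_genes < 1) stop("n_genes must be positive", call. = FALSE)
  if (sigma_id < 0 || sigma_dir < 0) stop("sigma parameters must be >= 0", call. = FALSE)
  p <- as.list(environment())
  structure(p, class = "dupsplice_params")
}

#' @noRd
as_probability <- function(params, family_size, age) {
  n <- max(length(family_size), length(age))
  family_size <- rep_len(family_size, n)
  age <- rep_len(age, n)
  ifelse(family_size <= 1L,
         params$p_singleton_as,
         plogis(params$beta0 + params$beta1 * age +
                  params$beta2 * (family_size >= params$large_family_min)))
}

#' @noRd
pad_id <- function(prefix, i, n) {
  sprintf(paste0(prefix, "%0", max(5L, nchar(n)), "d"), i)
}

#' Generate a complete synthetic dataset with planted structure
#'
#' Produces every input table the pipeline consumes — genes, peptides,
#' paralog pairs, Ka/Ks, domain counts, GO labels, EST alignments and the
#' isoform-to-gene map — plus a planted-truth sidecar recording family
#' membership, ages and per-gene AS probabilities. Deterministic under
#' the parameter seed.
#'
#' @param params A [synth_params()] object.
#' @return Object of class `dupsplice_sim`: a list of tibbles
#'   (`genes`, `peptides`, `pairs`, `kaks`, `domains`, `go`, `est`,
#'   `isoform_to_gene`) and a `truth` list.
#' @export
simulate_dataset <- function(params = synth_params()) {
  stopifnot(inherits(params, "dupsplice_params"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)

  n <- params$n_genes
  sizes_avail <- as.integer(names(params$family_size_probs))

  # allocate genes to units (families and singletons) until the budget is spent
  unit_sizes <- integer(0)
  remaining <- n
  while (remaining > 0) {
    feasible <- sizes_avail <= remaining
    if (!any(feasible)) break
    s <- sample(sizes_avail[feasible], 1,
                prob = params$family_size_probs[feasible])
    unit_sizes <- c(unit_sizes, s)
    remaining <- remaining - s
  }
  if (remaining > 0) unit_sizes <- c(unit_sizes, rep(1L, remaining))

  n_units <- length(unit_sizes)
  gene_id <- pad_id("G", sample.int(n), n)   # shuffled ids: family_id != insertion order
  unit_of_gene <- rep.int(seq_len(n_units), unit_sizes)
  age <- ifelse(unit_sizes >= 2L, rbeta(n_units, params$age_shape1,
                                        params$age_shape2), NA_real_)

  genes <- tibble::tibble(
    gene_id = gene_id,
    species = "synthetic",
    unit = unit_of_gene,
    family_size = unit_sizes[unit_of_gene],
    age = age[unit_of_gene]
  )

  # paralog pairs: full clique per family, identities from the family age
  fam_units <- which(unit_sizes >= 2L)
  pairs <- purrr::map_dfr(fam_units, function(u) {
    members <- sort(gene_id[unit_of_gene == u])
    idx <- utils::combn(length(members), 2)
    k <- ncol(idx)
    base <- 100 * (1 - age[u]) + rnorm(k, 0, params$sigma_id)
    tibble::tibble(
      gene_a = members[idx[1, ]],
      gene_b = members[idx[2, ]],
      identity_a = round(pmin(100, pmax(0, base + rnorm(k, 0, params$sigma_dir))), 2),
      identity_b = round(pmin(100, pmax(0, base + rnorm(k, 0, params$sigma_dir))), 2)
    )
  })
  if (nrow(pairs)) pairs <- canonicalise_pairs(pairs)

  # AS status and isoform counts
  p_as <- as_probability(params, genes$family_size, dplyr::coalesce(genes$age, 0))
  as_status <- rbinom(n, 1, p_as) == 1
  known_count <- ifelse(as_status, 2L + rpois(n, params$isoform_lambda), 1L)
  novel_count <- rpois(n, params$novel_lambda)
  is_dup <- genes$family_size >= 2L

  # peptide rows; the longest known peptide carries the planted length model
  longest <- round(rlnorm(n, params$length_meanlog +
                            log(params$length_as_mult) * as_status +
                            log(params$length_dup_mult) * is_dup,
                          params$length_sdlog))
  longest <- pmax(longest, 30L)
  pep_gene <- rep(genes$gene_id, known_count + novel_count)
  pep_status <- unlist(purrr::map2(known_count, novel_count,
                                   ~ c(rep("known", .x), rep("novel", .y))),
                       use.names = FALSE)
  pep_rank <- unlist(purrr::map2(known_count, novel_count,
                                 ~ seq_len(.x + .y)), use.names = FALSE)
  pep_longest <- rep(longest, known_count + novel_count)
  pep_length <- ifelse(pep_rank == 1L, pep_longest,
                       pmax(30L, round(pep_longest *
                                         runif(length(pep_gene), 0.5, 0.95))))
  peptides <- tibble::tibble(
    gene_id = pep_gene,
    peptide_id = pad_id("P", seq_along(pep_gene), length(pep_gene)),
    status = pep_status,
    peptide_length = as.integer(pep_length)
  )

  # Ka/Ks: young duplicates fastest, AS genes most constrained
  ks <- rlnorm(n, params$ks_meanlog, params$ks_sdlog)
  ratio <- exp(log(params$kaks_base) +
                 params$kaks_young_dup_effect * (1 - dplyr::coalesce(genes$age, 1)) * is_dup +
                 params$kaks_as_effect * as_status +
                 rnorm(n, 0, params$kaks_sdlog))
  ka <- ratio * ks
  zero_ks <- runif(n) < params$kaks_zero_ks_rate
  ks[zero_ks] <- 0
  ka[zero_ks] <- 0
  have_kaks <- runif(n) >= params$kaks_missing_rate
  kaks <- tibble::tibble(gene_id = genes$gene_id[have_kaks],
                         ka = round(ka[have_kaks], 4),
                         ks = round(ks[have_kaks], 4)) |>
    dplyr::arrange(.data$gene_id)

  # domain counts
  dom_mu <- params$domain_mu_base + params$domain_as_effect * as_status +
    params$domain_dup_effect * is_dup
  dom <- rnbinom(n, mu = dom_mu, size = params$domain_size)
  have_dom <- runif(n) >= params$domain_missing_rate
  domains <- tibble::tibble(gene_id = genes$gene_id[have_dom],
                            domain_count = as.integer(dom[have_dom])) |>
    dplyr::arrange(.data$gene_id)

  # GO labels: transducer activity boosted in duplicated no-AS genes
  mf_vocab <- c("molecular transducer activity", "catalytic activity",
                "binding", "structural molecule activity",
                "enzyme regulator activity",
                "nucleic acid binding transcription factor activity",
                "transporter activity")
  mf_base <- c(1, 5, 6, 2, 1.5, 2, 2)
  bp_vocab <- c("metabolic process", "cellular process", "signaling",
                "multicellular organismal process", "immune system process",
                "developmental process", "localization")
  bp_base <- c(5, 6, 2, 2, 1, 2, 2)
  n_mf <- 1L + rpois(n, 0.8)
  n_bp <- 1L + rpois(n, 0.8)
  draw_go <- function(i, k, vocab, base) {
    w <- base
    if (vocab[1] == "molecular transducer activity" && is_dup[i] && !as_status[i]) {
      w[1] <- w[1] * params$go_mf_transducer_boost
    }
    sample(vocab, min(k, length(vocab)), prob = w)
  }
  go <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = rep(genes$gene_id, pmin(n_mf, length(mf_vocab))),
      ontology = "MF",
      category = unlist(purrr::map(seq_len(n),
                                   ~ draw_go(.x, n_mf[.x], mf_vocab, mf_base)),
                        use.names = FALSE)),
    tibble::tibble(
      gene_id = rep(genes$gene_id, pmin(n_bp, length(bp_vocab))),
      ontology = "BP",
      category = unlist(purrr::map(seq_len(n),
                                   ~ draw_go(.x, n_bp[.x], bp_vocab, bp_base)),
                        use.names = FALSE))
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_id, .data$ontology, .data$category)

  # EST hits: transcripts are the known peptides; no-AS duplicates least expressed
  isoform_to_gene <- peptides |>
    dplyr::filter(.data$status == "known") |>
    dplyr::transmute(isoform_id = .data$peptide_id, gene_id = .data$gene_id) |>
    dplyr::arrange(.data$isoform_id)
  theta <- params$est_base_rate *
    ifelse(as_status, params$est_as_mult,
           ifelse(is_dup, params$est_noas_dup_mult, 1))
  theta_iso <- theta[match(isoform_to_gene$gene_id, genes$gene_id)]
  hits <- rpois(nrow(isoform_to_gene), theta_iso)
  hit_iso <- rep(isoform_to_gene$isoform_id, hits)
  n_hit <- length(hit_iso)
  n_noise <- rpois(1, params$est_noise_rate * max(n_hit, 1))
  noise_iso <- sample(isoform_to_gene$isoform_id, n_noise, replace = TRUE)
  est_len <- as.integer(round(runif(n_hit + n_noise, 150, 600)))
  aligned <- pmax(50L, as.integer(round(est_len * runif(n_hit + n_noise, 0.6, 1))))
  mism <- rbinom(n_hit + n_noise, aligned, 0.02)
  if (n_noise) {
    # noise records fail either the length or the identity bound
    short <- runif(n_noise) < 0.5
    idx <- n_hit + seq_len(n_noise)
    est_len[idx][short] <- as.integer(round(runif(sum(short), 40, 99)))
    mism[idx][!short] <- as.integer(round(aligned[idx][!short] * 0.10))
  }
  est <- tibble::tibble(
    est_id = pad_id("E", seq_len(n_hit + n_noise), max(n_hit + n_noise, 1)),
    isoform_id = c(hit_iso, noise_iso),
    est_length = est_len,
    matches = as.integer(aligned - mism),
    mismatches = as.integer(mism)
  )

  truth <- list(
    params = params[setdiff(names(params), "family_size_probs")],
    family_size_probs = as.list(params$family_size_probs),
    genes = tibble::tibble(
      gene_id = genes$gene_id,
      family_size = genes$family_size,
      age = genes$age,
      as_probability = p_as,
      as_status = as_status,
      known_peptide_count = known_count,
      est_rate = theta
    ),
    families = tibble::tibble(
      unit = seq_len(n_units), size = unit_sizes, age = age
    )
  )

  out <- list(
    genes = tibble::tibble(
      gene_id = genes$gene_id, species = genes$species) |>
      dplyr::arrange(.data$gene_id),
    peptides = dplyr::arrange(peptides, .data$peptide_id),
    pairs = pairs,
    kaks = kaks,
    domains = domains,
    go = go,
    est = est,
    isoform_to_gene = isoform_to_gene,
    truth = truth
  )
  structure(out, class = "dupsplice_sim")
}

#' @export
print.dupsplice_sim <- function(x, ...) {
  cat("<dupsplice_sim>\n")
  cat(sprintf("  %d genes, %d paralog pairs, %d peptides, %d EST alignments\n",
              nrow(x$genes), nrow(x$pairs), nrow(x$peptides), nrow(x$est)))
  invisible(x)
}
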