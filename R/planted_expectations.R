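#' Probability that a single planted pair qualifies at a criterion
#'
#' For a family of age `a`, a pair's two directional identities are
#' `100 (1 - a) + eps + delta_{a,b}` with `eps ~ N(0, sigma_id)` shared and
#' `delta ~ N(0, sigma_dir)` independent; the pair qualifies when the
#' larger of the two exceeds the criterion. The clipping of identities to
#' \[0, 100\] never changes qualification for criteria inside (0, 100), so
#' the unclipped Gaussian tail is exact. Computed by integrating the
#' shared-jitter density over a grid.
#'
#' @param age Numeric vector of family ages in (0, 1].
#' @param criterion Percent threshold.
#' @param params A [synth_params()].
#' @param n_eps Grid points for the shared-jitter integral.
#' @return Vector of qualification probabilities, one per age.
#' @export
pair_visibility <- function(age, criterion, params, n_eps = 121) {
  m <- 100 * (1 - age)
  if (params$sigma_id == 0) {
    both_below <- if (params$sigma_dir == 0) {
      as.numeric(m <= criterion)
    } else {
      pnorm((criterion - m) / params$sigma_dir)^2
    }
    return(1 - both_below)
  }
  eps <- seq(-6, 6, length.out = n_eps) * params$sigma_id
  w <- dnorm(eps, 0, params$sigma_id)
  w <- w / sum(w)
  vapply(m, function(mi) {
    below <- if (params$sigma_dir == 0) {
      as.numeric(mi + eps <= criterion)
    } else {
      pnorm((criterion - mi - eps) / params$sigma_dir)^2
    }
    1 - sum(w * below)
  }, numeric(1))
}

# P(G(m, p) connected), classic recursion on the component of a fixed vertex
#' @noRd
p_connected <- function(m, p) {
  pc <- numeric(m)
  pc[1] <- 1
  if (m >= 2) {
    for (mm in 2:m) {
      j <- 1:(mm - 1)
      pc[mm] <- 1 - sum(choose(mm - 1, j - 1) * pc[j] * (1 - p)^(j * (mm - j)))
    }
  }
  pc[m]
}

#' Component-size distribution of one member of a partially visible clique
#'
#' A planted size-k family is a clique whose edges survive independently
#' with probability `p` at a criterion (per-pair identity jitter). The
#' observed family of a member is then the connected component containing
#' it in an Erdos-Renyi graph G(k, p); this returns the exact distribution
#' of that component's size.
#'
#' @param k Planted family size.
#' @param p Per-pair qualification probability.
#' @return Numeric vector of length `k`; element s is P(component = s).
#' @export
component_size_dist <- function(k, p) {
  vapply(seq_len(k), function(s) {
    choose(k - 1, s - 1) * p_connected(s, p) * (1 - p)^(s * (k - s))
  }, numeric(1))
}

#' Closed-form planted AS expectations per criterion and size bin
#'
#' Integrates the generator's AS model over the planted family-size/age
#' mixture against the threshold rule: at each criterion, each pair of a
#' family qualifies independently with the age-dependent probability from
#' [pair_visibility()], so a member's observed family size follows
#' [component_size_dist()]; members whose component is 1 fall into the
#' singleton bin alongside true singletons. Expected AS proportions are
#' ratios of expected AS counts to expected gene counts.
#'
#' @param params A [synth_params()].
#' @param config A [run_config()] (criteria and size bins).
#' @param n_age_grid Age-grid resolution for the Beta integral.
#' @return Tibble: `criterion`, `size_bin` (the configured bins plus a
#'   pooled `"duplicate"` row), `expected_as_proportion`,
#'   `expected_gene_fraction` (share of all genes expected in the row).
#' @export
planted_expectations <- function(params, config = run_config(),
                                 n_age_grid = 400) {
  stopifnot(inherits(params, "dupsplice_params"),
            inherits(config, "dupsplice_config"))
  sizes <- as.integer(names(params$family_size_probs))
  pk <- as.numeric(params$family_size_probs)
  gene_w <- sizes * pk / sum(sizes * pk)   # share of genes per planted size

  a_grid <- (seq_len(n_age_grid) - 0.5) / n_age_grid
  f_a <- dbeta(a_grid, params$age_shape1, params$age_shape2)
  f_a <- f_a / sum(f_a)

  labs <- size_bin_labels(config)
  bin_of <- function(s) as.character(bin_family_size(s, config))

  purrr::map_dfr(config$identity_criteria, function(crit) {
    q <- pair_visibility(a_grid, crit, params)
    mass <- setNames(numeric(length(labs)), labs)
    as_mass <- mass

    # true singletons
    i1 <- which(sizes == 1L)
    if (length(i1)) {
      mass["singleton"] <- mass["singleton"] + gene_w[i1]
      as_mass["singleton"] <- as_mass["singleton"] +
        gene_w[i1] * params$p_singleton_as
    }

    for (j in which(sizes >= 2L)) {
      k <- sizes[j]
      p_as <- as_probability(params, k, a_grid)
      for (ai in seq_along(a_grid)) {
        cs <- component_size_dist(k, q[ai])
        wt <- gene_w[j] * f_a[ai]
        for (s in seq_len(k)) {
          b <- bin_of(s)
          mass[b] <- mass[b] + wt * cs[s]
          as_mass[b] <- as_mass[b] + wt * cs[s] * p_as[ai]
        }
      }
    }

    dup_mass <- sum(mass[labs != "singleton"])
    dup_as <- sum(as_mass[labs != "singleton"])
    tibble::tibble(
      criterion = crit,
      size_bin = c(labs, "duplicate"),
      expected_as_proportion = c(ifelse(mass > 0, as_mass / mass, NA_real_),
                                 if (dup_mass > 0) dup_as / dup_mass else NA_real_),
      expected_gene_fraction = c(mass, dup_mass)
    )
  })
}
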