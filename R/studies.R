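#' Parameter-recovery study for the Bayesian BM-delta model
#'
#' Simulates traits under Brownian motion with a delta transform on
#' birth trees, refits by MCMC, and scores recovery: whether the true
#' root state falls inside the 95% HPD of the posterior root, and the
#' point recovery of delta and sigma2.
#'
#' @param n_sims number of simulated datasets.
#' @param n_tips tips per tree.
#' @param delta,sigma2,root_state true generating values.
#' @param generations,burn_in,thin MCMC settings per fit.
#' @param seed integer seed; each simulation derives its own sub-seed.
#' @return A tibble with one row per simulation: `covered` (logical),
#'   `delta_hat`, `sigma2_hat`, `root_hat`.
#' @export
study_asr_coverage <- function(n_sims = 20L, n_tips = 128L, delta = 0.5,
                               sigma2 = 0.2, root_state = 1,
                               generations = 12000L, burn_in = 4000L,
                               thin = 10L, seed = 1L) {
  purrr::map_dfr(seq_len(n_sims), function(i) {
    s <- as.integer(seed) * 100L + i
    tree <- simulate_tree(n_tips, seed = s)
    traits <- simulate_bm(tree, sigma2, root_state,
                          transform = list(kind = "delta", value = delta),
                          seed = s + 50000L)
    chain <- mcmc_sample(tree, traits, model = "random_walk",
                         scaling = "delta", generations = generations,
                         burn_in = burn_in, thin = thin, seed = s + 90000L)
    h <- hpd_interval(chain$draws$root)
    tibble::tibble(
      sim = i,
      covered = root_state >= h[1] && root_state <= h[2],
      delta_hat = mean(chain$draws$scaling_value),
      sigma2_hat = mean(chain$draws$sigma2),
      root_hat = mean(chain$draws$root)
    )
  })
}

#' Regime-shift recovery study for the stepwise OU search
#'
#' Simulates a two-shift scenario on birth trees — two disjoint clades
#' attracted to a shared high optimum against a low basal optimum — and
#' runs the full forward/backward search. Scores, per simulation: the
#' final number of shifts, whether each true shift branch is recovered
#' within one node, and whether the two convergent clades are merged onto
#' a shared optimum by the backward phase.
#'
#' @param n_sims number of simulated datasets.
#' @param n_tips tips per tree.
#' @param theta_base,theta_shift basal and shifted optima.
#' @param alpha_depth attraction rate as alpha x tree depth.
#' @param stationary_sd stationary standard deviation around an optimum.
#' @param clade_size `c(min, max)` tips for the shifted clades.
#' @param seed integer seed.
#' @return A tibble with one row per simulation: `k_shifts_final`,
#'   `true_shifts_found` (0-2, within one node), `merged` (logical).
#' @export
study_surface_recovery <- function(n_sims = 20L, n_tips = 64L,
                                   theta_base = 0.7, theta_shift = 1.6,
                                   alpha_depth = 8, stationary_sd = 0.15,
                                   clade_size = c(6L, 14L), seed = 1L) {
  purrr::map_dfr(seq_len(n_sims), function(i) {
    s <- as.integer(seed) * 100L + i
    tree <- simulate_tree(n_tips, seed = s + 10000L)
    ed <- pick_disjoint_clades(tree, clade_size[1], clade_size[2])
    if (anyNA(ed)) return(tibble::tibble(sim = i, k_shifts_final = NA_integer_,
                                         true_shifts_found = NA_integer_,
                                         merged = NA))
    Td <- max(ape::node.depth.edgelength(tree))
    alpha <- alpha_depth / Td
    painting <- paint_regimes(tree, shifts = stats::setNames(
      c("S1", "S2"), as.character(tree$edge[ed, 2])))
    traits <- simulate_ou(tree, painting, alpha = alpha,
                          sigma2 = 2 * alpha * stationary_sd^2,
                          optima = c(R1 = theta_base, S1 = theta_shift,
                                     S2 = theta_shift),
                          seed = s + 20000L)
    fwd <- surface_forward(tree, traits)
    bwd <- surface_backward(tree, traits, fwd)
    found <- sum(vapply(ed, function(e) {
      any(vapply(fwd$shift_edges, within_one_node, logical(1),
                 tree = tree, target = e))
    }, logical(1)))
    # convergence recovered: the two true-shift branches end up painted
    # with one shared regime whose optimum is the high one
    final_er <- as.character(bwd$final$painting)
    lab <- final_er[ed[1]]
    merged <- lab == final_er[ed[2]] &&
      is.finite(bwd$final$theta[[lab]]) &&
      bwd$final$theta[[lab]] > (theta_base + theta_shift) / 2
    tibble::tibble(sim = i, k_shifts_final = bwd$final$k_shifts,
                   true_shifts_found = found, merged = merged)
  })
}

# two candidate shift edges subtending disjoint clades of bounded size
pick_disjoint_clades <- function(tree, lo, hi) {
  n <- length(tree$tip.label)
  sizes <- vapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= n) 1L else ape::Ntip(ape::extract.clade(tree, ch))
  }, integer(1))
  cand <- which(sizes >= lo & sizes <= hi)
  if (length(cand) < 2L) return(c(NA_integer_, NA_integer_))
  e1 <- cand[1]
  d1 <- c(tree$edge[e1, 2], descendants_of(tree, tree$edge[e1, 2]))
  for (e2 in cand[-1]) {
    d2 <- c(tree$edge[e2, 2], descendants_of(tree, tree$edge[e2, 2]))
    if (!(tree$edge[e2, 2] %in% d1) && !(tree$edge[e1, 2] %in% d2)) {
      return(c(e1, e2))
    }
  }
  c(NA_integer_, NA_integer_)
}

# is edge `found` the same as `target`, or its parent/child edge?
within_one_node <- function(found, tree, target) {
  if (found == target) return(TRUE)
  pe <- match(tree$edge[, 1], tree$edge[, 2])
  identical(pe[found], target) || identical(pe[target], found)
}
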