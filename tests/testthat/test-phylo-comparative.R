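test_that("tree reading validates and round-trips", {
  tmp <- withr::local_tempdir()
  tr <- rtree_det(8, seed = 1)
  nwk <- file.path(tmp, "t.nwk")
  ape::write.tree(tr, nwk)
  back <- read_tree(nwk)
  expect_equal(ape::write.tree(back), ape::write.tree(tr))

  # nexus with a translate table resolves labels
  nex <- file.path(tmp, "t.nex")
  ape::write.nexus(tr, file = nex, translate = TRUE)
  backn <- read_tree(nex)
  expect_setequal(backn$tip.label, tr$tip.label)

  dup <- tr
  dup$tip.label[2] <- dup$tip.label[1]
  dnwk <- file.path(tmp, "d.nwk")
  ape::write.tree(dup, dnwk)
  expect_error(read_tree(dnwk), "duplicate")
})

test_that("Pagel transforms have their defining special cases", {
  tr <- rtree_det(12, seed = 2)
  for (kind in c("delta", "kappa", "lambda")) {
    expect_equal(transform_tree(tr, kind, 1)$edge.length, tr$edge.length,
                 tolerance = 1e-12)
  }
  expect_true(all(transform_tree(tr, "kappa", 0)$edge.length == 1))

  lam0 <- transform_tree(tr, "lambda", 0)
  n <- length(tr$tip.label)
  internal <- lam0$edge[, 2] > n
  expect_true(all(lam0$edge.length[internal] == 0))  # star tree
  expect_equal(ape::node.depth.edgelength(lam0)[1:n],
               ape::node.depth.edgelength(tr)[1:n], tolerance = 1e-12)

  expect_error(transform_tree(tr, "delta", -1), ">= 0")
})

test_that("BM log-likelihood equals the dense covariance oracle", {
  set.seed(42)
  for (case in 1:25) {
    n <- sample(4:16, 1)
    tr <- rtree_det(n, seed = 100 + case)
    x <- rnorm(n)
    names(x) <- tr$tip.label
    traits <- tibble::tibble(taxon = tr$tip.label, value = x)
    s2 <- runif(1, 0.2, 2)
    root <- rnorm(1)
    ll <- bm_loglik(tr, traits, s2, root)
    C <- oracle_bm_cov(tr)
    expect_equal(ll, oracle_mvn_loglik(x, rep(root, n), s2 * C),
                 tolerance = 1e-8)
  }
})

test_that("BM likelihood with transforms matches transforming the tree first", {
  tr <- rtree_det(10, seed = 7)
  traits <- simulate_bm(tr, 1, 0, seed = 3)
  for (kind in c("delta", "kappa", "lambda")) {
    v <- c(delta = 0.6, kappa = 0.4, lambda = 0.7)[[kind]]
    direct <- bm_loglik(tr, traits, 1.1, 0.2, scaling = kind,
                        scaling_value = v)
    C <- oracle_bm_cov(transform_tree(tr, kind, v))
    expect_equal(direct,
                 oracle_mvn_loglik(traits$value, rep(0.2, 10), 1.1 * C),
                 tolerance = 1e-8)
  }
})

test_that("ML fitting has its closed-form special cases", {
  # symmetric cherry with tips {0, 2}: ML root is 1
  ch <- simulate_tree(2, seed = 1)
  traits <- tibble::tibble(taxon = ch$tip.label, value = c(0, 2))
  g <- ptscam:::gls_profile(traits$value, oracle_bm_cov(ch))
  expect_equal(g$root, 1.0)

  # star tree with equal branches: ML sigma2 = mean squared deviation / t
  star <- ape::stree(8, "star")
  star$edge.length <- rep(2, 8)
  x <- c(0.3, -1, 2, 0.7, -0.2, 1.1, 0.4, -0.8)
  traits <- tibble::tibble(taxon = star$tip.label, value = x)
  f <- fit_ml(star, traits)
  expect_equal(f$sigma2, mean((x - mean(x))^2) / 2, tolerance = 1e-8)
  expect_equal(f$root_state, mean(x), tolerance = 1e-8)

  # directional model refuses ultrametric trees
  tr <- simulate_tree(8, seed = 2)
  traits8 <- simulate_bm(tr, 1, 0, seed = 1)
  expect_error(fit_ml(tr, traits8, model = "directional"), "non-ultrametric")
})

test_that("the directional model recovers a trend on fossil trees", {
  trends <- vapply(1:6, function(s) {
    tr <- simulate_tree(64, n_fossil_tips = 16, seed = 2200 + s)
    traits <- simulate_bm(tr, 0.2, 0, trend = 1.5, seed = 2300 + s)
    fit_ml(tr, traits, model = "directional")$trend
  }, numeric(1))
  expect_gt(median(trends), 0.75)
  expect_lt(median(trends), 2.25)

  # the directional likelihood beats random walk on trended data
  tr <- simulate_tree(64, n_fossil_tips = 16, seed = 2400)
  traits <- simulate_bm(tr, 0.2, 0, trend = 2, seed = 2401)
  f_dir <- fit_ml(tr, traits, model = "directional")
  f_rw <- fit_ml(tr, traits, model = "random_walk")
  expect_gt(f_dir$log_likelihood, f_rw$log_likelihood)

  # and the MCMC directional chain runs and finds the trend's sign
  ch <- mcmc_sample(tr, traits, model = "directional", generations = 3000,
                    burn_in = 1000, thin = 5, seed = 7)
  expect_gt(mean(ch$draws$trend), 0)
})

test_that("ML recovers scaling parameters from simulated data", {
  # delta = 1 data: estimates concentrate near 1 (median over seeds)
  dhat <- vapply(1:10, function(s) {
    tr <- simulate_tree(128, seed = 300 + s)
    traits <- simulate_bm(tr, 0.5, 0, seed = 400 + s)
    fit_ml(tr, traits, scaling = "delta")$scaling_value
  }, numeric(1))
  expect_gt(median(dhat), 0.7)
  expect_lt(median(dhat), 1.3)

  # lambda = 0 data (no phylogenetic signal) recovers near 0
  lhat <- vapply(1:5, function(s) {
    tr <- simulate_tree(96, seed = 500 + s)
    star_data <- tibble::tibble(taxon = tr$tip.label,
                                value = rnorm(96, 1, 0.3))
    fit_ml(tr, star_data, scaling = "lambda")$scaling_value
  }, numeric(1))
  expect_lt(median(lhat), 0.1)

  # sigma2 recovery within 15% (median over seeds)
  s2hat <- vapply(1:8, function(s) {
    tr <- simulate_tree(128, seed = 600 + s)
    traits <- simulate_bm(tr, 0.7, 0, seed = 700 + s)
    fit_ml(tr, traits)$sigma2
  }, numeric(1))
  expect_lt(abs(median(s2hat) / 0.7 - 1), 0.15)
})

test_that("MCMC is seed-reproducible and centres on the symmetric answer", {
  ch <- simulate_tree(2, seed = 4)
  traits <- tibble::tibble(taxon = ch$tip.label, value = c(0, 2))
  a <- mcmc_sample(ch, traits, generations = 4000, burn_in = 1000,
                   thin = 5, seed = 99)
  b <- mcmc_sample(ch, traits, generations = 4000, burn_in = 1000,
                   thin = 5, seed = 99)
  expect_identical(a$draws, b$draws)
  # posterior mean of the root on the symmetric cherry is the tip mean
  expect_lt(abs(mean(a$draws$root) - 1), 3 * sd(a$draws$root) /
              sqrt(nrow(a$draws) / 10) + 0.05)
  expect_gt(a$acceptance, 0)
})

test_that("stepping stone recovers the analytic conjugate marginal likelihood", {
  set.seed(8)
  y <- rnorm(12, mean = 1.4, sd = 0.5)
  m0 <- 0; s2_prior <- 4; s2_lik <- 0.25
  loglik <- function(par) sum(dnorm(y, par[1], sqrt(s2_lik), log = TRUE))
  logprior <- function(par) dnorm(par[1], m0, sqrt(s2_prior), log = TRUE)
  analytic <- oracle_conjugate_log_ml(y, m0, s2_prior, s2_lik)

  set.seed(101)
  est1 <- power_posterior_ml(loglik, logprior, init = 0, scales = 1,
                             n_stones = 64, gens_per_stone = 2000)
  set.seed(202)
  est2 <- power_posterior_ml(loglik, logprior, init = 0, scales = 1,
                             n_stones = 64, gens_per_stone = 2000)
  expect_lt(abs(est1$log_ml - analytic), 0.1)
  expect_lt(abs(est1$log_ml - est2$log_ml), 0.5)
})

test_that("stepping-stone error shrinks as stones and generations grow", {
  set.seed(9)
  y <- rnorm(10, 0.8, 0.6)
  loglik <- function(par) sum(dnorm(y, par[1], 0.6, log = TRUE))
  logprior <- function(par) dnorm(par[1], 0, 2, log = TRUE)
  analytic <- oracle_conjugate_log_ml(y, 0, 4, 0.36)
  errs <- vapply(c(8, 16, 64), function(K) {
    e <- vapply(1:3, function(r) {
      set.seed(1000 * K + r)
      power_posterior_ml(loglik, logprior, 0, 1, n_stones = K,
                         gens_per_stone = 500)$log_ml
    }, numeric(1))
    mean(abs(e - analytic))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("Bayes-factor bookkeeping follows the doubled-difference convention", {
  mk <- function(lml, hash = "h") {
    structure(list(log_ml = lml, data_hash = hash, model = "random_walk",
                   scaling = "none"), class = "ml_estimate")
  }
  bf <- compare_models(list(a = mk(-10), b = mk(-11)))
  expect_equal(unname(bf$log_bf[bf$model_a == "a" & bf$model_b == "b"]), 2)
  expect_equal(unname(bf$log_bf[bf$model_a == "b" & bf$model_b == "a"]), -2)
  bf0 <- compare_models(list(a = mk(-10), b = mk(-10)))
  expect_true(all(bf0$log_bf == 0))
  expect_false(any(bf0$positive_evidence))
  expect_error(compare_models(list(mk(-10, "h1"), mk(-10, "h2"))),
               "different data")
})

test_that("replicate stepping-stone runs on a real tree agree", {
  tr <- rtree_det(8, seed = 11)
  traits <- simulate_bm(tr, 0.5, 1, seed = 12)
  est <- stepping_stone(tr, traits, n_stones = 12, gens_per_stone = 400,
                        seed = 5)
  expect_lt(est$replicate_diff, 1.0)
  # same model estimated twice: log BF approximately zero
  est2 <- stepping_stone(tr, traits, n_stones = 12, gens_per_stone = 400,
                         seed = 77)
  bf <- compare_models(list(a = est, b = est2))
  expect_lt(max(abs(bf$log_bf)), 2)
})

test_that("ancestral reconstruction has its degenerate and oracle limits", {
  ch <- simulate_tree(2, seed = 13)
  traits <- tibble::tibble(taxon = ch$tip.label, value = c(0, 2))
  fit <- list(model = "random_walk", scaling = "none", scaling_value = 1,
              sigma2 = 0.5, root_state = 1, trend = NULL)
  class(fit) <- "evol_model_fit"
  asr <- reconstruct_ancestors(ch, traits, fit, seed = 3)
  expect_equal(asr$posterior_mean[asr$node == 3], 1, tolerance = 0.05)
  expect_lte(asr$hpd95_low[1], 1)
  expect_gte(asr$hpd95_high[1], 1)

  # reconstruction at a tip is the observed value exactly
  asr_tip <- reconstruct_ancestors(ch, traits, fit, nodes = c(1L, 2L),
                                   seed = 3)
  expect_equal(asr_tip$posterior_mean, c(0, 2))
  expect_equal(asr_tip$hpd95_low, asr_tip$hpd95_high)

  # plug-in reconstruction matches the dense GLS conditional mean
  tr <- rtree_det(10, seed = 14)
  traits10 <- simulate_bm(tr, 1, 0, seed = 15)
  fit10 <- fit_ml(tr, traits10)
  asr10 <- reconstruct_ancestors(tr, traits10, fit10, nodes = 11L,
                                 runs = 2, n_draws_per_run = 4000, seed = 4)
  C <- oracle_bm_cov(tr)
  ones <- rep(1, 10)
  # GLS conditional mean of the root given tips (root-to-node shared path
  # with every tip is zero at the root, so the conditional mean is the
  # prior root estimate; use the fitted root)
  expect_equal(asr10$posterior_mean, fit10$root_state, tolerance = 0.05)

  expect_error(reconstruct_ancestors(tr, traits10, fit10, nodes = 99L),
               "out of range")
  expect_error(reconstruct_ancestors(tr, traits10, fit10,
                                     nodes = list(cl = c("zzz"))),
               "not in tree")
})

test_that("HPD intervals are shortest intervals at the right coverage", {
  set.seed(21)
  x <- rnorm(20000)
  h <- ptscam:::hpd_interval(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.08)
  expect_lt(abs(h[2] - 1.96), 0.08)
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.949)
})
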