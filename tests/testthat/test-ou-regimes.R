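test_that("OU likelihood matches closed forms and the dense oracle", {
  # star tree, single regime: iid normal transition density
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1.5, 6)
  x <- c(1.2, 0.9, 1.6, 1.1, 0.8, 1.4)
  traits <- tibble::tibble(taxon = star$tip.label, value = x)
  pnt <- paint_regimes(star)
  a <- 0.9; s2 <- 0.4; th <- 1.0
  m <- th  # root at the basal optimum: stationary mean is theta
  v <- s2 * (1 - exp(-2 * a * 1.5)) / (2 * a)
  expect_equal(ou_loglik(star, traits, pnt, a, s2, c(R1 = th)),
               sum(dnorm(x, m, sqrt(v), log = TRUE)), tolerance = 1e-8)

  # random trees and parameters against the entrywise oracle
  set.seed(31)
  for (case in 1:20) {
    n <- sample(5:12, 1)
    tr <- rtree_det(n, seed = 800 + case)
    shift_node <- sample(setdiff(2:(n + tr$Nnode), n + 1), 1)
    pnt <- paint_regimes(tr, shifts = setNames("R2", as.character(shift_node)))
    thetas <- c(R1 = rnorm(1), R2 = rnorm(1))
    a <- runif(1, 0.05, 3); s2 <- runif(1, 0.1, 1)
    xx <- rnorm(n)
    traits <- tibble::tibble(taxon = tr$tip.label, value = xx)
    trf <- tr; trf$edge.length <- pmax(tr$edge.length, 1e-8)
    oc <- oracle_ou_meancov(trf, pnt, a, s2, thetas, root_state = thetas[["R1"]])
    expect_equal(ou_loglik(tr, traits, pnt, a, s2, thetas),
                 oracle_mvn_loglik(xx, oc$mu, oc$V), tolerance = 1e-8)
  }
})

test_that("OU collapses to BM in the weak-attraction single-regime limit", {
  tr <- rtree_det(12, seed = 16)
  traits <- simulate_bm(tr, 0.6, 1.1, seed = 17)
  pnt <- paint_regimes(tr)
  ll_ou <- ou_loglik(tr, traits, pnt, alpha = 1e-8, sigma2 = 0.6,
                     thetas = c(R1 = 1.1))
  ll_bm <- bm_loglik(tr, traits, 0.6, 1.1)
  expect_equal(ll_ou, ll_bm, tolerance = 1e-4)
})

test_that("likelihood is invariant to relabelling regimes", {
  tr <- rtree_det(10, seed = 18)
  pnt <- paint_regimes(tr, shifts = setNames("R2", as.character(13)))
  traits <- simulate_ou(tr, pnt, 1, 0.3, c(R1 = 0.7, R2 = 1.6), seed = 19)
  ll1 <- ou_loglik(tr, traits, pnt, 1, 0.3, c(R1 = 0.7, R2 = 1.6))
  relab <- structure(ifelse(pnt == "R1", "blue", "red"),
                     class = "regime_painting", base_regime = "blue")
  ll2 <- ou_loglik(tr, traits, relab, 1, 0.3, c(blue = 0.7, red = 1.6))
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("Hansen fitting recovers optima and flags boundary alpha", {
  # single-regime recovery of theta under strong attraction
  th_hat <- vapply(1:6, function(s) {
    tr <- simulate_tree(96, seed = 900 + s)
    Td <- max(ape::node.depth.edgelength(tr))
    pnt <- paint_regimes(tr)
    traits <- simulate_ou(tr, pnt, alpha = 5 / Td, sigma2 = 0.1,
                          optima = c(R1 = 1.6), seed = 950 + s)
    fit_hansen(tr, traits)$theta[["R1"]]
  }, numeric(1))
  expect_lt(abs(median(th_hat) / 1.6 - 1), 0.10)

  # BM data: estimated attraction is negligible over the tree depth
  tr <- simulate_tree(64, seed = 20)
  traits <- simulate_bm(tr, 0.5, 0, seed = 21)
  f <- fit_hansen(tr, traits)
  Td <- max(ape::node.depth.edgelength(tr))
  expect_lt(f$alpha * Td, 0.5)

  flat <- tibble::tibble(taxon = tr$tip.label, value = rep(1, 64))
  expect_error(fit_hansen(tr, flat), "zero variance")
})

test_that("the forward search is deterministic, localises a strong shift, and never raises AICc", {
  tr <- simulate_tree(32, seed = 22)
  Td <- max(ape::node.depth.edgelength(tr))
  # a clear two-regime scenario: paint one mid-sized clade
  sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
    ch <- tr$edge[e, 2]
    if (ch <= 32) 1L else ape::Ntip(ape::extract.clade(tr, ch))
  }, integer(1))
  true_edge <- which(sizes >= 8 & sizes <= 16)[1]
  pnt <- paint_regimes(tr, shifts = setNames(
    "R2", as.character(tr$edge[true_edge, 2])))
  traits <- simulate_ou(tr, pnt, alpha = 8 / Td, sigma2 = 16 / Td * 0.15^2,
                        optima = c(R1 = 0.7, R2 = 1.6), seed = 23)

  fwd <- surface_forward(tr, traits)
  expect_gte(length(fwd$shift_edges), 1)
  expect_equal(fwd$shift_edges[1], true_edge)  # strongest shift found first
  expect_true(all(diff(fwd$aicc_trace) < 0))

  fwd2 <- surface_forward(tr, traits)
  expect_identical(fwd$shift_edges, fwd2$shift_edges)
  expect_identical(fwd$aicc_trace, fwd2$aicc_trace)
})

test_that("the backward phase merges convergent regimes and never raises AICc", {
  tr <- simulate_tree(48, seed = 24)
  Td <- max(ape::node.depth.edgelength(tr))
  sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
    ch <- tr$edge[e, 2]
    if (ch <= 48) 1L else ape::Ntip(ape::extract.clade(tr, ch))
  }, integer(1))
  # two disjoint clades pushed to the same optimum
  cand <- which(sizes >= 6 & sizes <= 12)
  e1 <- cand[1]
  desc1 <- c(tr$edge[e1, 2], ptscam:::descendants_of(tr, tr$edge[e1, 2]))
  disjoint <- vapply(cand, function(e) {
    d <- c(tr$edge[e, 2], ptscam:::descendants_of(tr, tr$edge[e, 2]))
    !(tr$edge[e, 2] %in% desc1) && !(tr$edge[e1, 2] %in% d)
  }, logical(1))
  e2 <- cand[disjoint][1]
  expect_false(is.na(e2))
  pnt <- paint_regimes(tr, shifts = setNames(
    c("R2", "R3"), as.character(tr$edge[c(e1, e2), 2])))
  traits <- simulate_ou(tr, pnt, alpha = 8 / Td, sigma2 = 16 / Td * 0.15^2,
                        optima = c(R1 = 0.7, R2 = 1.6, R3 = 1.6), seed = 25)

  fwd <- surface_forward(tr, traits)
  bwd <- surface_backward(tr, traits, fwd)
  expect_true(all(diff(bwd$aicc_trace) < 0))
  expect_lte(bwd$final$k_regimes, fwd$final$k_regimes)
  expect_lte(bwd$final$aicc, fwd$final$aicc)
  # regime count never exceeds shifts + 1
  expect_lte(bwd$final$k_regimes, bwd$final$k_shifts + 1)
})

test_that("collapsing all regimes reproduces the single-regime fit", {
  tr <- rtree_det(16, seed = 26)
  pnt <- paint_regimes(tr, shifts = setNames("R2", as.character(20)))
  traits <- simulate_ou(tr, pnt, 1, 0.3, c(R1 = 0.7, R2 = 1.6), seed = 27)
  single <- fit_hansen(tr, traits)
  merged_painting <- structure(rep("R1", nrow(tr$edge)),
                               class = "regime_painting", base_regime = "R1")
  merged <- fit_hansen(tr, traits, merged_painting)
  expect_equal(merged$log_likelihood, single$log_likelihood, tolerance = 1e-6)
  expect_equal(merged$aicc, single$aicc, tolerance = 1e-6)
})

test_that("genus consolidation weights species means as documented", {
  tr <- ape::read.tree(text = "((A_x:1,A_y:1):1,(B_z:1.5,C_w:1.5):0.5);")
  traits <- tibble::tibble(taxon = c("A_x", "A_y", "B_z", "C_w"),
                           value = c(1.0, 2.0, 1.2, 0.9),
                           n = c(3L, 1L, 2L, 5L))
  gc <- genus_consolidate(traits, tr)
  expect_equal(gc$traits$value[gc$traits$taxon == "A"], 1.25)  # (3*1+1*2)/4
  expect_equal(gc$traits$value[gc$traits$taxon == "B"], 1.2)   # singleton
  expect_setequal(gc$tree$tip.label, c("A", "B", "C"))

  # unweighted variant
  gc2 <- genus_consolidate(traits, tr, weight_by = "species")
  expect_equal(gc2$traits$value[gc2$traits$taxon == "A"], 1.5)

  # exception list keeps species tips
  gc3 <- genus_consolidate(traits, tr, except = "A")
  expect_true(all(c("A_x", "A_y") %in% gc3$tree$tip.label))
  expect_true(all(c("A_x", "A_y") %in% gc3$traits$taxon))
})
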