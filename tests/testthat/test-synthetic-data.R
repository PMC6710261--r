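test_that("synthetic talus spec enforces its invariants", {
  expect_error(synthetic_talus_spec(trochlea_radius = -1), "radius")
  expect_error(synthetic_talus_spec(trochlea_arc = 20), "arc")
  expect_error(synthetic_talus_spec(trochlea_radius = 2, shelf_offset = -2.5),
               "shelf_offset")
  expect_error(synthetic_talus_spec(groove_curvatures = c(0.5, 0.5)),
               "opposite signs")
  # resolution coarser than the curvature radii cannot resolve the saddle
  expect_error(synthetic_talus_spec(groove_curvatures = c(5, -5),
                                    mesh_resolution = 0.5),
               "unresolvable")
})

test_that("ground-truth PTS index follows (radius + offset) / radius", {
  t1 <- make_synthetic_talus(synthetic_talus_spec(3, shelf_offset = 0,
                                                  mesh_resolution = 0.15))
  expect_equal(t1$truth$true_pts_index, 1.0)
  t2 <- make_synthetic_talus(synthetic_talus_spec(3, shelf_offset = 1.5,
                                                  mesh_resolution = 0.15))
  expect_equal(t2$truth$true_pts_index, 1.5)
  t3 <- make_synthetic_talus(synthetic_talus_spec(2, shelf_offset = -0.6,
                                                  mesh_resolution = 0.15))
  expect_equal(t3$truth$true_pts_index, 0.7)
  # saddle point sits at the stated distance from the true axis
  s <- t2$truth$true_saddle_point
  expect_equal(sqrt(s[2]^2 + s[3]^2), 4.5)
  # region tags index real vertices and are disjoint
  expect_length(intersect(t2$truth$facet_vertex_ids,
                          t2$truth$groove_vertex_ids), 0)
  expect_lte(max(t2$truth$groove_vertex_ids), nrow(t2$mesh$vertices))
})

test_that("noisy mesh generation is deterministic given the seed", {
  sp <- synthetic_talus_spec(3, mesh_resolution = 0.2, noise_sd = 0.02,
                             seed = 7)
  a <- make_synthetic_talus(sp)
  b <- make_synthetic_talus(sp)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  c <- make_synthetic_talus(synthetic_talus_spec(3, mesh_resolution = 0.2,
                                                 noise_sd = 0.02, seed = 8))
  expect_false(identical(a$mesh$vertices, c$mesh$vertices))
})

test_that("simulated trees are rooted, ultrametric unless fossils are asked", {
  ch <- simulate_tree(2, seed = 1)
  expect_s3_class(ch, "phylo")
  expect_true(all(ch$edge.length > 0))

  tr <- simulate_tree(64, seed = 5)
  d <- ape::node.depth.edgelength(tr)[1:64]
  expect_lt(diff(range(d)), 1e-9 * max(d))

  trf <- simulate_tree(64, n_fossil_tips = 8, seed = 5)
  expect_false(ape::is.ultrametric(trf, tol = 1e-6))
  expect_error(simulate_tree(4, n_fossil_tips = 4), "n_fossil_tips")

  # determinism: identical newick on repeated calls
  expect_identical(ape::write.tree(simulate_tree(64, seed = 11)),
                   ape::write.tree(simulate_tree(64, seed = 11)))
})

test_that("BM simulation matches Brownian moments", {
  tr <- simulate_tree(8, seed = 2)
  flat <- simulate_bm(tr, sigma2 = 0, root_state = 1.3, seed = 1)
  expect_true(all(flat$value == 1.3))

  # tip variance over replicates approximates sigma2 * root-to-tip length
  ch <- simulate_tree(2, seed = 3)
  depth <- ape::node.depth.edgelength(ch)[1]
  reps <- vapply(seq_len(3000), function(s) {
    simulate_bm(ch, sigma2 = 1, root_state = 0, seed = s)$value[1]
  }, numeric(1))
  mc_se <- depth * sqrt(2 / 3000)
  expect_lt(abs(var(reps) - depth), 3 * mc_se)

  # directional trend shifts the mean by trend * depth on ultrametric trees
  tr8 <- simulate_tree(8, seed = 4)
  d8 <- max(ape::node.depth.edgelength(tr8))
  means <- vapply(seq_len(400), function(s) {
    mean(simulate_bm(tr8, sigma2 = 0.1, root_state = 2, trend = 0.5,
                     seed = 1000 + s)$value)
  }, numeric(1))
  expect_lt(abs(mean(means) - (2 + 0.5 * d8)), 4 * sd(means) / sqrt(400) + 0.02)
})

test_that("BM tip covariance converges to sigma2 x shared-path matrix", {
  tr <- rtree_det(5, seed = 9)
  nrep <- 1500
  X <- t(vapply(seq_len(nrep), function(s) {
    simulate_bm(tr, sigma2 = 0.8, root_state = 0, seed = 5000 + s)$value
  }, numeric(5)))
  emp <- cov(X)
  expected <- 0.8 * oracle_bm_cov(tr)
  # element-wise within 3 Monte Carlo SEs (normal theory for covariances)
  for (i in 1:5) for (j in 1:5) {
    se <- sqrt((expected[i, i] * expected[j, j] + expected[i, j]^2) / nrep)
    expect_lt(abs(emp[i, j] - expected[i, j]), 3.5 * se)
  }
})

test_that("OU simulation has the exact transition moments and BM limit", {
  ch <- simulate_tree(2, seed = 6)
  pnt <- paint_regimes(ch)
  # strong attraction: tips sit at the optimum
  tips <- vapply(seq_len(500), function(s) {
    simulate_ou(ch, pnt, alpha = 50, sigma2 = 0.01, optima = c(R1 = 1.6),
                root_state = 0, seed = s)$value[1]
  }, numeric(1))
  expect_lt(abs(mean(tips) - 1.6), 0.02)

  # sigma2 -> 0: deterministic decay towards the optimum
  tr <- rtree_det(6, seed = 10)
  pnt6 <- paint_regimes(tr)
  x <- simulate_ou(tr, pnt6, alpha = 0.7, sigma2 = 1e-12,
                   optima = c(R1 = 2), root_state = 5, seed = 1)
  depths <- ape::node.depth.edgelength(tr)[1:6]
  expect_equal(x$value, 2 + (5 - 2) * exp(-0.7 * depths), tolerance = 1e-4)

  # alpha -> 0 limit is distributionally BM (KS on one tip's marginal)
  n_mc <- 800
  ou_draws <- vapply(seq_len(n_mc), function(s) {
    simulate_ou(tr, pnt6, alpha = 1e-8, sigma2 = 0.5, optima = c(R1 = 0),
                root_state = 0, seed = 20000 + s)$value[3]
  }, numeric(1))
  bm_draws <- vapply(seq_len(n_mc), function(s) {
    simulate_bm(tr, sigma2 = 0.5, root_state = 0, seed = 60000 + s)$value[3]
  }, numeric(1))
  expect_gt(ks.test(ou_draws, bm_draws)$p.value, 0.01)

  expect_error(simulate_ou(tr, pnt6[-1], 1, 1, c(R1 = 0)), "every branch")
})
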