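# Independent oracles used across the test suite. Each is written against
# the mathematical definition, not the package's computation path.

# --- cylinder fitting: full nonlinear least squares over all 7 raw
# parameters (axis point, direction angles, radius) with Levenberg-
# Marquardt from random restarts -----------------------------------------
oracle_cylinder_fit <- function(pts, n_starts = 20L, seed = 42L) {
  stopifnot(requireNamespace("minpack.lm", quietly = TRUE))
  set.seed(seed)
  ctr <- colMeans(pts)
  resid_fn <- function(par) {
    u <- c(cos(par[1]) * sin(par[2]), sin(par[1]) * sin(par[2]), cos(par[2]))
    a <- ctr + par[3:5]
    w <- sweep(pts, 2, a)
    proj <- drop(w %*% u)
    d <- sqrt(pmax(rowSums(w^2) - proj^2, 0))
    d - par[6]
  }
  best <- NULL
  scale <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
  for (i in seq_len(n_starts)) {
    start <- c(runif(1, 0, 2 * pi), runif(1, 0, pi),
               rnorm(3, 0, scale / 4), runif(1, scale / 4, 2 * scale))
    fit <- tryCatch(
      minpack.lm::nls.lm(start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  u <- with(list(p = best$par),
            c(cos(p[1]) * sin(p[2]), sin(p[1]) * sin(p[2]), cos(p[2])))
  list(radius = abs(best$par[6]), direction = u / sqrt(sum(u^2)),
       deviance = best$deviance)
}

# --- Brownian covariance from first principles: shared path length of
# each tip pair computed from MRCA node depths ---------------------------
oracle_bm_cov <- function(tree) {
  n <- length(tree$tip.label)
  depths <- numeric(n + tree$Nnode)
  # cladewise order: parents appear before children
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  for (e in ord) {
    depths[tree$edge[e, 2]] <- depths[tree$edge[e, 1]] + tree$edge.length[e]
  }
  M <- ape::mrca(tree)
  C <- matrix(depths[M], n, n)
  diag(C) <- depths[seq_len(n)]
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

oracle_mvn_loglik <- function(x, mu, S) {
  n <- length(x)
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       t(x - mu) %*% solve(S) %*% (x - mu)))
}

# --- multi-regime OU mean and covariance assembled entry by entry -------
oracle_ou_meancov <- function(tree, painting, alpha, sigma2, thetas,
                              root_state) {
  n <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  depths <- numeric(n + tree$Nnode)
  parent_edge <- match(seq_len(n + tree$Nnode), tree$edge[, 2])
  for (e in ord) {
    depths[tree$edge[e, 2]] <- depths[tree$edge[e, 1]] + tree$edge.length[e]
  }
  path_edges <- function(tip) {
    out <- integer(0); node <- tip
    repeat {
      e <- parent_edge[node]
      if (is.na(e)) break
      out <- c(e, out)  # root -> tip order
      node <- tree$edge[e, 1]
    }
    out
  }
  mu <- numeric(n)
  for (i in seq_len(n)) {
    Ti <- depths[i]
    m <- root_state * exp(-alpha * Ti)
    for (e in path_edges(i)) {
      t0 <- depths[tree$edge[e, 1]]; t1 <- depths[tree$edge[e, 2]]
      th <- thetas[[as.character(painting[e])]]
      m <- m + th * (exp(-alpha * (Ti - t1)) - exp(-alpha * (Ti - t0)))
    }
    mu[i] <- m
  }
  M <- ape::mrca(tree)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ta <- if (i == j) depths[i] else depths[M[i, j]]
    d <- depths[i] + depths[j] - 2 * ta
    V[i, j] <- sigma2 / (2 * alpha) * exp(-alpha * d) * (1 - exp(-2 * alpha * ta))
  }
  list(mu = mu, V = V)
}

# --- taut string: Dijkstra over the full visibility graph of the cam
# polygon plus the two endpoints -----------------------------------------
oracle_taut_string <- function(profile, theta, n_polygon = 128L) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  poly <- ptscam::cam_polygon(profile, theta, n_polygon)
  O <- profile$origin_point
  I <- profile$insertion_point
  pts <- rbind(O, I, poly * (1 + 1e-9))
  m <- nrow(pts)
  blocked <- function(a, b) {
    p1 <- poly
    p2 <- poly[c(2:nrow(poly), 1L), , drop = FALSE]
    d <- b - a
    r1 <- d[1] * (p1[, 2] - a[2]) - d[2] * (p1[, 1] - a[1])
    r2 <- d[1] * (p2[, 2] - a[2]) - d[2] * (p2[, 1] - a[1])
    e <- p2 - p1
    s1 <- e[, 1] * (a[2] - p1[, 2]) - e[, 2] * (a[1] - p1[, 1])
    s2 <- e[, 1] * (b[2] - p1[, 2]) - e[, 2] * (b[1] - p1[, 1])
    any(r1 * r2 < -1e-14 & s1 * s2 < -1e-14)
  }
  edges <- integer(0)
  weights <- numeric(0)
  for (i in seq_len(m - 1L)) {
    for (j in seq((i + 1L), m)) {
      if (!blocked(pts[i, ], pts[j, ])) {
        edges <- c(edges, i, j)
        weights <- c(weights, sqrt(sum((pts[i, ] - pts[j, ])^2)))
      }
    }
  }
  g <- igraph::make_graph(edges, n = m, directed = FALSE)
  igraph::distances(g, v = 1, to = 2, weights = weights)[1, 1]
}

# --- one-way ANOVA F from raw sums of squares ---------------------------
oracle_anova_F <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# --- conjugate normal-normal marginal likelihood ------------------------
# y_i ~ N(mu, s2_lik) iid, mu ~ N(m0, s2_prior): marginal of y is
# multivariate normal with mean m0 and covariance s2_lik I + s2_prior J
oracle_conjugate_log_ml <- function(y, m0, s2_prior, s2_lik) {
  n <- length(y)
  S <- diag(s2_lik, n) + matrix(s2_prior, n, n)
  oracle_mvn_loglik(y, rep(m0, n), S)
}

# small deterministic random tree helper
rtree_det <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n)
  tree$edge.length <- tree$edge.length + 0.05
  tree
}
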