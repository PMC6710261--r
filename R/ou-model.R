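#' Multi-regime Ornstein-Uhlenbeck log-likelihood
#'
#' Hansen-model log-likelihood on a regime-painted, possibly
#' non-ultrametric tree. The expected tip value integrates the attraction
#' towards each regime's optimum along the root-to-tip path:
#' \deqn{E[x_i] = x_0 e^{-\alpha T_i} + \sum_s \theta_{r(s)}
#'   (e^{-\alpha (T_i - t^{end}_s)} - e^{-\alpha (T_i - t^{start}_s)})}
#' over the path segments \eqn{s}; the covariance (root state fixed) is
#' \deqn{Cov(x_i, x_j) = \frac{\sigma^2}{2\alpha}
#'   e^{-\alpha d_{ij}} (1 - e^{-2 \alpha t_{a}})}
#' with \eqn{t_a} the root-to-MRCA height and \eqn{d_{ij}} the patristic
#' distance. By default the root state is fixed at the basal regime's
#' optimum. As \eqn{\alpha \to 0} this reduces to Brownian motion.
#'
#' @param tree an [ape::phylo].
#' @param traits tibble (`taxon`, `value`).
#' @param painting a [paint_regimes()] painting.
#' @param alpha attraction rate (>= 0 is rejected only when negative).
#' @param sigma2 diffusion rate (> 0).
#' @param thetas named numeric vector of optima per regime id.
#' @param root_state_rule `"basal_optimum"` (default) or `"given"`.
#' @param root_state root value when `root_state_rule = "given"`.
#' @return Log-likelihood (scalar).
#' @export
ou_loglik <- function(tree, traits, painting, alpha, sigma2, thetas,
                      root_state_rule = c("basal_optimum", "given"),
                      root_state = NULL) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  root_state_rule <- match.arg(root_state_rule)
  xt <- match_traits(tree, traits)
  cache <- ou_cache(tree, xt$taxon)
  check_painting(tree, painting)
  base <- attr(painting, "base_regime") %||% as.character(painting[1])
  if (root_state_rule == "basal_optimum") root_state <- thetas[[base]]
  if (is.null(root_state)) stop("root_state required when rule is 'given'",
                                call. = FALSE)
  mu <- ou_mean(cache, as.character(painting), thetas, alpha, root_state)
  V0 <- ou_corr(cache, alpha)
  mvn_loglik(xt$value, mu, V0, sigma2)
}

check_painting <- function(tree, painting) {
  if (length(painting) != nrow(tree$edge)) {
    stop("painting must assign a regime to every branch", call. = FALSE)
  }
  if (anyNA(painting)) stop("unpainted branch in painting", call. = FALSE)
  invisible(painting)
}

# precomputed path/height structures shared by all OU fits on one tree
ou_cache <- function(tree, taxa = tree$tip.label) {
  idx <- match(taxa, tree$tip.label)
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  depths <- ape::node.depth.edgelength(tree)
  anc <- edge_ancestry(tree)
  seg <- do.call(rbind, lapply(seq_along(idx), function(i) {
    edges <- anc[[idx[i]]]
    cbind(tip = i, edge = edges,
          t0 = depths[tree$edge[edges, 1]],
          t1 = depths[tree$edge[edges, 2]])
  }))
  Ta <- unname(ape::vcv(tree)[idx, idx, drop = FALSE])
  Ti <- depths[idx]
  list(seg = seg, Ta = Ta, Ti = Ti, n = length(idx),
       n_edges = nrow(tree$edge), depth = max(depths))
}

# expected tip values under the painted OU model
ou_mean <- function(cache, edge_regimes, thetas, alpha, root_state) {
  drop(ou_design(cache, edge_regimes, names(thetas), alpha) %*%
         unname(thetas[names(thetas)])) +
    root_state * exp(-alpha * cache$Ti)
}

# design matrix W: tips x regimes of attraction weights (root term excluded)
ou_design <- function(cache, edge_regimes, regime_ids, alpha) {
  seg <- cache$seg
  Ttip <- cache$Ti[seg[, "tip"]]
  w <- exp(-alpha * (Ttip - seg[, "t1"])) - exp(-alpha * (Ttip - seg[, "t0"]))
  reg <- match(edge_regimes[seg[, "edge"]], regime_ids)
  W <- matrix(0, cache$n, length(regime_ids))
  key <- (reg - 1L) * cache$n + seg[, "tip"]
  acc <- rowsum(w, key)
  W[as.integer(rownames(acc))] <- acc
  W
}

# OU correlation structure (sigma2 factored out), fixed-root form
ou_corr <- function(cache, alpha) {
  Ta <- cache$Ta
  Ti <- cache$Ti
  D <- outer(Ti, Ti, "+") - 2 * Ta
  if (alpha == 0) return(Ta)
  (-expm1(-2 * alpha * Ta)) * exp(-alpha * D) / (2 * alpha)
}

#' Fit a Hansen OU model to a regime painting
#'
#' Maximises the OU likelihood over `alpha`, `sigma2` and the regime
#' optima: for fixed `alpha` the optima are profiled by generalised least
#' squares (with the root folded into the basal regime's column) and
#' `sigma2` by its closed form, leaving a bounded one-dimensional search
#' over `log(alpha)`. `alpha` is bounded in `[1e-8, 50 / tree depth]`;
#' hits on either bound are flagged, not hidden. AICc uses parameter
#' count `2 + number of shifts + number of distinct optima`, so that
#' collapsing two regimes onto a shared optimum is rewarded even when the
#' shifts remain.
#'
#' @inheritParams ou_loglik
#' @param painting a regime painting; `NULL` fits a single regime.
#' @param alpha_bounds optional `c(lo, hi)` override.
#' @return An object of class `ou_fit`: `alpha`, `sigma2`, `theta`
#'   (named), `log_likelihood`, `aicc`, `k_shifts`, `k_regimes`,
#'   `painting`, `alpha_at_bound`.
#' @export
fit_hansen <- function(tree, traits, painting = NULL, alpha_bounds = NULL) {
  if (length(tree$tip.label) < 4L) stop("need >= 4 tips", call. = FALSE)
  xt <- match_traits(tree, traits)
  if (stats::var(xt$value) == 0) stop("traits have zero variance", call. = FALSE)
  if (is.null(painting)) painting <- paint_regimes(tree)
  check_painting(tree, painting)
  cache <- ou_cache(tree, xt$taxon)
  fit_hansen_cached(cache, xt$value, painting, tree, alpha_bounds)
}

fit_hansen_cached <- function(cache, x, painting, tree, alpha_bounds = NULL) {
  if (is.null(alpha_bounds)) alpha_bounds <- c(1e-8, 50 / cache$depth)
  regime_ids <- unique(as.character(painting))
  base <- attr(painting, "base_regime") %||% as.character(painting[1])
  if (!base %in% regime_ids) base <- as.character(painting[1])
  er <- as.character(painting)
  n <- cache$n

  profile <- function(log_alpha) {
    a <- exp(log_alpha)
    W <- ou_design(cache, er, regime_ids, a)
    W[, match(base, regime_ids)] <- W[, match(base, regime_ids)] +
      exp(-a * cache$Ti)
    V0 <- ou_corr(cache, a)
    ch <- tryCatch(chol(V0), error = function(e) chol(V0 + diag(1e-10, n)))
    Ws <- backsolve(ch, W, transpose = TRUE)
    xs <- backsolve(ch, x, transpose = TRUE)
    qrW <- qr(Ws)
    theta <- qr.coef(qrW, xs)
    theta[is.na(theta)] <- mean(x)  # unreachable regime: no information
    r <- xs - Ws %*% theta
    sigma2 <- sum(r^2) / n
    loglik <- -0.5 * n * log(2 * pi * sigma2) - sum(log(diag(ch))) - 0.5 * n
    list(alpha = a, theta = stats::setNames(as.numeric(theta), regime_ids),
         sigma2 = sigma2, loglik = loglik)
  }

  opt <- stats::optimize(function(la) -profile(la)$loglik,
                         interval = log(alpha_bounds), tol = 1e-4)
  # check the bounds explicitly: the optimum may sit on one
  cand <- list(opt$minimum, log(alpha_bounds[1]), log(alpha_bounds[2]))
  vals <- vapply(cand, function(la) profile(la)$loglik, numeric(1))
  la_best <- cand[[which.max(vals)]]
  best <- profile(la_best)

  k_regimes <- length(regime_ids)
  k_shifts <- count_shifts(tree, painting)
  # parameter count rewards convergence: each shift and each distinct
  # optimum costs one parameter (plus alpha and sigma2), so collapsing two
  # regimes onto a shared optimum saves a parameter while keeping the shift
  k_par <- 2L + k_shifts + k_regimes
  aicc <- -2 * best$loglik + 2 * k_par +
    if (n - k_par - 1 > 0) 2 * k_par * (k_par + 1) / (n - k_par - 1) else Inf
  structure(list(
    alpha = best$alpha, sigma2 = best$sigma2, theta = best$theta,
    log_likelihood = best$loglik, aicc = aicc,
    k_shifts = k_shifts, k_regimes = k_regimes,
    painting = painting, n = n,
    alpha_at_bound = best$alpha <= alpha_bounds[1] * (1 + 1e-6) ||
      best$alpha >= alpha_bounds[2] * (1 - 1e-6)
  ), class = "ou_fit")
}

# a shift = an edge whose regime differs from its parent edge's regime
count_shifts <- function(tree, painting) {
  parent_edge <- match(tree$edge[, 1], tree$edge[, 2])
  er <- as.character(painting)
  base <- attr(painting, "base_regime") %||% er[1]
  parent_reg <- ifelse(is.na(parent_edge), base, er[parent_edge])
  sum(er != parent_reg)
}

#' @export
print.ou_fit <- function(x, ...) {
  cat("<ou_fit> ", x$k_regimes, " regime(s), ", x$k_shifts, " shift(s): ",
      "alpha = ", format(x$alpha, digits = 4),
      if (x$alpha_at_bound) " (at bound)",
      ", sigma2 = ", format(x$sigma2, digits = 4),
      ", logL = ", format(x$log_likelihood, digits = 6),
      ", AICc = ", format(x$aicc, digits = 6), "\n  theta: ",
      paste(names(x$theta), format(x$theta, digits = 3),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ou_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "sigma2", paste0("theta_", names(x$theta))),
                 estimate = c(x$alpha, x$sigma2, unname(x$theta)))
}

#' @export
glance.ou_fit <- function(x, ...) {
  tibble::tibble(k_regimes = x$k_regimes, k_shifts = x$k_shifts,
                 logLik = x$log_likelihood, AICc = x$aicc, nobs = x$n,
                 alpha_at_bound = x$alpha_at_bound)
}
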