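#' Default priors for the Bayesian BM-family models
#'
#' The defaults are weakly informative and data-scaled: root
#' `Normal(mean(x), 10 sd(x))`; `sigma2` half-Cauchy with scale equal to
#' the variance of the phylogenetically independent contrasts (the natural
#' magnitude of the Brownian rate); scaling parameter uniform on (0, 3)
#' for delta/kappa and (0, 1) for lambda; trend
#' `Normal(0, 10 sd(x) / depth)`. All are configurable.
#'
#' @param tree an [ape::phylo].
#' @param traits tibble (`taxon`, `value`).
#' @param scaling scaling parameter in use.
#' @return A named list of prior specifications.
#' @export
default_priors <- function(tree, traits, scaling = "none") {
  xt <- match_traits(tree, traits)
  x <- xt$value
  pic_var <- tryCatch(stats::var(ape::pic(stats::setNames(x, xt$taxon), tree)),
                      error = function(e) stats::var(x))
  if (!is.finite(pic_var) || pic_var <= 0) pic_var <- max(stats::var(x), 1e-6)
  depth <- max(ape::node.depth.edgelength(tree))
  list(
    root = list(mean = mean(x), sd = max(10 * stats::sd(x), 1e-3)),
    sigma2 = list(scale = pic_var),
    scaling = list(min = 0, max = if (scaling == "lambda") 1 else 3),
    trend = list(mean = 0, sd = max(10 * stats::sd(x) / depth, 1e-3))
  )
}

# log prior density over the sampling parameterisation
# par = (root, log sigma2 [, scaling] [, trend]); includes the Jacobian
# of the log-sigma2 reparameterisation
make_logprior <- function(priors, scaling, directional) {
  function(par) {
    lp <- stats::dnorm(par[1], priors$root$mean, priors$root$sd, log = TRUE)
    s2 <- exp(par[2])
    # half-Cauchy(scale) on sigma2, plus Jacobian d sigma2 / d log sigma2
    lp <- lp + log(2 / (pi * priors$sigma2$scale *
                          (1 + (s2 / priors$sigma2$scale)^2))) + par[2]
    k <- 3L
    if (scaling != "none") {
      if (par[k] < priors$scaling$min || par[k] > priors$scaling$max) return(-Inf)
      lp <- lp - log(priors$scaling$max - priors$scaling$min)
      k <- k + 1L
    }
    if (directional) {
      lp <- lp + stats::dnorm(par[k], priors$trend$mean, priors$trend$sd,
                              log = TRUE)
    }
    lp
  }
}

make_bm_loglik_fn <- function(tree, traits, scaling, directional) {
  xt <- match_traits(tree, traits)
  builder <- make_cov_builder(tree, xt$taxon)
  x <- xt$value
  function(par) {
    s2 <- exp(par[2])
    k <- 3L
    val <- 1
    if (scaling != "none") { val <- par[k]; k <- k + 1L }
    C <- builder(scaling, val)
    mu <- rep(par[1], length(x))
    if (directional) mu <- mu + par[k] * diag(C)
    ll <- tryCatch(mvn_loglik(x, mu, C, s2), error = function(e) -Inf)
    if (!is.finite(ll)) -Inf else ll
  }
}

# Adaptive random-walk Metropolis on target log p(x) = logprior + beta*loglik.
# Scales adapt towards ~25% acceptance during the adaptation window only,
# so the post-adaptation chain is a valid Markov chain.
mh_chain <- function(loglik, logprior, init, scales, generations,
                     beta = 1, adapt = floor(generations / 3), thin = 1L) {
  p <- length(init)
  cur <- init
  cur_ll <- loglik(cur)
  cur_lp <- logprior(cur)
  if (!is.finite(cur_lp)) stop("initial state has zero prior density", call. = FALSE)
  n_keep <- floor(generations / thin)
  draws <- matrix(NA_real_, n_keep, p)
  lls <- numeric(n_keep)
  acc <- 0L
  acc_win <- 0L
  kept <- 0L
  for (g in seq_len(generations)) {
    prop <- cur + stats::rnorm(p) * scales
    prop_lp <- logprior(prop)
    if (is.finite(prop_lp)) {
      prop_ll <- loglik(prop)
      logr <- (prop_lp + beta * prop_ll) - (cur_lp + beta * cur_ll)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        cur <- prop; cur_ll <- prop_ll; cur_lp <- prop_lp
        acc <- acc + 1L; acc_win <- acc_win + 1L
      }
    }
    if (g <= adapt && g %% 50L == 0L) {
      rate <- acc_win / 50
      scales <- scales * exp(0.5 * (rate - 0.25))
      acc_win <- 0L
    }
    if (g %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- cur
      lls[kept] <- cur_ll
    }
  }
  list(draws = draws, loglik = lls, acceptance = acc / generations,
       last = cur, scales = scales)
}

#' MCMC sampling of a BM-family model
#'
#' Gibbs-within-Metropolis sampler: the root state (and trend, under the
#' directional model) have exact conjugate normal conditionals given
#' `sigma2` and the scaling value and are drawn directly; `log(sigma2)`
#' and the scaling value are updated by random-walk Metropolis steps with
#' scales adapted during burn-in only. The Cholesky factor of the
#' correlation structure is cached and recomputed only when the scaling
#' value changes. Deterministic given `seed`.
#'
#' @inheritParams fit_ml
#' @param priors list as from [default_priors()] (the default).
#' @param generations total generations.
#' @param burn_in generations discarded (a count if >= 1, else a fraction).
#' @param thin keep every `thin`-th generation after burn-in.
#' @param seed integer RNG seed.
#' @return An object of class `pts_mcmc`: tibble of draws plus settings;
#'   see `tidy()` and `glance()` methods.
#' @export
mcmc_sample <- function(tree, traits, model = c("random_walk", "directional"),
                        scaling = c("none", "delta", "kappa", "lambda"),
                        priors = NULL, generations = 20000L, burn_in = 0.25,
                        thin = 10L, seed = 1L) {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  directional <- model == "directional"
  if (directional && is_ultrametric_tree(tree)) {
    stop("directional model requires a non-ultrametric tree", call. = FALSE)
  }
  if (is.null(priors)) priors <- default_priors(tree, traits, scaling)
  burn <- if (burn_in >= 1) as.integer(burn_in) else floor(burn_in * generations)
  xt <- match_traits(tree, traits)

  set.seed(as.integer(seed))
  main <- bm_gibbs_chain(tree, xt, scaling, directional, priors,
                         generations, burn, thin)
  if (main$acceptance == 0) {
    stop("zero acceptance after adaptation window", call. = FALSE)
  }

  d <- main$draws
  d$generation <- burn + seq_len(nrow(d)) * thin
  structure(list(
    draws = d, model = model, scaling = scaling, priors = priors,
    acceptance = main$acceptance, generations = generations,
    burn_in = burn, thin = thin, seed = as.integer(seed),
    data_hash = hash_traits(traits), tree = tree, traits = traits
  ), class = "pts_mcmc")
}

# Gibbs-within-Metropolis chain for the BM-family posterior.
# root (and trend) are conjugate normal given (sigma2, scaling value) and
# drawn exactly; log sigma2 and the scaling value take adaptive
# random-walk MH steps. The Cholesky of C(scaling value) is cached.
bm_gibbs_chain <- function(tree, xt, scaling, directional, priors,
                           generations, burn, thin) {
  x <- xt$value
  n <- length(x)
  builder <- make_cov_builder(tree, xt$taxon)

  chol_of <- function(val) {
    C <- builder(if (scaling == "none") "none" else scaling, val)
    ch <- tryCatch(chol(C), error = function(e) chol(C + diag(1e-10, n)))
    list(ch = ch, logdet = 2 * sum(log(diag(ch))), depths = diag(C))
  }

  # quadratic form pieces given cached Cholesky and current (root, trend)
  quad_resid <- function(cc, root, trend) {
    mu <- rep(root, n)
    if (directional) mu <- mu + trend * cc$depths
    r <- backsolve(cc$ch, x - mu, transpose = TRUE)
    sum(r^2)
  }
  log_s2_prior <- function(ls2) {
    s2 <- exp(ls2)
    log(2 / (pi * priors$sigma2$scale * (1 + (s2 / priors$sigma2$scale)^2))) +
      ls2
  }

  val <- if (scaling == "none") 1 else 1
  cc <- chol_of(val)
  root <- mean(x)
  trend <- 0
  ls2 <- log(max(priors$sigma2$scale, 1e-8))
  s2_scale <- 0.6
  val_scale <- if (scaling != "none") {
    0.1 * (priors$scaling$max - priors$scaling$min)
  } else 0
  acc_s2 <- acc_val <- 0L
  win_s2 <- win_val <- 0L

  n_keep <- floor((generations - burn) / thin)
  draws <- matrix(NA_real_, n_keep, 2L + (scaling != "none") + directional)
  lls <- numeric(n_keep)
  kept <- 0L

  for (g in seq_len(generations)) {
    s2 <- exp(ls2)
    # --- Gibbs: (root [, trend]) | s2, val -----------------------------
    X <- if (directional) cbind(1, cc$depths) else matrix(1, n, 1)
    Xs <- backsolve(cc$ch, X, transpose = TRUE)
    xs <- backsolve(cc$ch, x, transpose = TRUE)
    prior_prec <- if (directional) {
      diag(c(1 / priors$root$sd^2, 1 / priors$trend$sd^2), 2)
    } else {
      matrix(1 / priors$root$sd^2, 1, 1)
    }
    prior_mean <- if (directional) c(priors$root$mean, priors$trend$mean)
                  else priors$root$mean
    prec <- crossprod(Xs) / s2 + prior_prec
    rhs <- crossprod(Xs, xs) / s2 + prior_prec %*% prior_mean
    chp <- chol(prec)
    mean_beta <- backsolve(chp, backsolve(chp, rhs, transpose = TRUE))
    beta <- drop(mean_beta + backsolve(chp, stats::rnorm(nrow(prec))))
    root <- beta[1]
    if (directional) trend <- beta[2]

    # --- MH: log sigma2 ------------------------------------------------
    q <- quad_resid(cc, root, trend)
    cur_ll <- -0.5 * n * log(2 * pi) - 0.5 * n * ls2 - 0.5 * cc$logdet -
      q / (2 * exp(ls2))
    prop <- ls2 + stats::rnorm(1) * s2_scale
    prop_ll <- -0.5 * n * log(2 * pi) - 0.5 * n * prop - 0.5 * cc$logdet -
      q / (2 * exp(prop))
    if (log(stats::runif(1)) <
        (prop_ll + log_s2_prior(prop)) - (cur_ll + log_s2_prior(ls2))) {
      ls2 <- prop
      cur_ll <- prop_ll
      acc_s2 <- acc_s2 + 1L; win_s2 <- win_s2 + 1L
    }

    # --- MH: scaling value ---------------------------------------------
    if (scaling != "none") {
      prop_val <- val + stats::rnorm(1) * val_scale
      if (prop_val >= priors$scaling$min && prop_val <= priors$scaling$max) {
        cc_prop <- chol_of(prop_val)
        prop_ll <- -0.5 * n * log(2 * pi) - 0.5 * n * ls2 -
          0.5 * cc_prop$logdet -
          quad_resid(cc_prop, root, trend) / (2 * exp(ls2))
        cur_ll <- -0.5 * n * log(2 * pi) - 0.5 * n * ls2 - 0.5 * cc$logdet -
          quad_resid(cc, root, trend) / (2 * exp(ls2))
        if (log(stats::runif(1)) < prop_ll - cur_ll) {
          val <- prop_val
          cc <- cc_prop
          cur_ll <- prop_ll
          acc_val <- acc_val + 1L; win_val <- win_val + 1L
        }
      }
    }

    # --- adapt during burn-in only --------------------------------------
    if (g <= burn && g %% 50L == 0L) {
      s2_scale <- s2_scale * exp(0.5 * (win_s2 / 50 - 0.3))
      if (scaling != "none") {
        val_scale <- val_scale * exp(0.5 * (win_val / 50 - 0.3))
      }
      win_s2 <- win_val <- 0L
    }

    if (g > burn && (g - burn) %% thin == 0L) {
      kept <- kept + 1L
      row <- c(root, exp(ls2))
      if (scaling != "none") row <- c(row, val)
      if (directional) row <- c(row, trend)
      draws[kept, ] <- row
      lls[kept] <- -0.5 * n * log(2 * pi) - 0.5 * n * ls2 - 0.5 * cc$logdet -
        quad_resid(cc, root, trend) / (2 * exp(ls2))
    }
  }

  cn <- c("root", "sigma2",
          if (scaling != "none") "scaling_value",
          if (directional) "trend")
  d <- tibble::as_tibble(stats::setNames(as.data.frame(draws[seq_len(kept), ,
                                                             drop = FALSE]),
                                         cn))
  d$loglik <- lls[seq_len(kept)]
  list(draws = d, acceptance = acc_s2 / generations)
}

hash_traits <- function(traits) {
  x <- tibble::as_tibble(traits)
  paste(nrow(x), paste(x$taxon, collapse = "|"),
        format(sum(x$value), digits = 15),
        format(sum(x$value^2), digits = 15), sep = "#")
}

#' @export
print.pts_mcmc <- function(x, ...) {
  cat("<pts_mcmc> ", x$model,
      if (x$scaling != "none") paste0(" + ", x$scaling),
      ": ", nrow(x$draws), " stored draws (", x$generations,
      " generations, acceptance ", format(x$acceptance, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.pts_mcmc <- function(x, ...) {
  pars <- intersect(c("root", "sigma2", "scaling_value", "trend"),
                    names(x$draws))
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    h <- hpd_interval(v)
    tibble::tibble(term = p, estimate = mean(v), std.error = stats::sd(v),
                   hpd95_low = h[1], hpd95_high = h[2])
  })
}

#' @export
glance.pts_mcmc <- function(x, ...) {
  tibble::tibble(model = x$model, scaling = x$scaling,
                 n_draws = nrow(x$draws), acceptance = x$acceptance,
                 generations = x$generations, seed = x$seed)
}

# empirical 95% highest posterior density interval (shortest interval)
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  w <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(w)
  c(x[i], x[i + k])
}

#' Stepping-stone marginal-likelihood engine
#'
#' Power-posterior path sampling from the prior (beta = 0) to the
#' posterior (beta = 1), with beta values spaced by the quantiles of a
#' Beta(0.3, 1) distribution (concentrating stones near the prior, where
#' the integrand changes fastest). Each stone is a short MCMC run warm
#' started from the previous stone; the log marginal likelihood is
#' assembled from per-stone importance ratios. Exposed separately from the
#' tree models so that conjugate toy problems (with analytic marginals)
#' can exercise exactly the same estimator.
#'
#' @param loglik,logprior functions of the parameter vector.
#' @param init initial parameter vector (must have positive prior density).
#' @param scales initial proposal scales.
#' @param n_stones number of stones (beta intervals).
#' @param gens_per_stone generations per stone.
#' @param alpha_schedule Beta-quantile exponent for the stone schedule.
#' @return List with `log_ml` and the per-stone log ratio contributions.
#' @export
power_posterior_ml <- function(loglik, logprior, init, scales,
                               n_stones = 64L, gens_per_stone = 2000L,
                               alpha_schedule = 0.3) {
  K <- n_stones
  betas <- (seq(0, K) / K)^(1 / alpha_schedule)
  cur <- init
  cur_scales <- scales
  log_ratios <- numeric(K)
  for (k in seq_len(K)) {
    run <- mh_chain(loglik, logprior, cur, cur_scales, gens_per_stone,
                    beta = betas[k], adapt = floor(gens_per_stone / 4))
    ll <- run$loglik
    if (!any(is.finite(ll))) stop("degenerate stone (no finite likelihood)",
                                  call. = FALSE)
    db <- betas[k + 1] - betas[k]
    log_ratios[k] <- log_mean_exp(db * ll)
    cur <- run$last
    cur_scales <- run$scales
  }
  list(log_ml = sum(log_ratios), log_ratios = log_ratios, betas = betas)
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Stepping-stone marginal likelihood of a BM-family model
#'
#' Runs two independent replicate stepping-stone analyses (differing only
#' in seed) and reports both estimates with their difference as a
#' convergence diagnostic; the returned `log_ml` is the replicate mean.
#'
#' @inheritParams mcmc_sample
#' @param n_stones number of stones.
#' @param gens_per_stone generations per stone.
#' @param replicates number of independent replicate runs.
#' @return An object of class `ml_estimate`: `log_ml`, `replicate_log_ml`,
#'   `replicate_diff`, sampler settings, `data_hash`.
#' @export
stepping_stone <- function(tree, traits,
                           model = c("random_walk", "directional"),
                           scaling = c("none", "delta", "kappa", "lambda"),
                           priors = NULL, n_stones = 64L,
                           gens_per_stone = 2000L, replicates = 2L,
                           seed = 1L) {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  directional <- model == "directional"
  if (directional && is_ultrametric_tree(tree)) {
    stop("directional model requires a non-ultrametric tree", call. = FALSE)
  }
  if (is.null(priors)) priors <- default_priors(tree, traits, scaling)
  loglik <- make_bm_loglik_fn(tree, traits, scaling, directional)
  logprior <- make_logprior(priors, scaling, directional)
  xt <- match_traits(tree, traits)
  init <- c(mean(xt$value), log(max(priors$sigma2$scale, 1e-8)))
  scales <- c(stats::sd(xt$value) / 2 + 1e-6, 0.5)
  if (scaling != "none") {
    init <- c(init, 0.5 * (priors$scaling$min + priors$scaling$max))
    scales <- c(scales, 0.1 * (priors$scaling$max - priors$scaling$min))
  }
  if (directional) {
    init <- c(init, 0)
    scales <- c(scales, priors$trend$sd / 10)
  }
  reps <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(as.integer(seed) + (r - 1L) * 1000L)
    reps[r] <- power_posterior_ml(loglik, logprior, init, scales,
                                  n_stones, gens_per_stone)$log_ml
  }
  structure(list(
    log_ml = mean(reps), replicate_log_ml = reps,
    replicate_diff = if (replicates > 1) max(reps) - min(reps) else NA_real_,
    model = model, scaling = scaling, n_stones = n_stones,
    gens_per_stone = gens_per_stone, seed = as.integer(seed),
    data_hash = hash_traits(traits)
  ), class = "ml_estimate")
}

#' @export
print.ml_estimate <- function(x, ...) {
  cat("<ml_estimate> ", x$model,
      if (x$scaling != "none") paste0(" + ", x$scaling),
      ": log ML = ", format(x$log_ml, digits = 7),
      " (replicate diff ", format(x$replicate_diff, digits = 3), "; ",
      x$n_stones, " stones x ", x$gens_per_stone, " gens)\n", sep = "")
  invisible(x)
}

#' @export
glance.ml_estimate <- function(x, ...) {
  tibble::tibble(model = x$model, scaling = x$scaling, log_ml = x$log_ml,
                 replicate_diff = x$replicate_diff, n_stones = x$n_stones,
                 gens_per_stone = x$gens_per_stone)
}

#' Log Bayes-factor comparison of marginal-likelihood estimates
#'
#' Pairwise log Bayes factors in the convention
#' `2 * (log ML_i - log ML_j)`; values above 2 are flagged as positive
#' evidence. All estimates must come from the same trait data.
#'
#' @param estimates a (possibly named) list of [stepping_stone()] results.
#' @return A tibble with one row per ordered model pair: `model_a`,
#'   `model_b`, `log_bf` and `positive_evidence`.
#' @export
compare_models <- function(estimates) {
  if (length(estimates) < 2L) stop("need >= 2 estimates", call. = FALSE)
  stopifnot(all(vapply(estimates, inherits, logical(1), "ml_estimate")))
  hashes <- vapply(estimates, `[[`, character(1), "data_hash")
  if (length(unique(hashes)) > 1L) {
    stop("marginal likelihoods computed on different data", call. = FALSE)
  }
  nm <- names(estimates)
  if (is.null(nm)) nm <- paste0("model", seq_along(estimates))
  labs <- ifelse(nzchar(nm), nm, paste0("model", seq_along(estimates)))
  grid <- expand.grid(a = seq_along(estimates), b = seq_along(estimates))
  grid <- grid[grid$a != grid$b, ]
  tibble::tibble(
    model_a = labs[grid$a],
    model_b = labs[grid$b],
    log_bf = unname(2 * (vapply(estimates[grid$a], `[[`, numeric(1), "log_ml") -
                           vapply(estimates[grid$b], `[[`, numeric(1), "log_ml"))),
  ) |>
    dplyr::mutate(positive_evidence = .data$log_bf > 2)
}

#' Bayesian ancestral state reconstruction
#'
#' For each stored posterior draw the tree is transformed by the drawn
#' scaling value and the ancestral state at each requested node is the
#' conditional (GLS) normal distribution given the tips under BM; a state
#' is sampled from that conditional per draw, the draws pooled across two
#' (or more) independent runs, and each node reported as posterior mean
#' with 95% HPD interval. At a tip the conditional is degenerate at the
#' observed value.
#'
#' @param tree an [ape::phylo].
#' @param traits tibble (`taxon`, `value`).
#' @param fit a `pts_mcmc` chain (posterior ASR) or an `evol_model_fit`
#'   (plug-in ML ASR).
#' @param nodes nodes to reconstruct: `NULL` for all internal nodes, an
#'   integer vector of node numbers, or a named list of tip-label vectors
#'   whose most recent common ancestors are used (named clades).
#' @param runs independent reconstruction runs to pool.
#' @param n_draws_per_run posterior draws resampled per run.
#' @param seed integer RNG seed.
#' @return A tibble of class `asr_result`: `node`, `label`,
#'   `posterior_mean`, `hpd95_low`, `hpd95_high`.
#' @export
reconstruct_ancestors <- function(tree, traits, fit, nodes = NULL,
                                  runs = 2L, n_draws_per_run = 500L,
                                  seed = 1L) {
  xt <- match_traits(tree, traits)
  n <- length(tree$tip.label)
  node_tbl <- resolve_nodes(tree, nodes)
  M <- ape::mrca(tree, full = TRUE)

  if (inherits(fit, "pts_mcmc")) {
    d <- fit$draws
    scaling <- fit$scaling
    directional <- fit$model == "directional"
  } else if (inherits(fit, "evol_model_fit")) {
    scaling <- fit$scaling
    directional <- fit$model == "directional"
    d <- tibble::tibble(root = fit$root_state, sigma2 = fit$sigma2,
                        scaling_value = fit$scaling_value,
                        trend = if (directional) fit$trend else 0)
  } else {
    stop("fit must be a pts_mcmc chain or an evol_model_fit", call. = FALSE)
  }
  if (!"scaling_value" %in% names(d)) d$scaling_value <- 1
  if (!"trend" %in% names(d)) d$trend <- 0

  floored <- tree
  floored$edge.length <- pmax(tree$edge.length, 1e-8)
  base_depths <- ape::node.depth.edgelength(floored)
  Tdepth <- max(base_depths[seq_len(n)])

  set.seed(as.integer(seed))
  samples <- vector("list", runs)
  run_means <- matrix(NA_real_, runs, nrow(node_tbl))
  for (r in seq_len(runs)) {
    rows <- sample.int(nrow(d), n_draws_per_run, replace = TRUE)
    out <- matrix(NA_real_, n_draws_per_run, nrow(node_tbl))
    for (j in seq_len(n_draws_per_run)) {
      dr <- d[rows[j], ]
      nd <- transformed_depths(floored, base_depths, Tdepth,
                               scaling, dr$scaling_value)
      out[j, ] <- draw_ancestral_states(
        xt$value, nd, M, n, node_tbl$node,
        root = dr$root, sigma2 = dr$sigma2,
        trend = if (directional) dr$trend else 0
      )
    }
    samples[[r]] <- out
    run_means[r, ] <- colMeans(out)
  }
  pooled <- do.call(rbind, samples)
  hp <- apply(pooled, 2, hpd_interval)
  res <- tibble::tibble(
    node = node_tbl$node,
    label = node_tbl$label,
    posterior_mean = colMeans(run_means),
    hpd95_low = hp[1, ],
    hpd95_high = hp[2, ]
  )
  class(res) <- c("asr_result", class(res))
  attr(res, "model") <- list(
    source = class(fit)[1],
    model = if (inherits(fit, "pts_mcmc")) fit$model else fit$model,
    scaling = scaling, runs = runs, n_draws_per_run = n_draws_per_run,
    seed = as.integer(seed)
  )
  res
}

resolve_nodes <- function(tree, nodes) {
  n <- length(tree$tip.label)
  if (is.null(nodes)) {
    ids <- n + seq_len(tree$Nnode)
    return(tibble::tibble(node = ids, label = paste0("node", ids)))
  }
  if (is.list(nodes)) {
    ids <- vapply(nodes, function(tips) {
      miss <- setdiff(tips, tree$tip.label)
      if (length(miss)) stop("clade tip(s) not in tree: ",
                             paste(miss, collapse = ", "), call. = FALSE)
      if (length(tips) == 1L) return(match(tips, tree$tip.label))
      ape::getMRCA(tree, tips)
    }, integer(1))
    return(tibble::tibble(node = ids, label = names(nodes)))
  }
  ids <- as.integer(nodes)
  if (any(ids < 1L) || any(ids > n + tree$Nnode)) {
    stop("node number(s) out of range", call. = FALSE)
  }
  tibble::tibble(node = ids, label = paste0("node", ids))
}

# transformed node depths (all nodes, tips first) under one Pagel transform
transformed_depths <- function(tree, base_depths, Tdepth, kind, value) {
  switch(kind,
    none = base_depths,
    delta = Tdepth * (base_depths / Tdepth)^value,
    {
      tt <- transform_tree(tree, kind, value)
      ape::node.depth.edgelength(tt)
    }
  )
}

# one joint draw of ancestral states at `nodes` given tips, under BM with
# mean root + trend * depth and covariance sigma2 * sharedpath
draw_ancestral_states <- function(x, nd, M, n, nodes, root, sigma2, trend) {
  tips <- seq_len(n)
  Ctt <- matrix(nd[M[tips, tips]], n, n)
  ch <- tryCatch(chol(Ctt), error = function(e) chol(Ctt + diag(1e-10, n)))
  mu_t <- root + trend * nd[tips]
  resid <- x - mu_t
  out <- numeric(length(nodes))
  Cnt <- matrix(nd[M[tips, nodes, drop = FALSE]], n, length(nodes))
  W <- backsolve(ch, backsolve(ch, Cnt, transpose = TRUE))
  cond_mean <- root + trend * nd[nodes] + drop(crossprod(W, resid))
  cond_var <- sigma2 * pmax(nd[nodes] - colSums(Cnt * W), 0)
  is_tip <- nodes <= n
  cond_mean[is_tip] <- x[nodes[is_tip]]
  cond_var[is_tip] <- 0
  stats::rnorm(length(nodes), cond_mean, sqrt(cond_var))
}

#' @export
autoplot.asr_result <- function(object, ...) {
  df <- object
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$posterior_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$hpd95_low,
                                          ymax = .data$hpd95_high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "ancestral PTS index (mean, 95% HPD)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
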