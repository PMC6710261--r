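#' Brownian-motion log-likelihood on a (transformed) tree
#'
#' Log-density of the tip trait vector under Brownian motion on the
#' Pagel-transformed tree: multivariate normal with mean `root_state`
#' (plus `trend` times root-to-tip path length under the directional
#' model) and covariance `sigma2` times the shared-path-length matrix of
#' the transformed tree.
#'
#' @param tree an [ape::phylo].
#' @param traits tibble with `taxon`, `value` covering all tips.
#' @param sigma2 Brownian rate (> 0).
#' @param root_state root trait value.
#' @param trend directional trend (per unit transformed branch length),
#'   or `NULL` for the random-walk model.
#' @param scaling `"none"`, `"delta"`, `"kappa"` or `"lambda"`.
#' @param scaling_value transform parameter.
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, traits, sigma2, root_state, trend = NULL,
                      scaling = "none", scaling_value = 1) {
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  xt <- match_traits(tree, traits)
  builder <- make_cov_builder(tree, xt$taxon)
  C <- builder(scaling, scaling_value)
  mu <- rep(root_state, nrow(xt))
  if (!is.null(trend)) mu <- mu + trend * diag(C)
  mvn_loglik(xt$value, mu, C, sigma2)
}

match_traits <- function(tree, traits) {
  traits <- tibble::as_tibble(traits)
  if (!all(c("taxon", "value") %in% names(traits))) {
    stop("traits must have columns taxon, value", call. = FALSE)
  }
  miss <- setdiff(tree$tip.label, traits$taxon)
  if (length(miss)) stop("traits missing for tips: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(is.finite(traits$value))) stop("non-finite trait values", call. = FALSE)
  traits[match(tree$tip.label, traits$taxon), c("taxon", "value")]
}

#' Maximum-likelihood fit of a BM-family model
#'
#' Fits the random-walk (Brownian) or directional model, optionally with
#' one Pagel scaling parameter. The root state (and trend) are profiled by
#' generalised least squares and `sigma2` by its closed form, leaving a
#' bounded one-dimensional search over the scaling value.
#'
#' The directional model is only identifiable on non-ultrametric trees
#' (with all tips equidistant from the root the trend is confounded with
#' the root state), so ultrametric input is rejected for it.
#'
#' @param tree an [ape::phylo] with >= 3 tips.
#' @param traits tibble (`taxon`, `value`).
#' @param model `"random_walk"` or `"directional"`.
#' @param scaling `"none"`, `"delta"`, `"kappa"` or `"lambda"`.
#' @param scaling_bounds search interval; defaults to (0, 3) for delta and
#'   kappa and (0, 1) for lambda.
#' @return An object of class `evol_model_fit`: `sigma2`, `root_state`,
#'   `trend`, `scaling`, `scaling_value`, `log_likelihood`, `model`, `n`.
#' @export
fit_ml <- function(tree, traits, model = c("random_walk", "directional"),
                   scaling = c("none", "delta", "kappa", "lambda"),
                   scaling_bounds = NULL) {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  if (length(tree$tip.label) < 3L) stop("need >= 3 tips", call. = FALSE)
  if (model == "directional" && is_ultrametric_tree(tree)) {
    stop("directional model requires a non-ultrametric tree", call. = FALSE)
  }
  xt <- match_traits(tree, traits)
  builder <- make_cov_builder(tree, xt$taxon)
  x <- xt$value
  n <- length(x)

  profile <- function(value) {
    C <- builder(scaling, value)
    gls_profile(x, C, directional = model == "directional")
  }

  if (scaling == "none") {
    best <- profile(1)
    value <- 1
  } else {
    if (is.null(scaling_bounds)) {
      scaling_bounds <- if (scaling == "lambda") c(0, 1) else c(1e-6, 3)
    }
    opt <- stats::optimize(function(v) -profile(v)$loglik,
                           interval = scaling_bounds, tol = 1e-7)
    value <- opt$minimum
    best <- profile(value)
  }
  structure(list(
    model = model, scaling = scaling, scaling_value = value,
    sigma2 = best$sigma2, root_state = best$root,
    trend = if (model == "directional") best$trend else NULL,
    log_likelihood = best$loglik, n = n,
    n_par = 2L + (scaling != "none") + (model == "directional")
  ), class = "evol_model_fit")
}

# GLS profile of (root [, trend]) and sigma2 given a correlation structure C
gls_profile <- function(x, C, directional = FALSE) {
  n <- length(x)
  ch <- tryCatch(chol(C), error = function(e) chol(C + diag(1e-10, n)))
  X <- if (directional) cbind(1, diag(C)) else matrix(1, n, 1)
  Xs <- backsolve(ch, X, transpose = TRUE)
  xs <- backsolve(ch, x, transpose = TRUE)
  beta <- qr.coef(qr(Xs), xs)
  r <- xs - Xs %*% beta
  sigma2 <- sum(r^2) / n
  loglik <- -0.5 * n * log(2 * pi * sigma2) - sum(log(diag(ch))) - 0.5 * n
  list(root = beta[1], trend = if (directional) beta[2] else NULL,
       sigma2 = sigma2, loglik = loglik)
}

#' @export
print.evol_model_fit <- function(x, ...) {
  cat("<evol_model_fit> ", x$model,
      if (x$scaling != "none") paste0(" + ", x$scaling, " = ",
                                      format(x$scaling_value, digits = 4)),
      "\n  sigma2 = ", format(x$sigma2, digits = 5),
      ", root = ", format(x$root_state, digits = 5),
      if (!is.null(x$trend)) paste0(", trend = ", format(x$trend, digits = 4)),
      ", logL = ", format(x$log_likelihood, digits = 7),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.evol_model_fit <- function(x, ...) {
  terms <- c("sigma2", "root_state",
             if (!is.null(x$trend)) "trend",
             if (x$scaling != "none") x$scaling)
  est <- c(x$sigma2, x$root_state,
           if (!is.null(x$trend)) x$trend,
           if (x$scaling != "none") x$scaling_value)
  tibble::tibble(term = terms, estimate = est)
}

#' @export
glance.evol_model_fit <- function(x, ...) {
  tibble::tibble(model = x$model, scaling = x$scaling,
                 logLik = x$log_likelihood, nobs = x$n, n_par = x$n_par)
}
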