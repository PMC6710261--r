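#' One-sample t-test of the PTS index against a null value
#'
#' Tests whether a group's mean PTS index differs from a reference value,
#' by default 1 — the null under which the groove saddle point lies on the
#' curvature of the lateral tibial facet and the cam has no rise beyond
#' its base circle.
#'
#' @param values numeric vector of species-mean indices (n >= 2, non-zero
#'   spread).
#' @param mu null value.
#' @return One-row tibble: `estimate`, `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need n >= 2", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance sample", call. = FALSE)
  ht <- stats::t.test(values, mu = mu)
  tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value)
}

#' One-way ANOVA with pairwise group comparisons
#'
#' Overall one-way ANOVA across the groups plus all pairwise two-sample
#' comparisons (each pairwise F is the square of the pooled-variance t, a
#' pairwise one-way ANOVA), with a multiple-comparison adjustment on the
#' pairwise p-values (Bonferroni by default).
#'
#' @param data data frame with one row per species.
#' @param value,group column names (strings) of the trait value and the
#'   group label.
#' @param adjust p-adjustment method (see [stats::p.adjust()]).
#' @return An object of class `pts_anova`: `glance()` gives the overall
#'   `F`, `df_between`, `df_within`, `p`; `$pairwise` holds the pairwise
#'   tibble.
#' @export
anova_pairwise <- function(data, value = "value", group = "group",
                           adjust = "bonferroni") {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop("each group needs n >= 2: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(v ~ g)
  an <- stats::anova(fit)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(pr) {
    x1 <- v[g == pr[1]]; x2 <- v[g == pr[2]]
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   F = unname(tt$statistic)^2, df1 = 1,
                   df2 = unname(tt$parameter), p = tt$p.value)
  })
  pw$p_adj <- stats::p.adjust(pw$p, method = adjust)
  structure(list(
    F = an$`F value`[1], df_between = an$Df[1], df_within = an$Df[2],
    p = an$`Pr(>F)`[1], pairwise = pw, adjust = adjust
  ), class = "pts_anova")
}

#' @export
print.pts_anova <- function(x, ...) {
  cat("<pts_anova> F = ", format(x$F, digits = 5), ", df = (", x$df_between,
      ", ", x$df_within, "), p = ", format(x$p, digits = 4), "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' @export
glance.pts_anova <- function(x, ...) {
  tibble::tibble(F = x$F, df_between = x$df_between, df_within = x$df_within,
                 p = x$p)
}

#' @export
tidy.pts_anova <- function(x, ...) x$pairwise

#' Ordinary least-squares regression
#'
#' @param x,y numeric vectors (n >= 3; x must vary).
#' @return One-row tibble: `slope`, `intercept`, `slope_se`, `r2`, `p`
#'   (slope test).
#' @export
ols <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = s$coefficients[2, 2],
                 r2 = s$r.squared,
                 p = s$coefficients[2, 4])
}

#' Phylogenetic generalised least squares regression
#'
#' GLS regression of `y` on `x` with a Brownian-motion correlation
#' structure over the tree (optionally with Pagel's lambda estimated by
#' maximum likelihood). On a star tree with equal branch lengths the BM
#' correlation is the identity and PGLS reduces to OLS. Used in this
#' pipeline for allometry: whether larger taxa have lower PTS indices.
#'
#' @param tree an [ape::phylo].
#' @param data data frame with `taxon` plus the predictor and response
#'   columns; taxa must match the tree tips.
#' @param x,y column names (strings).
#' @param correlation `"bm"` or `"lambda_ml"`.
#' @return One-row tibble: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `p` (slope test), `lambda` (NA unless estimated).
#' @export
pgls <- function(tree, data, x = "x", y = "y",
                 correlation = c("bm", "lambda_ml")) {
  correlation <- match.arg(correlation)
  data <- as.data.frame(data)
  if (!"taxon" %in% names(data)) stop("data needs a `taxon` column", call. = FALSE)
  if (!setequal(data$taxon, tree$tip.label)) {
    stop("taxa mismatch between tree and data", call. = FALSE)
  }
  df <- data[match(tree$tip.label, data$taxon), , drop = FALSE]
  df <- data.frame(taxon = df$taxon, xv = df[[x]], yv = df[[y]])
  if (nrow(df) == 2L) {
    # exact fit through two points
    slope <- diff(df$yv) / diff(df$xv)
    return(tibble::tibble(slope = slope,
                          intercept = df$yv[1] - slope * df$xv[1],
                          slope_se = NA_real_, intercept_se = NA_real_,
                          p = NA_real_, lambda = NA_real_))
  }
  cs <- if (correlation == "bm") {
    ape::corBrownian(1, phy = tree, form = ~taxon)
  } else {
    ape::corPagel(0.5, phy = tree, form = ~taxon, fixed = FALSE)
  }
  fit <- nlme::gls(yv ~ xv, data = df, correlation = cs, method = "ML")
  s <- summary(fit)$tTable
  lam <- if (correlation == "lambda_ml") {
    unname(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  } else {
    NA_real_
  }
  tibble::tibble(slope = s["xv", "Value"], intercept = s["(Intercept)", "Value"],
                 slope_se = s["xv", "Std.Error"],
                 intercept_se = s["(Intercept)", "Std.Error"],
                 p = s["xv", "p-value"], lambda = lam)
}

#' Group bar chart of PTS indices
#'
#' Bar chart of group means with standard-deviation whiskers and the
#' no-cam reference line at index 1.
#'
#' @param data data frame of species means.
#' @param value,group column names.
#' @return A ggplot.
#' @export
plot_pts_by_group <- function(data, value = "value", group = "group") {
  df <- data |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::summarise(mean = mean(.data[[value]]), sd = stats::sd(.data[[value]]),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[group]], y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "PTS index") +
    ggplot2::theme_minimal()
}
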