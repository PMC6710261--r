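#' Select a mesh region
#'
#' Builds a region selection (e.g. the lateral tibial facet, "LTF", or the
#' flexor fibularis groove, "FFG") either from an explicit vertex-id vector
#' or from a label in a region sidecar (see [read_regions()]). Selections
#' below six vertices are refused: they cannot support a cylinder fit or a
#' curvature estimate.
#'
#' @param m a [mesh()].
#' @param ids integer vertex ids (1-based), or `NULL` to look up `label`.
#' @param regions named list of vertex-id vectors (a parsed sidecar).
#' @param label region label to look up in `regions`.
#' @return An object of class `facet_selection`.
#' @export
select_region <- function(m, ids = NULL, regions = NULL, label = NULL) {
  stopifnot(inherits(m, "talus_mesh"))
  if (is.null(ids)) {
    if (is.null(regions) || is.null(label)) {
      stop("supply either `ids` or both `regions` and `label`", call. = FALSE)
    }
    if (!label %in% names(regions)) {
      stop("unknown region label: ", label, call. = FALSE)
    }
    ids <- regions[[label]]
  }
  ids <- as.integer(ids)
  if (anyNA(ids) || any(ids < 1L) || any(ids > nrow(m$vertices))) {
    stop("vertex ids out of range", call. = FALSE)
  }
  ids <- unique(ids)
  if (length(ids) < 6L) {
    stop("selection too small (", length(ids), " vertices; need >= 6)",
         call. = FALSE)
  }
  structure(list(mesh = m, vertex_ids = ids,
                 label = if (is.null(label)) "custom" else label),
            class = "facet_selection")
}

#' @export
print.facet_selection <- function(x, ...) {
  cat("<facet_selection> '", x$label, "': ", length(x$vertex_ids),
      " vertices\n", sep = "")
  invisible(x)
}

#' Best-fit cylinder to a point set
#'
#' Fits an unconstrained cylinder (axis point, axis direction, radius) to
#' the selected vertices by orthogonal least squares, minimising
#' \eqn{\sum_i (d_i - r)^2} where \eqn{d_i} is the distance of point
#' \eqn{i} to the axis. The radius is profiled out (for a fixed axis the
#' optimal \eqn{r} is the mean of the \eqn{d_i}), leaving a 4-parameter
#' axis search initialised from the principal axes of the point cloud with
#' deterministic quasi-random restarts as fallback. Because the fit is
#' unconstrained by the surface, the fitted cylinder need not touch the
#' mesh ("do not contact" behaviour).
#'
#' @param x a `facet_selection` or an `n x 3` point matrix.
#' @param n_restarts extra deterministic direction restarts tried when the
#'   principal-axis starts leave a poor fit.
#' @param tol convergence tolerance on the objective.
#' @return An object of class `cylinder_fit` with `axis_point`,
#'   `axis_direction` (unit), `radius`, `rms_residual`, `n_points`.
#' @export
fit_cylinder <- function(x, n_restarts = 10L, tol = 1e-10) {
  pts <- if (inherits(x, "facet_selection")) {
    x$mesh$vertices[x$vertex_ids, , drop = FALSE]
  } else {
    as.matrix(x)
  }
  if (nrow(pts) < 6L) stop("need at least 6 points", call. = FALSE)
  ctr <- colMeans(pts)
  pc <- pts - rep(ctr, each = nrow(pts))
  cv <- crossprod(pc) / nrow(pts)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] < 1e-12 * ev$values[1]) {
    stop("degenerate geometry: points are collinear", call. = FALSE)
  }
  if (ev$values[3] < 1e-12 * ev$values[1]) {
    stop("degenerate geometry: points are coplanar", call. = FALSE)
  }

  obj_axis <- function(par) {
    # par = (theta, phi, o1, o2): direction angles + axis offset in the
    # plane orthogonal to the direction, relative to the centroid
    u <- c(cos(par[1]) * sin(par[2]), sin(par[1]) * sin(par[2]), cos(par[2]))
    basis <- orthobasis(u)
    a <- basis[, 1] * par[3] + basis[, 2] * par[4]
    w <- pc - rep(a, each = nrow(pc))
    proj <- drop(w %*% u)
    d <- sqrt(pmax(rowSums(w^2) - proj^2, 0))
    sum((d - mean(d))^2)
  }

  dir_to_par <- function(u) {
    u <- u / sqrt(sum(u^2))
    c(atan2(u[2], u[1]), acos(max(-1, min(1, u[3]))), 0, 0)
  }

  starts <- lapply(seq_len(3), function(i) dir_to_par(ev$vectors[, i]))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj_axis, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = tol))
    fit <- stats::optim(fit$par, obj_axis, method = "BFGS",
                        control = list(maxit = 500, reltol = tol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # quasi-random fallback directions (deterministic Fibonacci sphere)
  if (best$value / nrow(pts) > (1e-3 * sqrt(ev$values[1]))^2 && n_restarts > 0) {
    for (i in seq_len(n_restarts)) {
      z <- 1 - 2 * (i - 0.5) / n_restarts
      th <- i * pi * (3 - sqrt(5))
      u <- c(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
      fit <- stats::optim(dir_to_par(u), obj_axis, method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = tol))
      fit <- stats::optim(fit$par, obj_axis, method = "BFGS",
                          control = list(maxit = 500, reltol = tol))
      if (fit$value < best$value) best <- fit
    }
  }

  par <- best$par
  u <- c(cos(par[1]) * sin(par[2]), sin(par[1]) * sin(par[2]), cos(par[2]))
  u <- u / sqrt(sum(u^2))
  basis <- orthobasis(u)
  a <- ctr + basis[, 1] * par[3] + basis[, 2] * par[4]
  w <- pts - rep(a, each = nrow(pts))
  proj <- drop(w %*% u)
  d <- sqrt(pmax(rowSums(w^2) - proj^2, 0))
  r <- mean(d)
  if (r <= 0) stop("cylinder fit failed (non-positive radius)", call. = FALSE)
  # canonical direction sign: first component with |.| > eps is positive
  lead <- which(abs(u) > 1e-8)[1]
  if (u[lead] < 0) u <- -u
  structure(list(
    axis_point = a - u * drop(crossprod(a - ctr, u)),  # foot near centroid
    axis_direction = u,
    radius = r,
    rms_residual = sqrt(mean((d - r)^2)),
    n_points = nrow(pts)
  ), class = "cylinder_fit")
}

# orthonormal basis of the plane orthogonal to unit vector u
orthobasis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- ref - u * sum(ref * u)
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(u[2] * b1[3] - u[3] * b1[2],
          u[3] * b1[1] - u[1] * b1[3],
          u[1] * b1[2] - u[2] * b1[1])
  cbind(b1, b2)
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat("<cylinder_fit> r = ", format(x$radius, digits = 6),
      " mm, rms residual = ", format(x$rms_residual, digits = 3),
      " mm (", x$n_points, " points)\n", sep = "")
  invisible(x)
}

#' Signed distance from a point to a fitted cylinder surface
#'
#' Distance from the point to the cylinder axis minus the radius: positive
#' outside the cylinder, negative inside (the landmark can fall within the
#' best-fit cylinder, so negative values are meaningful).
#'
#' @param point numeric length-3 point, or an `n x 3` matrix.
#' @param cyl a [fit_cylinder()] result.
#' @return Signed distance(s), mm.
#' @export
signed_distance_to_cylinder <- function(point, cyl) {
  stopifnot(inherits(cyl, "cylinder_fit"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  w <- p - rep(cyl$axis_point, each = nrow(p))
  proj <- drop(w %*% cyl$axis_direction)
  d <- sqrt(pmax(rowSums(w^2) - proj^2, 0))
  drop(d - cyl$radius)
}

#' Per-vertex principal curvatures by local quadric fitting
#'
#' For each requested vertex, neighbours within an adaptive radius
#' (a multiple of the mean edge length, grown until at least eight
#' neighbours are found) are projected into a local frame aligned with the
#' area-weighted vertex normal and a quadric height field
#' \eqn{h(x, y) = a x^2 + b x y + c y^2 + d x + e y} is fitted by least
#' squares. Principal curvatures are the eigenvalues of the shape operator
#' of the fitted surface at the vertex.
#'
#' @param m a [mesh()].
#' @param ids vertices to evaluate (default: all).
#' @param neighborhood_factor neighbourhood radius as a multiple of the
#'   mean edge length.
#' @return A tibble with columns `vertex`, `k1`, `k2` (`k1 >= k2`).
#' @export
vertex_curvature <- function(m, ids = seq_len(nrow(m$vertices)),
                             neighborhood_factor = 3) {
  stopifnot(inherits(m, "talus_mesh"))
  V <- m$vertices
  F <- m$faces
  adj <- mesh_adjacency(m)
  mel <- mean_edge_length(m)
  vnorm <- vertex_normals(m)
  h <- neighborhood_factor * mel

  k1 <- k2 <- rep(NA_real_, length(ids))
  for (q in seq_along(ids)) {
    v <- ids[q]
    nb <- neighborhood(adj, V, v, h)
    if (length(nb) < 8L) next
    n <- vnorm[v, ]
    basis <- orthobasis(n)
    rel <- V[nb, , drop = FALSE] - rep(V[v, ], each = length(nb))
    xq <- drop(rel %*% basis[, 1])
    yq <- drop(rel %*% basis[, 2])
    zq <- drop(rel %*% n)
    X <- cbind(xq^2, xq * yq, yq^2, xq, yq)
    cf <- tryCatch(stats::lm.fit(X, zq)$coefficients, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    a <- cf[1]; b <- cf[2]; cc <- cf[3]; d <- cf[4]; e <- cf[5]
    # fundamental forms of z = h(x, y) at the origin
    W <- sqrt(1 + d^2 + e^2)
    E <- 1 + d^2; Ff <- d * e; G <- 1 + e^2
    L <- 2 * a / W; M <- b / W; N <- 2 * cc / W
    S <- matrix(c(L, M, M, N), 2) %*% solve(matrix(c(E, Ff, Ff, G), 2))
    kk <- sort(Re(eigen(S, only.values = TRUE)$values), decreasing = TRUE)
    k1[q] <- kk[1]; k2[q] <- kk[2]
  }
  tibble::tibble(vertex = ids, k1 = k1, k2 = k2)
}

# vertex adjacency list from faces
mesh_adjacency <- function(m) {
  F <- m$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  split(e[, 2], factor(e[, 1], levels = seq_len(nrow(m$vertices))))
}

mean_edge_length <- function(m) {
  F <- m$faces
  V <- m$vertices
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  mean(sqrt(rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2)))
}

vertex_normals <- function(m) {
  V <- m$vertices
  F <- m$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted
  vn <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      vn[, c] <- vn[, c] + tapply_sum(F[, k], fn[, c], nrow(V))
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# breadth-first neighbourhood within Euclidean radius h of vertex v
neighborhood <- function(adj, V, v, h, min_size = 8L, max_grow = 4L) {
  grow <- 0L
  repeat {
    seen <- v
    frontier <- v
    repeat {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      dist <- sqrt(rowSums((V[nxt, , drop = FALSE] -
                              rep(V[v, ], each = length(nxt)))^2))
      nxt <- nxt[dist <= h]
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    nb <- setdiff(seen, v)
    if (length(nb) >= min_size || grow >= max_grow) return(nb)
    h <- h * 1.5
    grow <- grow + 1L
  }
}

#' Locate the flexor fibularis groove landmark
#'
#' In `"saddle"` mode (the usual case: the groove is concave mediolaterally
#' and convex dorsoplantarly), per-vertex principal curvatures are
#' estimated over the groove region and the landmark is the vertex with
#' `k1 > 0 > k2` maximising `|k1 * k2|` — the most saddle-like point. If no
#' saddle candidate exists the error signals the convex case so the caller
#' can switch to `"convex_max"` mode, which returns the vertex of maximal
#' mean-curvature magnitude among vertices whose principal curvatures share
#' a sign (used for the occasional specimen whose groove is convex in both
#' directions). A manual vertex id overrides both modes.
#'
#' @param m a [mesh()].
#' @param groove a `facet_selection` covering the groove.
#' @param mode `"saddle"` or `"convex_max"`.
#' @param landmark_id optional manual vertex id override.
#' @param neighborhood_factor passed to [vertex_curvature()].
#' @return The landmark coordinates (length-3 numeric) with the chosen
#'   vertex id as attribute `"vertex"`.
#' @export
locate_ffg_landmark <- function(m, groove, mode = c("saddle", "convex_max"),
                                landmark_id = NULL, neighborhood_factor = 3) {
  stopifnot(inherits(m, "talus_mesh"), inherits(groove, "facet_selection"))
  mode <- match.arg(mode)
  if (!is.null(landmark_id)) {
    landmark_id <- as.integer(landmark_id)
    if (landmark_id < 1L || landmark_id > nrow(m$vertices)) {
      stop("manual landmark id out of range", call. = FALSE)
    }
    out <- m$vertices[landmark_id, ]
    attr(out, "vertex") <- landmark_id
    attr(out, "mode") <- "manual"
    return(out)
  }
  cur <- vertex_curvature(m, groove$vertex_ids, neighborhood_factor)
  cur <- cur[!is.na(cur$k1), , drop = FALSE]
  if (nrow(cur) == 0L) stop("groove region too small for curvature estimation",
                            call. = FALSE)
  if (mode == "saddle") {
    cand <- cur[cur$k1 > 0 & cur$k2 < 0, , drop = FALSE]
    if (nrow(cand) == 0L) {
      stop("no saddle candidate in groove region; the groove may be convex ",
           "(retry with mode = \"convex_max\")", call. = FALSE)
    }
    pick <- cand$vertex[which.max(abs(cand$k1 * cand$k2))]
  } else {
    cand <- cur[cur$k1 * cur$k2 > 0, , drop = FALSE]
    if (nrow(cand) == 0L) stop("no convex candidate in groove region",
                               call. = FALSE)
    pick <- cand$vertex[which.max(abs(cand$k1 + cand$k2) / 2)]
  }
  out <- m$vertices[pick, ]
  attr(out, "vertex") <- pick
  attr(out, "mode") <- mode
  out
}

#' Measure the PTS index of one specimen
#'
#' Runs the full measurement protocol: best-fit cylinder to the lateral
#' tibial facet selection (its radius is the cam base-circle radius and its
#' axis models the talocrural joint axis), groove landmark placement,
#' signed landmark-to-cylinder distance, and the index itself. The identity
#' `axis_to_groove = radius + groove_to_cylinder` holds exactly by
#' construction, and `pts_index = axis_to_groove / radius`. The natural-log
#' transform of the index is stored alongside (defined only for positive
#' indices); downstream analyses use the raw index by default.
#'
#' @param m a [mesh()].
#' @param ltf facet selection for the lateral tibial facet.
#' @param ffg facet selection for the flexor fibularis groove.
#' @param specimen_id,taxon identifiers carried into the output row.
#' @param mode,landmark_id passed to [locate_ffg_landmark()].
#' @return A one-row tibble with columns `specimen`, `taxon`, `radius`,
#'   `groove_to_cylinder`, `axis_to_groove`, `pts_index`, `ln_pts_index`,
#'   with the cylinder fit and a log record attached as attributes.
#' @export
measure_specimen <- function(m, ltf, ffg, specimen_id = "specimen",
                             taxon = NA_character_,
                             mode = c("saddle", "convex_max"),
                             landmark_id = NULL) {
  mode <- match.arg(mode)
  cyl <- fit_cylinder(ltf)
  lmk <- locate_ffg_landmark(m, ffg, mode = mode, landmark_id = landmark_id)
  g2c <- signed_distance_to_cylinder(as.numeric(lmk), cyl)
  a2g <- cyl$radius + g2c
  idx <- a2g / cyl$radius
  out <- tibble::tibble(
    specimen = specimen_id,
    taxon = taxon,
    radius = cyl$radius,
    groove_to_cylinder = g2c,
    axis_to_groove = a2g,
    pts_index = idx,
    ln_pts_index = if (idx > 0) log(idx) else NA_real_
  )
  attr(out, "cylinder_fit") <- cyl
  attr(out, "log") <- list(rms_residual = cyl$rms_residual,
                           landmark_mode = attr(lmk, "mode"),
                           landmark_vertex = attr(lmk, "vertex"))
  out
}

#' Write or read a measurement table
#'
#' The CSV mirrors the column layout of per-specimen measurement databases
#' for this protocol: `Specimen, Taxon, Radius, GrooveToCylinder,
#' AxisToGroove, PTSIndex, LnPTSIndex`.
#'
#' @param measurements a tibble of [measure_specimen()] rows.
#' @param path CSV path.
#' @return `path` (writer) or a tibble in package-internal column names
#'   (reader).
#' @export
write_measurements <- function(measurements, path) {
  out <- data.frame(
    Specimen = measurements$specimen,
    Taxon = measurements$taxon,
    Radius = measurements$radius,
    GrooveToCylinder = measurements$groove_to_cylinder,
    AxisToGroove = measurements$axis_to_groove,
    PTSIndex = measurements$pts_index,
    LnPTSIndex = measurements$ln_pts_index
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    specimen = as.character(x$Specimen),
    taxon = as.character(x$Taxon),
    radius = x$Radius,
    groove_to_cylinder = x$GrooveToCylinder,
    axis_to_groove = x$AxisToGroove,
    pts_index = x$PTSIndex,
    ln_pts_index = x$LnPTSIndex
  )
}

#' Species means from specimen measurements
#'
#' Collapses a per-specimen measurement table to per-taxon means with
#' sample sizes; comparative analyses are run on species means.
#'
#' @param measurements tibble with at least `taxon` and `pts_index`.
#' @return tibble with `taxon`, `value` (mean PTS index), `n`.
#' @export
species_means <- function(measurements) {
  measurements |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(value = mean(.data$pts_index), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::rename(taxon = "taxon")
}
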