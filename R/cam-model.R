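#' Cam profile for the talus-as-cam model
#'
#' A two-dimensional (sagittal-plane) abstraction of the talus as the
#' driver of a cam-follower mechanism: a base circle of radius equal to the
#' talocrural (best-fit cylinder) radius, plus a smooth raised-cosine
#' "rise" representing the posterior trochlear shelf. The flexor fibularis
#' tendon is the follower: a taut string from a proximal origin to a distal
#' insertion that must not cross the cam body. The profile rotates by the
#' flexion angle while the endpoints stay fixed, so the computed
#' path-length change isolates the rise-induced cam effect: a circular
#' profile (zero rise) produces no excursion.
#'
#' Coordinates: the talocrural axis is at the origin, +y is proximal
#' (towards the muscle origin), +x is posterior (towards the tendon). The
#' default geometry places the origin at `(1.1 r, 10 r)` and the insertion
#' at `(1.1 r, -3 r)`: the taut tendon then clears the base circle by
#' `0.1 r`, so only a rise taller than that clearance engages it. Positive
#' flexion angles are dorsiflexion; the default `rise_center` of `-pi/4`
#' puts the rise posteroplantar in neutral pose so that dorsiflexion
#' rotates it into the tendon path, maximising path length in dorsiflexed
#' postures.
#'
#' @param base_radius base-circle radius, mm (> 0).
#' @param rise_height signed rise height, mm; `rise_height / base_radius
#'   + 1` equals the PTS index. `base_radius + rise_height` must be > 0.
#' @param rise_center angular position (rad) of the rise on the profile,
#'   measured from +x in the cam's body frame.
#' @param rise_width angular width (rad) of the raised-cosine rise, in
#'   (0, pi).
#' @param origin_point,insertion_point 2-D points (mm); defaults as above.
#' @return An object of class `cam_profile`.
#' @export
cam_profile <- function(base_radius, rise_height, rise_center = -pi / 4,
                        rise_width = pi / 2, origin_point = NULL,
                        insertion_point = NULL) {
  if (base_radius <= 0) stop("base_radius must be > 0", call. = FALSE)
  if (base_radius + rise_height <= 0) {
    stop("base_radius + rise_height must be > 0", call. = FALSE)
  }
  if (rise_width <= 0 || rise_width >= pi) {
    stop("rise_width must lie in (0, pi)", call. = FALSE)
  }
  if (is.null(origin_point)) origin_point <- c(1.1, 10) * base_radius
  if (is.null(insertion_point)) insertion_point <- c(1.1 * base_radius,
                                                     -3 * base_radius)
  structure(list(base_radius = base_radius, rise_height = rise_height,
                 rise_center = rise_center, rise_width = rise_width,
                 origin_point = as.numeric(origin_point),
                 insertion_point = as.numeric(insertion_point)),
            class = "cam_profile")
}

#' Build a cam profile from a PTS index
#'
#' The rise height is `(pts_index - 1) * base_radius`: an index of 1 is a
#' circular cam (no rise), indices above 1 are strongly developed cams,
#' and indices below 1 sink the rise inside the base circle.
#'
#' @param pts_index dimensionless PTS index (> 0).
#' @param base_radius base-circle radius, mm.
#' @param ... further arguments to [cam_profile()].
#' @return A `cam_profile`.
#' @export
profile_from_index <- function(pts_index, base_radius, ...) {
  if (pts_index <= 0) stop("pts_index must be > 0", call. = FALSE)
  cam_profile(base_radius, (pts_index - 1) * base_radius, ...)
}

# polar radius of the profile at body-frame angle psi
profile_radius <- function(profile, psi) {
  d <- (psi - profile$rise_center + pi) %% (2 * pi) - pi
  bump <- ifelse(abs(d) <= profile$rise_width / 2,
                 0.5 * (1 + cos(2 * pi * d / profile$rise_width)), 0)
  profile$base_radius + profile$rise_height * bump
}

#' Polygonal discretisation of a rotated cam profile
#'
#' @param profile a [cam_profile()].
#' @param theta flexion angle, rad (positive = dorsiflexion).
#' @param n number of polygon vertices (>= 64).
#' @return An `n x 2` matrix of world-frame polygon vertices.
#' @export
cam_polygon <- function(profile, theta = 0, n = 2048L) {
  stopifnot(n >= 64L)
  psi_world <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rho <- profile_radius(profile, psi_world - theta)
  cbind(rho * cos(psi_world), rho * sin(psi_world))
}

#' Tendon path length at a flexion angle
#'
#' Length of the taut string (shortest path avoiding the cam body) from
#' the muscle origin to the tendon insertion, with the cam cross-section
#' rotated by `theta`. The profile is discretised into a dense polygon; if
#' the straight origin-insertion segment clears the polygon the length is
#' the Euclidean distance, otherwise the string wraps the convex hull of
#' the profile and the shorter of the two wrap chains is returned (a taut
#' string cannot enter concavities, so hull chords across the rise
#' shoulders are exactly the taut configuration).
#'
#' @param profile a [cam_profile()].
#' @param theta flexion angle, rad.
#' @param n polygon resolution (default 2048 segments).
#' @return Path length, mm.
#' @export
tendon_path_length <- function(profile, theta, n = 2048L) {
  poly <- cam_polygon(profile, theta, n)
  O <- profile$origin_point
  I <- profile$insertion_point
  if (point_in_polygon(O, poly) || point_in_polygon(I, poly)) {
    stop("origin or insertion lies inside the cam body", call. = FALSE)
  }
  if (!segment_blocked(O, I, poly)) {
    return(sqrt(sum((O - I)^2)))
  }
  wrap_length(O, I, poly)
}

# does segment a-b intersect the polygon boundary (or pass through it)?
segment_blocked <- function(a, b, poly) {
  p1 <- poly
  p2 <- poly[c(2:nrow(poly), 1L), , drop = FALSE]
  d <- b - a
  # cross products for orientation tests, vectorised over edges
  r1 <- d[1] * (p1[, 2] - a[2]) - d[2] * (p1[, 1] - a[1])
  r2 <- d[1] * (p2[, 2] - a[2]) - d[2] * (p2[, 1] - a[1])
  e <- p2 - p1
  s1 <- e[, 1] * (a[2] - p1[, 2]) - e[, 2] * (a[1] - p1[, 1])
  s2 <- e[, 1] * (b[2] - p1[, 2]) - e[, 2] * (b[1] - p1[, 1])
  any(r1 * r2 < 0 & s1 * s2 < 0)
}

point_in_polygon <- function(p, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- (y > p[2]) != (yn > p[2])
  xint <- x + (p[2] - y) / (yn - y) * (xn - x)
  sum(cross & p[1] < xint) %% 2 == 1
}

# shortest wrap around the polygon via its convex hull: take the hull of
# {O, I, polygon}, split the hull cycle at O and I, return the shorter chain
wrap_length <- function(O, I, poly) {
  pts <- rbind(O, I, poly)
  h <- grDevices::chull(pts)
  iO <- match(1L, h)
  iI <- match(2L, h)
  if (is.na(iO) || is.na(iI)) {
    # an endpoint fell inside the hull of the cam: taut path hugs the hull
    # between tangent points; fall back to rubber-band relaxation
    return(rubber_band_length(O, I, poly))
  }
  cyc <- pts[h, , drop = FALSE]
  k <- nrow(cyc)
  idx <- seq_len(k)
  if (iO < iI) {
    chain1 <- cyc[iO:iI, , drop = FALSE]
    chain2 <- cyc[c(iI:k, 1:iO), , drop = FALSE]
  } else {
    chain1 <- cyc[iI:iO, , drop = FALSE]
    chain2 <- cyc[c(iO:k, 1:iI), , drop = FALSE]
  }
  min(chain_length(chain1), chain_length(chain2))
}

chain_length <- function(ch) {
  if (nrow(ch) < 2L) return(0)
  sum(sqrt(rowSums((ch[-1, , drop = FALSE] - ch[-nrow(ch), , drop = FALSE])^2)))
}

# iterative shortening of a path threaded around one side of the polygon;
# used as fallback and by tests as an independent oracle
rubber_band_length <- function(O, I, poly, side = NULL) {
  best <- Inf
  for (s in if (is.null(side)) c(1, -1) else side) {
    path <- thread_path(O, I, poly, s)
    repeat {
      changed <- FALSE
      i <- 2L
      while (i < nrow(path)) {
        if (!segment_blocked(path[i - 1L, ], path[i + 1L, ], poly)) {
          path <- path[-i, , drop = FALSE]
          changed <- TRUE
        } else {
          i <- i + 1L
        }
      }
      if (!changed) break
    }
    best <- min(best, chain_length(path))
  }
  best
}

# initial path from O to I following the polygon boundary on one side
thread_path <- function(O, I, poly, s) {
  angO <- atan2(O[2], O[1])
  angI <- atan2(I[2], I[1])
  ang <- atan2(poly[, 2], poly[, 1])
  if (s > 0) {
    sel <- ((ang - angO) %% (2 * pi)) <= ((angI - angO) %% (2 * pi))
    ord <- order((ang[sel] - angO) %% (2 * pi))
  } else {
    sel <- ((angO - ang) %% (2 * pi)) <= ((angO - angI) %% (2 * pi))
    ord <- order((angO - ang[sel]) %% (2 * pi))
  }
  mid <- poly[sel, , drop = FALSE][ord, , drop = FALSE]
  # push boundary points slightly outwards so the initial path is valid
  mid <- mid * (1 + 1e-9)
  rbind(O, mid, I)
}

#' Tendon path length across a range of flexion angles
#'
#' Samples [tendon_path_length()] on a uniform angle grid and reports the
#' angle of maximal path length and the total excursion (max minus min
#' length) — the quantity the cam mechanism is hypothesised to convert
#' into tendon translation.
#'
#' @param profile a [cam_profile()].
#' @param theta_min,theta_max angle range, rad.
#' @param n number of grid points.
#' @param n_polygon polygon resolution per evaluation.
#' @return A tibble of class `path_length_curve` with columns `angle`
#'   (rad) and `length` (mm); attributes `argmax_angle` and `excursion`.
#' @export
cam_excursion <- function(profile, theta_min = -pi / 3, theta_max = pi / 3,
                          n = 121L, n_polygon = 2048L) {
  if (theta_min >= theta_max) stop("theta_min must be < theta_max", call. = FALSE)
  angles <- seq(theta_min, theta_max, length.out = n)
  lengths <- vapply(angles, function(th) tendon_path_length(profile, th, n_polygon),
                    numeric(1))
  out <- tibble::tibble(angle = angles, length = lengths)
  class(out) <- c("path_length_curve", class(out))
  attr(out, "argmax_angle") <- angles[which.max(lengths)]
  attr(out, "excursion") <- max(lengths) - min(lengths)
  attr(out, "profile") <- profile
  out
}

#' @export
autoplot.path_length_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$angle * 180 / pi,
                                       y = .data$length)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "flexion angle (deg; + dorsiflexion)",
                  y = "tendon path length (mm)") +
    ggplot2::theme_minimal()
}
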