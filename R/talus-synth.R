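#' Specify a synthetic talus
#'
#' Defines the ground-truth geometry for a synthetic talus-like mesh: a
#' partial-cylinder "trochlea" of known radius (standing in for the lateral
#' tibial facet) and a saddle-shaped "flexor fibularis groove" patch whose
#' saddle point sits at a known signed offset beyond (+) or inside (-) the
#' trochlear base circle. The true PTS index of such a specimen is
#' `(trochlea_radius + shelf_offset) / trochlea_radius`.
#'
#' @param trochlea_radius cylinder radius, mm (> 0).
#' @param trochlea_arc angular extent of the cylindrical facet, degrees,
#'   in (30, 270).
#' @param shelf_offset signed distance (mm) of the groove saddle point
#'   beyond (+) or inside (-) the base circle. Must satisfy
#'   `trochlea_radius + shelf_offset > 0`.
#' @param groove_curvatures length-2 numeric, principal curvatures (1/mm)
#'   of the groove patch at the saddle point; must have opposite signs.
#' @param mesh_resolution target edge length, mm (> 0). Must resolve the
#'   saddle: coarser than the smallest principal curvature radius is
#'   rejected.
#' @param noise_sd standard deviation (mm) of Gaussian vertex noise applied
#'   along vertex normals after region tagging.
#' @param seed integer RNG seed; recorded in the output.
#' @return An object of class `talus_spec`.
#' @export
synthetic_talus_spec <- function(trochlea_radius = 3, trochlea_arc = 120,
                                 shelf_offset = 1.5,
                                 groove_curvatures = c(0.8, -0.8),
                                 mesh_resolution = 0.1, noise_sd = 0,
                                 seed = 1L) {
  stopifnot(length(trochlea_radius) == 1, length(shelf_offset) == 1,
            length(groove_curvatures) == 2)
  if (trochlea_radius <= 0) stop("trochlea_radius must be > 0", call. = FALSE)
  if (trochlea_arc <= 30 || trochlea_arc >= 270) {
    stop("trochlea_arc must lie in (30, 270) degrees", call. = FALSE)
  }
  if (trochlea_radius + shelf_offset <= 0) {
    stop("trochlea_radius + shelf_offset must be > 0", call. = FALSE)
  }
  if (prod(sign(groove_curvatures)) >= 0) {
    stop("groove_curvatures must have opposite signs (saddle)", call. = FALSE)
  }
  if (mesh_resolution <= 0) stop("mesh_resolution must be > 0", call. = FALSE)
  if (mesh_resolution > min(1 / abs(groove_curvatures))) {
    stop("mesh_resolution coarser than the principal curvature radii: ",
         "saddle unresolvable", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(
    trochlea_radius = trochlea_radius, trochlea_arc = trochlea_arc,
    shelf_offset = shelf_offset, groove_curvatures = sort(groove_curvatures,
                                                          decreasing = TRUE),
    mesh_resolution = mesh_resolution, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "talus_spec")
}

#' Generate a synthetic talus mesh with ground truth
#'
#' Builds a triangle mesh with two tagged regions in a canonical pose: the
#' talocrural axis is the x-axis, the cylindrical facet faces dorsally
#' (+z) and the saddle groove patch sits posteriorly (-z) at the specified
#' offset from the base circle. Gaussian noise (if any) is applied along
#' analytic vertex normals after the regions are tagged, mimicking surface
#' scan roughness without destroying topology.
#'
#' @param spec a [synthetic_talus_spec()].
#' @return A list with elements `mesh` (a [mesh()]) and `truth`, a
#'   `talus_truth` list carrying `true_axis` (point + unit direction),
#'   `true_radius`, `true_saddle_point`, `true_pts_index`,
#'   `facet_vertex_ids`, `groove_vertex_ids` and `seed`.
#' @export
make_synthetic_talus <- function(spec) {
  stopifnot(inherits(spec, "talus_spec"))
  r <- spec$trochlea_radius
  res <- spec$mesh_resolution
  k1 <- spec$groove_curvatures[1]
  k2 <- spec$groove_curvatures[2]
  R0 <- r + spec$shelf_offset

  # --- cylindrical facet (axis = x-axis, centred on +z) ---
  half_arc <- spec$trochlea_arc / 2 * pi / 180
  len <- 1.5 * r
  xs <- seq(-len / 2, len / 2, by = res)
  phis <- seq(-half_arc, half_arc, by = res / r)
  fg <- expand.grid(x = xs, phi = phis)
  facet_v <- cbind(fg$x, r * sin(fg$phi), r * cos(fg$phi))
  facet_n <- cbind(0, sin(fg$phi), cos(fg$phi))
  facet_f <- grid_faces(length(xs), length(phis))

  # --- saddle groove patch at (0, 0, -R0) ---
  # height field z(u, v) = -R0 + (k1 u^2 + k2 v^2) / 2 over a patch small
  # enough that the curvature magnitudes peak at the centre
  hw <- min(0.6 / abs(k1), 0.6 / abs(k2), 0.8 * r)
  us <- seq(-hw, hw, by = res)
  vs <- seq(-hw, hw, by = res)
  gg <- expand.grid(u = us, v = vs)
  gz <- -R0 + (k1 * gg$u^2 + k2 * gg$v^2) / 2
  groove_v <- cbind(gg$u, gg$v, gz)
  gn <- cbind(-k1 * gg$u, -k2 * gg$v, 1)
  groove_n <- gn / sqrt(rowSums(gn^2))
  groove_f <- grid_faces(length(us), length(vs)) + nrow(facet_v)

  verts <- rbind(facet_v, groove_v)
  faces <- rbind(facet_f, groove_f)
  facet_ids <- seq_len(nrow(facet_v))
  groove_ids <- nrow(facet_v) + seq_len(nrow(groove_v))

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    normals <- rbind(facet_n, groove_n)
    verts <- verts + normals * stats::rnorm(nrow(verts), sd = spec$noise_sd)
  }

  m <- mesh(verts, faces, clean = FALSE)
  class(m) <- "talus_mesh"
  truth <- structure(list(
    true_axis = list(point = c(0, 0, 0), direction = c(1, 0, 0)),
    true_radius = r,
    true_saddle_point = c(0, 0, -R0),
    true_pts_index = R0 / r,
    facet_vertex_ids = facet_ids,
    groove_vertex_ids = groove_ids,
    seed = spec$seed
  ), class = "talus_truth")
  list(mesh = m, truth = truth)
}

# triangulate an nu x nv structured grid stored with u varying fastest
grid_faces <- function(nu, nv) {
  i <- rep(seq_len(nu - 1L), nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  a <- (j - 1L) * nu + i
  b <- a + 1L
  c <- a + nu
  d <- c + 1L
  rbind(cbind(a, b, d), cbind(a, d, c))
}

#' Write a synthetic talus with its region sidecar
#'
#' Convenience wrapper used by the pipeline and fixtures: writes the mesh
#' as ASCII PLY and the facet/groove vertex tags as a JSON sidecar with
#' labels `"LTF"` and `"FFG"`.
#'
#' @param talus a list as returned by [make_synthetic_talus()].
#' @param mesh_path,regions_path output paths.
#' @return `mesh_path`, invisibly.
#' @export
write_synthetic_talus <- function(talus, mesh_path, regions_path) {
  write_mesh(talus$mesh, mesh_path)
  write_regions(list(LTF = talus$truth$facet_vertex_ids,
                     FFG = talus$truth$groove_vertex_ids), regions_path)
  invisible(mesh_path)
}
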