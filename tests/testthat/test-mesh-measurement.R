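# shared fixtures: one clean synthetic talus, built once
talus15 <- make_synthetic_talus(synthetic_talus_spec(
  trochlea_radius = 3, shelf_offset = 1.5, mesh_resolution = 0.12))

cyl_points <- function(r = 3, arc = 120, n = 200, seed = NULL, sd = 0) {
  phis <- seq(-arc / 2, arc / 2, length.out = 20) * pi / 180
  xs <- seq(-2, 2, length.out = 10)
  g <- expand.grid(x = xs, phi = phis)
  pts <- cbind(g$x, r * sin(g$phi), r * cos(g$phi))
  if (sd > 0) {
    set.seed(seed)
    pts <- pts + rnorm(length(pts), sd = sd)
  }
  pts
}

test_that("mesh IO round-trips and cleans degenerate input", {
  tmp <- withr::local_tempdir()
  ply <- file.path(tmp, "t.ply")
  write_mesh(talus15$mesh, ply)
  back <- read_mesh(ply)
  expect_equal(nrow(back$vertices), nrow(talus15$mesh$vertices))
  expect_equal(back$vertices, unname(talus15$mesh$vertices),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(nrow(back$faces), nrow(talus15$mesh$faces))

  # STL stores each face's vertices independently; loading merges them
  stl <- file.path(tmp, "t.stl")
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))
  F <- matrix(c(1L, 2L, 3L, 2L, 3L, 4L), ncol = 3, byrow = TRUE)
  lines <- c("solid t")
  for (f in 1:2) {
    lines <- c(lines, " facet normal 0 0 1", "  outer loop",
               paste("   vertex", apply(V[F[f, ], ], 1, paste, collapse = " ")),
               "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid t"), stl)
  m <- read_mesh(stl)
  expect_lt(nrow(m$vertices), attr(m, "n_raw_vertices"))
  expect_equal(nrow(m$vertices), 4)

  # zero-face input is an error
  empty <- file.path(tmp, "e.ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 0",
               "property float x", "property float y", "property float z",
               "element face 0", "property list uchar int vertex_indices",
               "end_header"), empty)
  expect_error(read_mesh(empty))

  # region sidecar round trip
  js <- file.path(tmp, "t.json")
  write_regions(list(LTF = 1:10, FFG = 11:20), js)
  expect_identical(read_regions(js)$FFG, 11:20)
})

test_that("region selection validates ids, labels and minimum size", {
  m <- talus15$mesh
  truth <- talus15$truth
  regions <- list(LTF = truth$facet_vertex_ids, FFG = truth$groove_vertex_ids)
  sel <- select_region(m, regions = regions, label = "LTF")
  expect_setequal(sel$vertex_ids, truth$facet_vertex_ids)
  expect_error(select_region(m, regions = regions, label = "XYZ"), "unknown")
  expect_error(select_region(m, ids = c(1, 2, 3)), "too small")
  expect_error(select_region(m, ids = c(1:5, nrow(m$vertices) + 1)),
               "out of range")
})

test_that("cylinder fit recovers exact and noisy sector data", {
  pts <- cyl_points()
  fit <- fit_cylinder(pts)
  expect_equal(fit$radius, 3, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-6)
  cosang <- abs(sum(fit$axis_direction * c(1, 0, 0)))
  expect_gt(cosang, cos(0.01 * pi / 180))

  # noisy fixture agrees with the multi-start Levenberg-Marquardt oracle
  ptsn <- cyl_points(seed = 31, sd = 0.01)
  fitn <- fit_cylinder(ptsn)
  expect_equal(fitn$radius, 3, tolerance = 0.02)
  oracle <- oracle_cylinder_fit(ptsn)
  expect_lt(abs(fitn$radius - oracle$radius), 1e-4)

  # degenerate inputs
  plane <- cbind(runif(50), runif(50), 0)
  expect_error(fit_cylinder(plane), "coplanar")
  line <- cbind(seq_len(20), 2 * seq_len(20), 3 * seq_len(20))
  expect_error(fit_cylinder(line), "collinear")
})

test_that("signed distance to the cylinder surface is signed correctly", {
  cyl <- structure(list(axis_point = c(0, 0, 0),
                        axis_direction = c(0, 0, 1), radius = 2),
                   class = "cylinder_fit")
  expect_equal(signed_distance_to_cylinder(c(3, 0, 0), cyl), 1.0)
  expect_equal(signed_distance_to_cylinder(c(1.5, 0, 0), cyl), -0.5)
  expect_equal(signed_distance_to_cylinder(c(0, 2, 5), cyl), 0.0)
})

test_that("saddle landmark detection finds analytic saddles and rejects convex patches", {
  # meshed analytic saddle z = x^2 - y^2
  g <- expand.grid(x = seq(-1, 1, by = 0.08), y = seq(-1, 1, by = 0.08))
  nu <- length(seq(-1, 1, by = 0.08))
  verts <- cbind(g$x, g$y, g$x^2 - g$y^2)
  faces <- ptscam:::grid_faces(nu, nu)
  m <- mesh(verts, faces)
  sel <- select_region(m, ids = seq_len(nrow(verts)))
  lmk <- locate_ffg_landmark(m, sel, mode = "saddle")
  expect_lt(sqrt(sum(lmk^2)), 0.12)  # within ~one edge length of the origin

  # convex bowl: saddle mode refuses, convex_max finds the apex
  verts2 <- cbind(g$x, g$y, g$x^2 + g$y^2)
  m2 <- mesh(verts2, faces)
  sel2 <- select_region(m2, ids = seq_len(nrow(verts2)))
  expect_error(locate_ffg_landmark(m2, sel2, mode = "saddle"), "convex")
  apex <- locate_ffg_landmark(m2, sel2, mode = "convex_max")
  expect_lt(sqrt(sum(apex[1:2]^2)), 0.12)

  # manual override returns the requested vertex
  manual <- locate_ffg_landmark(m, sel, landmark_id = 5L)
  expect_equal(as.numeric(manual), unname(verts[5, ]))
})

test_that("synthetic talus landmark lands on the generator's saddle point", {
  truth <- talus15$truth
  ffg <- select_region(talus15$mesh, ids = truth$groove_vertex_ids)
  lmk <- locate_ffg_landmark(talus15$mesh, ffg, mode = "saddle")
  expect_lt(sqrt(sum((as.numeric(lmk) - truth$true_saddle_point)^2)), 0.12)
})

test_that("end-to-end measurement recovers the true index within 2%", {
  cases <- list(c(radius = 3, offset = 1.5, lo = 1.47, hi = 1.53),
                c(radius = 3, offset = 0, lo = 0.98, hi = 1.02),
                c(radius = 2, offset = -0.6, lo = 0.686, hi = 0.714))
  for (cs in cases) {
    tal <- make_synthetic_talus(synthetic_talus_spec(
      trochlea_radius = cs[["radius"]], shelf_offset = cs[["offset"]],
      mesh_resolution = 0.12))
    m <- measure_specimen(
      tal$mesh,
      select_region(tal$mesh, ids = tal$truth$facet_vertex_ids),
      select_region(tal$mesh, ids = tal$truth$groove_vertex_ids),
      specimen_id = "s", taxon = "t")
    expect_gte(m$pts_index, cs[["lo"]])
    expect_lte(m$pts_index, cs[["hi"]])
    # the defining identity holds exactly
    expect_identical(m$axis_to_groove, m$radius + m$groove_to_cylinder)
    expect_identical(m$pts_index, m$axis_to_groove / m$radius)
  }
})

test_that("pts_index is rigid-motion invariant, scale-free, and monotone in offset", {
  measure_mesh <- function(tal) {
    measure_specimen(
      tal$mesh,
      select_region(tal$mesh, ids = tal$truth$facet_vertex_ids),
      select_region(tal$mesh, ids = tal$truth$groove_vertex_ids),
      "s", "t")$pts_index
  }
  base_idx <- measure_mesh(talus15)

  # rigid motion
  ang <- 0.7
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  moved <- talus15
  moved$mesh$vertices <- talus15$mesh$vertices %*% R +
    rep(c(10, -4, 2), each = nrow(talus15$mesh$vertices))
  expect_lt(abs(measure_mesh(moved) - base_idx), 1e-6)

  # uniform scaling leaves the dimensionless index unchanged
  scaled <- talus15
  scaled$mesh$vertices <- talus15$mesh$vertices * 2.5
  expect_lt(abs(measure_mesh(scaled) - base_idx), 1e-6)

  # monotonicity across shelf offsets at fixed radius
  idxs <- vapply(c(-0.6, 0, 0.5, 1.0, 1.5), function(off) {
    measure_mesh(make_synthetic_talus(synthetic_talus_spec(
      trochlea_radius = 3, shelf_offset = off, mesh_resolution = 0.15)))
  }, numeric(1))
  expect_true(all(diff(idxs) > 0))
})

test_that("measurement tables round-trip through the CSV layout", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  rows <- measure_specimen(
    talus15$mesh,
    select_region(talus15$mesh, ids = talus15$truth$facet_vertex_ids),
    select_region(talus15$mesh, ids = talus15$truth$groove_vertex_ids),
    "spec1", "Genus_species")
  write_measurements(rows, tmp)
  hdr <- names(read.csv(tmp, nrows = 1))
  expect_identical(hdr, c("Specimen", "Taxon", "Radius", "GrooveToCylinder",
                          "AxisToGroove", "PTSIndex", "LnPTSIndex"))
  back <- read_measurements(tmp)
  expect_equal(back$pts_index, rows$pts_index)
  sm <- species_means(dplyr::bind_rows(back, back))
  expect_equal(sm$n, 2L)
  expect_equal(sm$value, rows$pts_index)
})
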