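#' Validate a pipeline configuration
#'
#' Checks a run configuration without executing anything: referenced
#' paths must exist, every clade/group taxon must be known, and stage
#' settings must be usable. Problems are returned as a report rather than
#' thrown, with `error` entries blocking [run_pipeline()] and `warning`
#' entries not.
#'
#' @param config a named list; see [run_pipeline()] for the keys.
#' @return A tibble report with columns `level` (`"error"`, `"warning"`,
#'   `"note"`), `key`, `message`.
#' @export
validate_config <- function(config) {
  rep <- list()
  add <- function(level, key, message) {
    rep[[length(rep) + 1L]] <<- tibble::tibble(level = level, key = key,
                                               message = message)
  }
  if (is.null(config$stages)) {
    add("note", "stages", "no stages requested; defaults apply at run time")
  }
  known <- c("measure", "stats", "asr", "surface")
  bad <- setdiff(config$stages %||% character(), known)
  if (length(bad)) add("error", "stages",
                       paste("unknown stage(s):", paste(bad, collapse = ", ")))

  for (key in c("tree", "traits_csv")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      add("error", key, paste("path does not exist:", config[[key]]))
    }
  }
  if (!is.null(config$meshes)) {
    missing <- config$meshes[!file.exists(unlist(config$meshes))]
    if (length(missing)) add("error", "meshes",
                             paste("missing mesh file(s):",
                                   paste(missing, collapse = ", ")))
    if (is.null(config$regions)) {
      add("error", "regions", "meshes given without region sidecars")
    } else if (length(config$regions) != length(config$meshes)) {
      add("error", "regions", "meshes and regions differ in length")
    } else {
      missing <- config$regions[!file.exists(unlist(config$regions))]
      if (length(missing)) add("error", "regions",
                               paste("missing sidecar file(s):",
                                     paste(missing, collapse = ", ")))
    }
  }

  taxa <- NULL
  if (!is.null(config$traits_csv) && file.exists(config$traits_csv)) {
    taxa <- tryCatch(read_traits(config$traits_csv)$taxon,
                     error = function(e) NULL)
    if (is.null(taxa)) add("error", "traits_csv", "unparseable trait CSV")
  }
  tree <- NULL
  if (!is.null(config$tree) && file.exists(config$tree)) {
    tree <- tryCatch(read_tree(config$tree), error = function(e) NULL)
    if (is.null(tree)) add("error", "tree", "unparseable tree file")
  }
  if (!is.null(tree) && !is.null(taxa)) {
    extra <- setdiff(taxa, tree$tip.label)
    if (length(extra)) add("warning", "traits_csv",
                           paste("trait taxa not in tree (unused):",
                                 paste(extra, collapse = ", ")))
  }
  if (!is.null(config$clades) && !is.null(tree)) {
    for (cl in names(config$clades)) {
      unknown <- setdiff(config$clades[[cl]], tree$tip.label)
      if (length(unknown)) add("error", paste0("clades.", cl),
                               paste("tip(s) not in tree:",
                                     paste(unknown, collapse = ", ")))
    }
  }
  if (!length(rep)) add("note", "config", "configuration valid")
  dplyr::bind_rows(rep)
}

#' Run the measurement-to-inference pipeline
#'
#' Executes the requested stages in order with seeded reproducibility and
#' writes versioned outputs plus a JSON manifest (effective config, input
#' hashes, seeds, package version, per-stage wall time). Stage failures
#' halt the run with a stage-tagged error.
#'
#' Recognised config keys: `meshes` and `regions` (parallel file lists)
#' with optional `taxa` and `landmark_mode` for the `measure` stage;
#' `traits_csv` (species means, used when `measure` is not run); `tree`;
#' `stages` (subset of `measure`, `stats`, `asr`, `surface`); `mu`
#' (t-test null, default 1); `groups` (named taxon lists for the ANOVA);
#' `clades` (named tip lists naming ASR nodes); `asr` (list: `model`,
#' `scaling`, `generations`, `burn_in`, `thin`); `surface` (list:
#' `consolidate`, `except`, `weight_by`); `seed`; `out_dir`.
#'
#' @param config named list (see above).
#' @return The manifest, invisibly; outputs are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  report <- validate_config(config)
  if (any(report$level == "error")) {
    stop("invalid configuration:\n",
         paste0("  [", report$key[report$level == "error"], "] ",
                report$message[report$level == "error"], collapse = "\n"),
         call. = FALSE)
  }
  out_dir <- config$out_dir %||% "ptscam_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("stats")
  manifest <- list(
    package_version = as.character(utils::packageVersion("ptscam")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    inputs = input_hashes(config),
    stages = list()
  )

  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = res
    )
  }

  traits <- NULL

  if ("measure" %in% stages) {
    run_stage("measure", function() {
      rows <- purrr::map_dfr(seq_along(config$meshes), function(i) {
        m <- read_mesh(config$meshes[[i]])
        regions <- read_regions(config$regions[[i]])
        measure_specimen(
          m,
          select_region(m, regions = regions, label = "LTF"),
          select_region(m, regions = regions, label = "FFG"),
          specimen_id = basename(config$meshes[[i]]),
          taxon = (config$taxa %||% basename(unlist(config$meshes)))[[i]],
          mode = config$landmark_mode %||% "saddle"
        )
      })
      mpath <- file.path(out_dir, "measurements.csv")
      write_measurements(rows, mpath)
      traits <<- species_means(rows)
      tpath <- file.path(out_dir, "species_means.csv")
      write_traits(traits, tpath)
      c(mpath, tpath)
    })
  }
  if (is.null(traits) && !is.null(config$traits_csv)) {
    traits <- read_traits(config$traits_csv)
  }
  tree <- if (!is.null(config$tree)) read_tree(config$tree) else NULL

  if ("stats" %in% stages) {
    run_stage("stats", function() {
      if (is.null(traits)) stop("no trait table available")
      outs <- character()
      tpath <- file.path(out_dir, "t_test.csv")
      utils::write.csv(one_sample_t(traits$value, mu = config$mu %||% 1),
                       tpath, row.names = FALSE)
      outs <- c(outs, tpath)
      if (!is.null(config$groups)) {
        gdf <- purrr::map_dfr(names(config$groups), function(g) {
          tibble::tibble(group = g,
                         taxon = config$groups[[g]])
        }) |>
          dplyr::inner_join(traits, by = "taxon")
        an <- anova_pairwise(gdf, value = "value", group = "group")
        apath <- file.path(out_dir, "anova.csv")
        utils::write.csv(cbind(glance(an), adjust = an$adjust), apath,
                         row.names = FALSE)
        ppath <- file.path(out_dir, "anova_pairwise.csv")
        utils::write.csv(an$pairwise, ppath, row.names = FALSE)
        outs <- c(outs, apath, ppath)
      }
      outs
    })
  }

  if ("asr" %in% stages) {
    run_stage("asr", function() {
      if (is.null(tree) || is.null(traits)) stop("asr needs tree and traits")
      a <- config$asr %||% list()
      chain <- mcmc_sample(tree, traits,
                           model = a$model %||% "random_walk",
                           scaling = a$scaling %||% "delta",
                           generations = a$generations %||% 20000L,
                           burn_in = a$burn_in %||% 0.25,
                           thin = a$thin %||% 10L, seed = seed)
      cpath <- file.path(out_dir, "mcmc_chain.csv")
      utils::write.csv(chain$draws, cpath, row.names = FALSE)
      asr <- reconstruct_ancestors(tree, traits, chain,
                                   nodes = config$clades, seed = seed)
      apath <- file.path(out_dir, "asr.csv")
      utils::write.csv(asr, apath, row.names = FALSE)
      c(cpath, apath)
    })
  }

  if ("surface" %in% stages) {
    run_stage("surface", function() {
      if (is.null(tree) || is.null(traits)) stop("surface needs tree and traits")
      s <- config$surface %||% list()
      tr <- traits; ph <- tree
      if (isTRUE(s$consolidate)) {
        gc <- genus_consolidate(traits, tree, except = s$except %||% character(),
                                weight_by = s$weight_by %||% "individuals")
        tr <- gc$traits; ph <- gc$tree
      }
      fwd <- surface_forward(ph, tr)
      bwd <- surface_backward(ph, tr, fwd)
      spath <- file.path(out_dir, "surface.json")
      jsonlite::write_json(list(
        aicc_forward = fwd$aicc_trace,
        aicc_backward = bwd$aicc_trace,
        shift_edges = fwd$shift_edges,
        optima = as.list(bwd$final$theta),
        alpha = bwd$final$alpha, sigma2 = bwd$final$sigma2,
        convergent_classes = bwd$convergent_classes
      ), spath, auto_unbox = TRUE, digits = NA)
      spath
    })
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}

input_hashes <- function(config) {
  paths <- c(unlist(config$meshes), unlist(config$regions),
             config$tree, config$traits_csv)
  paths <- paths[!is.null(paths) & file.exists(paths %||% character())]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}
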