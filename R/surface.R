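#' Forward phase of the stepwise OU regime search
#'
#' Starting from a single adaptive optimum, greedily adds the one regime
#' shift (placed at the origin of any branch, applying to the branch and
#' its descendants until overridden) that most improves AICc, stopping
#' when no addition improves it. Deterministic given the data: there is
#' no randomness in the search.
#'
#' @param tree an [ape::phylo].
#' @param traits tibble (`taxon`, `value`).
#' @param max_steps safety cap on the number of added shifts.
#' @return An object of class `surface_forward`: list with `fits` (the
#'   model sequence, one [fit_hansen()] per accepted step), `aicc_trace`,
#'   `shift_edges` (edge indices, in acceptance order) and `final`.
#' @export
surface_forward <- function(tree, traits, max_steps = 20L) {
  xt <- match_traits(tree, traits)
  if (stats::var(xt$value) == 0) stop("traits have zero variance", call. = FALSE)
  cache <- ou_cache(tree, xt$taxon)
  x <- xt$value
  painting <- paint_regimes(tree)
  current <- fit_hansen_cached(cache, x, painting, tree)
  fits <- list(current)
  shift_edges <- integer(0)
  ne <- nrow(tree$edge)

  for (step in seq_len(max_steps)) {
    best_fit <- NULL
    best_edge <- NA_integer_
    for (e in setdiff(seq_len(ne), shift_edges)) {
      cand_painting <- add_shift(tree, painting, e,
                                 paste0("R", length(fits) + 1L))
      cand <- fit_hansen_cached(cache, x, cand_painting, tree)
      if (is.null(best_fit) || cand$aicc < best_fit$aicc) {
        best_fit <- cand
        best_edge <- e
      }
    }
    if (is.null(best_fit) || best_fit$aicc >= current$aicc) break
    current <- best_fit
    painting <- best_fit$painting
    shift_edges <- c(shift_edges, best_edge)
    fits <- c(fits, list(best_fit))
  }
  structure(list(
    fits = fits,
    aicc_trace = vapply(fits, `[[`, numeric(1), "aicc"),
    shift_edges = shift_edges,
    final = current,
    tree = tree, traits = xt
  ), class = "surface_forward")
}

# paint a new regime on edge e and its descendants, honouring existing
# tipward shifts (their subtrees keep their own regimes). Regime ids are
# never reused after being overridden, so within the subtree of e the
# edges still carrying e's regime form exactly the contiguous block the
# new shift should repaint.
add_shift <- function(tree, painting, e, new_id) {
  er <- as.character(painting)
  child <- tree$edge[e, 2]
  sub_edges <- which(tree$edge[, 2] %in% c(child, descendants_of(tree, child)))
  er[sub_edges[er[sub_edges] == er[e]]] <- new_id
  structure(er, class = "regime_painting",
            base_regime = attr(painting, "base_regime") %||% er[1])
}

#' @export
print.surface_forward <- function(x, ...) {
  cat("<surface_forward> ", length(x$fits) - 1L, " shift(s) added; AICc ",
      paste(format(x$aicc_trace, digits = 6), collapse = " -> "), "\n",
      sep = "")
  invisible(x)
}

#' @export
autoplot.surface_forward <- function(object, ...) {
  df <- tibble::tibble(step = seq_along(object$aicc_trace) - 1L,
                       aicc = object$aicc_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$aicc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "forward step (shifts added)", y = "AICc") +
    ggplot2::theme_minimal()
}

#' Backward (convergence-collapse) phase of the stepwise OU search
#'
#' Greedily merges pairs of regimes into shared adaptive optima while the
#' merge improves AICc. Regimes that end up sharing an optimum despite
#' arising from independent shifts are reported as convergent classes.
#'
#' @param tree an [ape::phylo].
#' @param traits tibble (`taxon`, `value`).
#' @param forward a [surface_forward()] result.
#' @return An object of class `surface_backward`: `final` ([fit_hansen()]
#'   fit under the collapsed painting), `aicc_trace`,
#'   `convergent_classes` (list mapping collapsed regime id to the forward
#'   regimes it absorbs).
#' @export
surface_backward <- function(tree, traits, forward) {
  stopifnot(inherits(forward, "surface_forward"))
  xt <- match_traits(tree, traits)
  cache <- ou_cache(tree, xt$taxon)
  x <- xt$value
  current <- forward$final
  painting <- current$painting
  trace <- current$aicc
  merges <- stats::setNames(as.list(unique(as.character(painting))),
                            unique(as.character(painting)))

  repeat {
    ids <- unique(as.character(painting))
    if (length(ids) < 2L) break
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    best <- NULL
    best_pair <- NULL
    for (pr in pairs) {
      er <- as.character(painting)
      er[er == pr[2]] <- pr[1]
      cand_painting <- structure(er, class = "regime_painting",
                                 base_regime = sub_base(painting, pr))
      cand <- fit_hansen_cached(cache, x, cand_painting, tree)
      if (is.null(best) || cand$aicc < best$aicc) {
        best <- cand
        best_pair <- pr
      }
    }
    if (is.null(best) || best$aicc >= current$aicc) break
    current <- best
    painting <- best$painting
    trace <- c(trace, best$aicc)
    merges[[best_pair[1]]] <- c(merges[[best_pair[1]]],
                                merges[[best_pair[2]]])
    merges[[best_pair[2]]] <- NULL
  }
  structure(list(
    final = current,
    aicc_trace = trace,
    convergent_classes = merges,
    forward = forward
  ), class = "surface_backward")
}

sub_base <- function(painting, pr) {
  base <- attr(painting, "base_regime") %||% as.character(painting[1])
  if (identical(base, pr[2])) pr[1] else base
}

#' @export
print.surface_backward <- function(x, ...) {
  conv <- Filter(function(v) length(v) > 1L, x$convergent_classes)
  cat("<surface_backward> ", x$final$k_regimes, " regime(s) after collapse; ",
      length(conv), " convergent class(es)\n", sep = "")
  invisible(x)
}

#' Consolidate species to the genus level
#'
#' Collapses a species-level tree and trait table to one tip per genus
#' (removing short terminal branches before regime fitting), with a
#' configurable exception list of genera that keep their species tips.
#' Genus mean trait values are weighted by species representation:
#' by default each species mean is weighted by its number of measured
#' individuals (`weight_by = "individuals"`, requires an `n` column);
#' `weight_by = "species"` weights species equally instead.
#'
#' @param traits tibble (`taxon`, `value`, optionally `n`).
#' @param tree an [ape::phylo] whose tips match `traits$taxon`.
#' @param genus_map optional tibble (`taxon`, `genus`); by default the
#'   genus is the part of the taxon label before the first underscore.
#' @param except genera to leave at the species level.
#' @param weight_by `"individuals"` or `"species"`.
#' @return List with `tree` and `traits` at the genus level.
#' @export
genus_consolidate <- function(traits, tree, genus_map = NULL,
                              except = character(),
                              weight_by = c("individuals", "species")) {
  weight_by <- match.arg(weight_by)
  traits <- tibble::as_tibble(traits)
  if (is.null(genus_map)) {
    genus_map <- tibble::tibble(taxon = traits$taxon,
                                genus = sub("_.*$", "", traits$taxon))
  }
  miss <- setdiff(traits$taxon, genus_map$taxon)
  if (length(miss)) stop("genus map missing taxa: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d <- dplyr::left_join(traits, genus_map, by = "taxon")
  if (weight_by == "individuals") {
    if (!"n" %in% names(d)) {
      stop("weight_by = 'individuals' needs an `n` column in traits",
           call. = FALSE)
    }
    d$w <- d$n
  } else {
    d$w <- 1
  }
  if (any(tapply(d$w, d$genus, sum) <= 0)) {
    stop("genus with zero total weight", call. = FALSE)
  }
  keep_species <- d$genus %in% except
  collapsed <- d[!keep_species, , drop = FALSE] |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(value = sum(.data$value * .data$w) / sum(.data$w),
                     n = sum(.data$w),
                     keep_tip = .data$taxon[which.max(.data$w)],
                     .groups = "drop")
  out_traits <- dplyr::bind_rows(
    tibble::tibble(taxon = collapsed$genus, value = collapsed$value,
                   n = collapsed$n),
    tibble::tibble(taxon = d$taxon[keep_species],
                   value = d$value[keep_species],
                   n = if ("n" %in% names(d)) d$n[keep_species] else
                     rep(1, sum(keep_species)))
  )
  drop <- setdiff(tree$tip.label, c(collapsed$keep_tip,
                                    d$taxon[keep_species]))
  out_tree <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  ren <- match(out_tree$tip.label, collapsed$keep_tip)
  out_tree$tip.label[!is.na(ren)] <- collapsed$genus[ren[!is.na(ren)]]
  list(tree = out_tree, traits = out_traits)
}
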