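#' Simulate a rooted birth tree, optionally with fossil tips
#'
#' Pure-birth trees give ultrametric topologies; fossil tips are produced
#' by truncating randomly chosen pendant branches by a uniform random
#' fraction, yielding a non-ultrametric tree (tips that "end early", as
#' extinct taxa do). Deterministic given the seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per unit time (> 0).
#' @param n_fossil_tips number of tips to truncate (< `n_tips`).
#' @param seed integer RNG seed.
#' @return An [ape::phylo] tree with tip labels `t1 ... tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, n_fossil_tips = 0L,
                          seed = 1L) {
  if (n_tips < 2L) stop("n_tips must be >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  if (n_fossil_tips >= n_tips) stop("n_fossil_tips must be < n_tips", call. = FALSE)
  set.seed(as.integer(seed))
  tree <- if (n_tips == 2L) {
    t2 <- ape::rcoal(2)  # cherry; rescale to birth-rate timescale
    t2$edge.length <- stats::rexp(2, birth_rate) + 1e-3
    t2$edge.length <- rep(max(t2$edge.length), 2)  # keep ultrametric
    t2
  } else {
    ape::rphylo(n_tips, birth = birth_rate, death = 0)
  }
  tree$tip.label <- paste0("t", seq_len(n_tips))
  if (n_fossil_tips > 0L) {
    fossils <- sample(n_tips, n_fossil_tips)
    pend <- match(fossils, tree$edge[, 2])
    frac <- stats::runif(n_fossil_tips, 0.2, 0.8)
    tree$edge.length[pend] <- tree$edge.length[pend] * (1 - frac)
  }
  attr(tree, "seed") <- as.integer(seed)
  tree
}

#' Paint adaptive regimes onto a tree
#'
#' A regime painting assigns one regime id to every branch. A shift placed
#' on a branch applies to that branch and all its descendants until
#' overridden by a more tipward shift, so regimes are contiguous from the
#' branch where they originate.
#'
#' @param tree an [ape::phylo].
#' @param shifts named character vector: names are the tipward node of the
#'   branch carrying the shift (node number, or a tip label), values are
#'   regime ids.
#' @param base_regime regime id of the root (basal) regime.
#' @return Character vector of regime ids, one per row of `tree$edge`,
#'   of class `regime_painting`; attribute `base_regime`.
#' @export
paint_regimes <- function(tree, shifts = NULL, base_regime = "R1") {
  ne <- nrow(tree$edge)
  painting <- rep(base_regime, ne)
  if (length(shifts)) {
    nodes <- names(shifts)
    node_ids <- suppressWarnings(as.integer(nodes))
    lab <- match(nodes, tree$tip.label)
    node_ids[!is.na(lab)] <- lab[!is.na(lab)]
    if (anyNA(node_ids)) stop("unknown shift node(s): ",
                              paste(nodes[is.na(node_ids)], collapse = ", "),
                              call. = FALSE)
    # preorder so tipward shifts override rootward ones
    ord <- order(node_depths_internal(tree)[node_ids])
    for (i in ord) {
      desc_edges <- which(tree$edge[, 2] %in%
                            c(node_ids[i], descendants_of(tree, node_ids[i])))
      painting[desc_edges] <- shifts[[i]]
    }
  }
  structure(painting, class = "regime_painting", base_regime = base_regime)
}

# all descendant nodes (internal and tips) of `node`
descendants_of <- function(tree, node) {
  out <- integer(0)
  frontier <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

node_depths_internal <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Simulate Brownian-motion trait evolution
#'
#' Simulates a continuous trait branchwise along the (optionally
#' Pagel-transformed) tree: each branch contributes a Gaussian increment
#' with variance `sigma2` times the transformed branch length, plus
#' `trend` times branch length under the directional model.
#'
#' @param tree an [ape::phylo].
#' @param sigma2 Brownian rate (>= 0).
#' @param root_state trait value at the root.
#' @param transform `NULL`, or `list(kind =, value =)` with kind one of
#'   `"delta"`, `"kappa"`, `"lambda"` (see [transform_tree()]).
#' @param trend directional trend per unit branch length, or `NULL`.
#' @param seed integer RNG seed.
#' @return A tibble (`taxon`, `value`) with the seed as attribute.
#' @export
simulate_bm <- function(tree, sigma2, root_state = 0, transform = NULL,
                        trend = NULL, seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  wtree <- if (is.null(transform)) tree else
    transform_tree(tree, transform$kind, transform$value)
  set.seed(as.integer(seed))
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  x <- rep(NA_real_, nnode)
  root <- n + 1L
  x[root] <- root_state
  mu <- if (is.null(trend)) 0 else trend
  ord <- reorder_edges_preorder(wtree)
  for (e in ord) {
    par <- wtree$edge[e, 1]; child <- wtree$edge[e, 2]
    len <- wtree$edge.length[e]
    x[child] <- x[par] + mu * len + stats::rnorm(1, sd = sqrt(sigma2 * len))
  }
  out <- tibble::tibble(taxon = tree$tip.label, value = x[seq_len(n)])
  attr(out, "seed") <- as.integer(seed)
  out
}

reorder_edges_preorder <- function(tree) {
  cl <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  cl
}

#' Simulate multi-regime Ornstein-Uhlenbeck trait evolution
#'
#' Exact transition sampling branch by branch: for a branch of length `t`
#' in regime with optimum `theta`, the child state is
#' `Normal(theta + (parent - theta) exp(-alpha t),
#' sigma2 (1 - exp(-2 alpha t)) / (2 alpha))`.
#'
#' @param tree an [ape::phylo].
#' @param painting a [paint_regimes()] painting (one regime per branch).
#' @param alpha attraction rate (> 0).
#' @param sigma2 diffusion rate (> 0).
#' @param optima named numeric vector of optima, one per regime id.
#' @param root_state trait value at the root.
#' @param seed integer RNG seed.
#' @return A tibble (`taxon`, `value`) with the seed as attribute.
#' @export
simulate_ou <- function(tree, painting, alpha, sigma2, optima,
                        root_state = NULL, seed = 1L) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (length(painting) != nrow(tree$edge)) {
    stop("painting must assign a regime to every branch", call. = FALSE)
  }
  if (anyNA(painting)) stop("unpainted branch in painting", call. = FALSE)
  miss <- setdiff(unique(as.character(painting)), names(optima))
  if (length(miss)) stop("no optimum for regime(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  base <- attr(painting, "base_regime") %||% as.character(painting[1])
  if (is.null(root_state)) root_state <- optima[[base]]
  set.seed(as.integer(seed))
  n <- length(tree$tip.label)
  x <- rep(NA_real_, n + tree$Nnode)
  x[n + 1L] <- root_state
  for (e in reorder_edges_preorder(tree)) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    th <- optima[[as.character(painting[e])]]
    m <- th + (x[par] - th) * exp(-alpha * t)
    v <- sigma2 * (-expm1(-2 * alpha * t)) / (2 * alpha)
    x[child] <- stats::rnorm(1, mean = m, sd = sqrt(v))
  }
  out <- tibble::tibble(taxon = tree$tip.label, value = x[seq_len(n)])
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Write or read a trait table
#'
#' @param traits tibble with `taxon`, `value` and optionally `n`.
#' @param path CSV path.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "value") %in% names(x))) {
    stop("trait CSV must have columns taxon, value", call. = FALSE)
  }
  tibble::as_tibble(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
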