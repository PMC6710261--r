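#' Read a rooted phylogeny
#'
#' Thin wrapper over the ape parsers with the validation the comparative
#' machinery needs: exactly one root, unique tip labels, non-negative
#' branch lengths. Polytomies are permitted; zero-length branches are
#' permitted with a warning (they get a small floor inside covariance
#' matrices only).
#'
#' @param path newick or nexus file.
#' @param format `"newick"` or `"nexus"`; guessed from the extension when
#'   missing.
#' @return An [ape::phylo].
#' @export
read_tree <- function(path, format = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus", "trees")) "nexus" else "newick"
  }
  format <- match.arg(format, c("newick", "nexus"))
  tree <- switch(format,
    newick = ape::read.tree(path),
    nexus = ape::read.nexus(path)
  )
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree)) stop("could not parse tree: ", path, call. = FALSE)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (any(tree$edge.length == 0)) {
    warning("tree contains zero-length branches; a 1e-8 floor is applied ",
            "inside covariance matrices", call. = FALSE)
  }
  invisible(tree)
}

#' Pagel tree transforms
#'
#' Rescales branch lengths under the three standard transforms:
#' * `delta` — node heights `h` (root at 0), after normalising total tree
#'   depth to 1, are raised to the power `delta` and rescaled back, so
#'   `delta` is scale-free; `delta < 1` concentrates change early in the
#'   tree (rapid early evolution), `delta > 1` late.
#' * `kappa` — each branch length is raised to the power `kappa`;
#'   `kappa = 0` makes all branches equal (speciational change).
#' * `lambda` — internal branch lengths are scaled by `lambda` with
#'   root-to-tip heights preserved; `lambda = 0` is a star tree
#'   (no phylogenetic signal).
#'
#' `value = 1` is the identity for all three.
#'
#' @param tree an [ape::phylo].
#' @param kind `"delta"`, `"kappa"` or `"lambda"`.
#' @param value transform parameter (>= 0; `lambda` additionally must not
#'   exceed 1 for a valid covariance on non-star trees).
#' @return A transformed [ape::phylo].
#' @export
transform_tree <- function(tree, kind = c("delta", "kappa", "lambda"), value) {
  kind <- match.arg(kind)
  if (value < 0) stop("transform value must be >= 0", call. = FALSE)
  out <- tree
  if (kind == "kappa") {
    out$edge.length <- tree$edge.length^value
    return(out)
  }
  depths <- ape::node.depth.edgelength(tree)
  if (kind == "delta") {
    T <- max(depths)
    nd <- T * (depths / T)^value
    out$edge.length <- nd[tree$edge[, 2]] - nd[tree$edge[, 1]]
    return(out)
  }
  # lambda: scale internal branches, preserve tip heights
  n <- length(tree$tip.label)
  is_tip_edge <- tree$edge[, 2] <= n
  el <- tree$edge.length * value
  el[is_tip_edge] <- depths[tree$edge[is_tip_edge, 2]] -
    value * depths[tree$edge[is_tip_edge, 1]]
  if (any(el < -1e-12)) {
    stop("lambda transform produced negative branch lengths (value > 1?)",
         call. = FALSE)
  }
  out$edge.length <- pmax(el, 0)
  out
}

# ---- covariance machinery ------------------------------------------------
# A builder precomputes topology-dependent structures once so that
# per-draw covariance matrices under any transform value cost O(n^2).

make_cov_builder <- function(tree, taxa = tree$tip.label) {
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) stop("taxa missing from tree: ",
                       paste(taxa[is.na(idx)], collapse = ", "), call. = FALSE)
  if (any(tree$edge.length == 0)) {
    # documented floor for zero-length branches, inside covariances only
    tree$edge.length <- pmax(tree$edge.length, 1e-8)
  }
  H <- ape::vcv(tree)[idx, idx, drop = FALSE]  # shared path lengths
  Tdepth <- max(ape::node.depth.edgelength(tree))
  # branch incidence for kappa: tips x edges indicator
  n <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  A <- matrix(0, length(idx), ne)
  anc <- edge_ancestry(tree)
  for (i in seq_along(idx)) A[i, anc[[idx[i]]]] <- 1
  el <- tree$edge.length
  tipd <- diag(H)
  function(kind = "none", value = 1) {
    C <- switch(kind,
      none = H,
      delta = {
        Z <- Tdepth * (pmax(H, 0) / Tdepth)^value
        Z
      },
      kappa = A %*% (el^value * t(A)),
      lambda = {
        Z <- value * H
        diag(Z) <- tipd
        Z
      },
      stop("unknown transform kind: ", kind, call. = FALSE)
    )
    unname(C)
  }
}

# list: for each tip, the edge indices on its root-to-tip path
edge_ancestry <- function(tree) {
  n <- length(tree$tip.label)
  parent_edge <- match(seq_len(n + tree$Nnode), tree$edge[, 2])
  lapply(seq_len(n), function(tip) {
    path <- integer(0)
    node <- tip
    repeat {
      e <- parent_edge[node]
      if (is.na(e)) break
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
}

# log-density of x ~ N(mu, sigma2 * C) via Cholesky, with a documented
# 1e-10 ridge retry when C is numerically singular
mvn_loglik <- function(x, mu, C, sigma2) {
  n <- length(x)
  S <- sigma2 * C
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular covariance; applying 1e-10 ridge", call. = FALSE)
    ch <- chol(S + diag(1e-10, n))
  }
  r <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(r^2)
}

is_ultrametric_tree <- function(tree, tol = 1e-8) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(d)) < tol * max(d)
}
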