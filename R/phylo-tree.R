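## Trees, phylogenetic covariance, and branch-length transforms ---------------
##
## Trees are ape "phylo" objects with branch lengths in absolute time
## (millions of years).  The Brownian-motion covariance between two
## species is the depth of their most recent common ancestor, so the VCV
## matrix and its lambda/delta transforms carry all model structure.

#' Read a rooted tree from Newick text or file
#'
#' @param source Newick string (recognized by a `(` ... `;`) or a path to
#'   a file containing a single Newick tree.
#' @return An `ape::phylo` tree with branch lengths.
#' @export
read_newick <- function(source) {
  tr <- if (grepl("(", source[1], fixed = TRUE))
    tryCatch(suppressWarnings(ape::read.tree(text = source)),
             error = function(e) NULL)
  else
    tryCatch(suppressWarnings(ape::read.tree(source)),
             error = function(e) NULL)
  if (is.null(tr))
    stop("failed to parse Newick input", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("expected a single Newick tree, found ", length(tr), call. = FALSE)
    tr <- tr[[1]]
  }
  if (is.null(tr$edge.length))
    stop("Newick tree has no branch lengths; absolute-time lengths are required",
         call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in tree", call. = FALSE)
  if (any(tr$edge.length < 0))
    stop("negative branch lengths in tree", call. = FALSE)
  tr
}

#' Prune a tree to a set of species
#'
#' Drops all other tips and collapses the resulting degree-2 nodes,
#' summing branch lengths, so root-to-tip depths of retained species are
#' preserved.
#'
#' @param tree An `ape::phylo`.
#' @param species Character vector of tip labels to keep.
#' @return The pruned `phylo`.
#' @export
prune_to <- function(tree, species) {
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(species) < 2L)
    stop("cannot prune a tree to fewer than 2 tips", call. = FALSE)
  ape::keep.tip(tree, species)
}

#' Is a tree ultrametric (equal root-to-tip depths)?
#'
#' @param tree An `ape::phylo`.
#' @param tol Relative tolerance on depth spread.
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(depths)) <= tol * max(depths)
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' Entry (i, j) is the shared path length from the root to the most
#' recent common ancestor of species i and j; diagonal entries are
#' root-to-tip depths.  Under constant-rate Brownian motion the tip
#' values are jointly normal with covariance `sigma2 * C`.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return Symmetric species-labelled matrix.
#' @export
vcv_matrix <- function(tree) {
  ape::vcv(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies all off-diagonal (shared-history) covariances by `lambda`,
#' leaving tip variances unchanged.  `lambda = 1` is Brownian motion on
#' the original tree; `lambda = 0` is a star phylogeny (no phylogenetic
#' signal, independent tips).
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Value in \[0, 1\].
#' @return Transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  Ct <- C * lambda
  diag(Ct) <- diag(C)
  Ct
}

#' Pagel's delta transform of a phylogenetic covariance matrix
#'
#' Raises every entry (node depths, i.e. both shared and tip path
#' lengths) elementwise to the power `delta`.  `delta = 1` leaves the
#' tree unchanged (Brownian motion); `delta > 1` concentrates trait
#' change toward the tips (late evolution); `delta < 1` toward the root
#' (early evolution).  No total-depth rescaling is applied: rescaling
#' only shifts the estimated rate, not the likelihood ordering of
#' transform parameters.  Requires an ultrametric tree, so `C` must have
#' (near-)equal diagonal entries.
#'
#' @param C Phylogenetic covariance matrix from an ultrametric tree.
#' @param delta Value in (0, 3\].
#' @param tol Relative tolerance for the ultrametricity check.
#' @return Transformed matrix.
#' @export
delta_transform <- function(C, delta, tol = 1e-6) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 3)
    stop("delta must be a single value in (0, 3]", call. = FALSE)
  d <- diag(C)
  if (diff(range(d)) > tol * max(d))
    stop("delta transform requires an ultrametric tree (equal tip depths)",
         call. = FALSE)
  C^delta
}
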