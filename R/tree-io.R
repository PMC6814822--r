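#' Read a rooted, branch-length-bearing phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()] / [ape::read.nexus()].
#' Every downstream computation in this package needs a rooted tree with
#' non-negative branch lengths in time units (Myr for a chronogram), so the
#' reader refuses trees that lack them instead of propagating `NA` edges.
#'
#' @param text Newick/NEXUS string, or `NULL` if `file` is given.
#' @param file path to a tree file, or `NULL` if `text` is given.
#' @param format `"newick"` or `"nexus"`.
#' @return an [ape::phylo] object (rooted, with `edge.length`).
#' @export
read_tree <- function(text = NULL, file = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tr <- tryCatch(
    withCallingHandlers({
      if (format == "newick") {
        if (is.null(text)) ape::read.tree(file = file) else ape::read.tree(text = text)
      } else {
        if (is.null(file)) {
          tf <- tempfile(fileext = ".nex")
          on.exit(unlink(tf), add = TRUE)
          writeLines(text, tf)
          file <- tf
        }
        ape::read.nexus(file = file)
      }
    }, warning = function(w) stop(conditionMessage(w), call. = FALSE)),
    error = function(e) {
      src <- if (is.null(file)) substr(text, 1, 60) else file
      stop(sprintf("failed to parse %s tree from '%s': %s", format, src,
                   conditionMessage(e)), call. = FALSE)
    })
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("input contains ", length(tr), " trees; expected exactly one")
    tr <- tr[[1L]]
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("failed to parse a tree from the input")
  validate_tree(tr)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks: class `phylo`, rooted, unique non-empty tip labels, branch
#' lengths present, finite and non-negative.
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly unchanged, or an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  # a star tree (basal polytomy) is a legitimate rooted tree here, so
  # check root uniqueness directly instead of ape::is.rooted()
  roots <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(roots) != 1L) stop("tree must be rooted (found ",
                                length(roots), " root nodes)")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; time-calibrated branch lengths are required")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree has missing or non-finite branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  lab <- tree$tip.label
  if (any(!nzchar(lab))) stop("tree has empty tip labels")
  if (anyDuplicated(lab)) {
    dup <- unique(lab[duplicated(lab)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  tree
}

#' Phylogenetic (Brownian) variance-covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j (Myr);
#' the diagonal holds root-to-tip depths. This is the covariance structure
#' of a unit-rate Brownian motion run along the tree.
#'
#' @param tree an [ape::phylo] object.
#' @return an n x n symmetric positive semi-definite matrix with tip labels
#'   as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lam`, leaving the diagonal
#' untouched. `lam = 1` returns `C`; `lam = 0` is the star-tree covariance.
#'
#' @param C covariance matrix from [phylo_vcv()].
#' @param lam scalar in `[0, 1]` (values above 1 only with
#'   `allow_above_one = TRUE`).
#' @param allow_above_one permit `lam > 1` (off by default; such values can
#'   break positive-definiteness).
#' @return the transformed matrix.
#' @export
lambda_transform <- function(C, lam, allow_above_one = FALSE) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam))
    stop("`lam` must be a single number")
  ub <- if (allow_above_one) Inf else 1
  if (lam < 0 || lam > ub)
    stop("`lam` must lie in [0, ", ub, "]")
  Cl <- C * lam
  diag(Cl) <- diag(C)
  Cl
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on `names`, with degree-2 internal nodes
#' suppressed and their branch lengths summed, so pairwise patristic
#' distances among the kept tips are preserved. Taxa named but absent from
#' the tree are reported.
#'
#' @param tree an [ape::phylo] object.
#' @param names character vector of tip labels to keep.
#' @return the pruned tree, with attribute `"dropped"` listing the tips of
#'   the original tree that were removed.
#' @export
prune_to_taxa <- function(tree, names) {
  validate_tree(tree)
  keep <- intersect(tree$tip.label, names)
  if (length(keep) == 0L)
    stop("none of the requested taxa occur in the tree")
  missing <- setdiff(names, tree$tip.label)
  if (length(missing) > 0L)
    warning("taxa not in tree (ignored): ", paste(missing, collapse = ", "))
  if (length(keep) == ape::Ntip(tree)) {
    out <- tree
  } else if (length(keep) == 1L) {
    stop("cannot prune to a single tip")
  } else {
    # keep the stem above the retained clade so root-to-tip depths are
    # preserved: graft the original depth of the kept tips' MRCA back in
    # as a root edge
    out <- ape::keep.tip(tree, keep)
    out$root.edge <- node_depths(tree)[ape::getMRCA(tree, keep)]
    out <- graft_root_edge(out)
  }
  attr(out, "dropped") <- setdiff(tree$tip.label, keep)
  out
}

# turn a $root.edge stem into an explicit edge below a new root node
graft_root_edge <- function(tr) {
  if (is.null(tr$root.edge) || length(tr$root.edge) == 0L ||
      tr$root.edge <= 0) {
    tr$root.edge <- NULL
    return(tr)
  }
  n <- ape::Ntip(tr)
  e <- tr$edge
  e[e > n] <- e[e > n] + 1L
  tr$edge <- rbind(c(n + 1L, n + 2L), e)
  tr$edge.length <- c(tr$root.edge, tr$edge.length)
  tr$Nnode <- tr$Nnode + 1L
  tr$root.edge <- NULL
  tr
}

#' Root-to-node depths
#'
#' Depth (total path length from the root, Myr) of every node, indexed in
#' ape node order (tips `1..n`, then internals).
#'
#' @param tree an [ape::phylo] object.
#' @return numeric vector of length `n + Nnode`.
#' @export
node_depths <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  depth <- numeric(n + nn)
  root <- n + 1L
  ord <- reorder_edges_preorder(tree)
  for (k in ord) {
    par <- tree$edge[k, 1L]
    ch <- tree$edge[k, 2L]
    depth[ch] <- depth[par] + tree$edge.length[k]
  }
  depth
}

#' Tree depth (max root-to-tip path length)
#' @param tree an [ape::phylo] object.
#' @return scalar depth in the tree's branch-length units.
#' @export
tree_depth <- function(tree) max(node_depths(tree)[seq_len(ape::Ntip(tree))])

#' Is a tree ultrametric (to a relative tolerance)?
#'
#' All root-to-tip depths must agree within `tol` times the tree depth
#' (default relative 1e-6, the tolerance used wherever stationary OU
#' covariance is requested).
#'
#' @param tree an [ape::phylo] object.
#' @param tol relative tolerance.
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d)
}

# edge indices in preorder (root first); works for any rooted phylo
reorder_edges_preorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  tr
}

# children edge indices per node, as a list indexed by node id
edge_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  out <- vector("list", n_nodes)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    out[[p]] <- c(out[[p]], k)
  }
  out
}

# normalize labels for tree/table matching: underscores <-> spaces, trim
normalize_label <- function(x) {
  x <- trimws(x)
  gsub("[ _]+", "_", x)
}
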