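#' Build a mapped tree from per-branch regime segments
#'
#' A mapped tree ("simmap") is a phylogeny whose every branch carries an
#' ordered piecewise-constant regime history. Segments are stored
#' rootward-to-tipward: `maps[[k]]` is a named numeric vector for edge `k`
#' whose names are regime states and whose values are segment durations
#' (Myr). This is the interchange convention of the standard
#' comparative-methods simmap dialect, and it is enforced here because the
#' convention matters for every Ornstein-Uhlenbeck weight computation.
#'
#' @param tree an [ape::phylo] object.
#' @param maps list (one element per edge, in `tree$edge` order) of named
#'   numeric vectors of segment durations; names are states.
#' @param states optional regime alphabet; defaults to the states observed.
#' @return an object of class `c("simmap", "phylo")` with elements `maps`
#'   and `mapped.edge`, compatible with the standard simmap tooling.
#' @export
make_simmap_tree <- function(tree, maps, states = NULL) {
  validate_tree(tree)
  if (length(maps) != nrow(tree$edge))
    stop("`maps` must have one element per edge")
  used <- sort(unique(unlist(lapply(maps, names))))
  st <- if (is.null(states)) used else states
  bad <- setdiff(used, st)
  if (length(bad) > 0L)
    stop("segments use states outside the regime alphabet: ",
         paste(bad, collapse = ", "))
  obj <- tree
  obj$maps <- maps
  obj$mapped.edge <- mapped_edge_matrix(tree, maps, st)
  attr(obj, "map.order") <- "right-to-left"
  class(obj) <- c("simmap", class(tree))
  validate_simmap(obj, states = st)
  obj
}

mapped_edge_matrix <- function(tree, maps, states) {
  me <- matrix(0, nrow(tree$edge), length(states),
               dimnames = list(paste(tree$edge[, 1], tree$edge[, 2], sep = ","),
                               states))
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    for (j in seq_along(m)) me[k, names(m)[j]] <- me[k, names(m)[j]] + m[j]
  }
  me
}

#' Validate a mapped tree's invariants
#'
#' Checks, per branch: segment durations sum to the branch length (relative
#' tolerance `1e-9`); every state belongs to the regime alphabet; and the
#' first segment state equals the last segment state of the parent branch
#' (history continuity). Zero-length branches must carry exactly one
#' zero-duration segment.
#'
#' @param map a `simmap` object.
#' @param states optional regime alphabet to check against.
#' @param tol relative tolerance on duration sums.
#' @return the object, invisibly, or an error.
#' @export
validate_simmap <- function(map, states = NULL, tol = 1e-9) {
  if (!inherits(map, "phylo") || is.null(map$maps))
    stop("not a mapped tree (missing `maps`)")
  nb <- nrow(map$edge)
  scale <- max(map$edge.length, 1e-12)
  alphabet <- if (is.null(states)) colnames(map$mapped.edge) else states
  # state at each node: the tipward end of its parent branch; for the
  # root, the common rootward start of its child branches
  node_state <- character(ape::Ntip(map) + map$Nnode)
  ord <- reorder_edges_preorder(map)
  for (k in ord) {
    m <- map$maps[[k]]
    if (length(m) == 0L) stop("edge ", k, " carries no segments")
    if (is.null(names(m)) || any(!nzchar(names(m))))
      stop("edge ", k, " has unnamed segments")
    bad <- setdiff(names(m), alphabet)
    if (length(bad) > 0L)
      stop("edge ", k, " uses states outside the regime alphabet: ",
           paste(bad, collapse = ", "))
    if (any(m < 0)) stop("edge ", k, " has negative segment durations")
    el <- map$edge.length[k]
    if (abs(sum(m) - el) > tol * max(scale, el))
      stop(sprintf("edge %d: segment durations sum to %.12g but branch length is %.12g",
                   k, sum(m), el))
    par <- map$edge[k, 1L]
    ch <- map$edge[k, 2L]
    if (nzchar(node_state[par]) && names(m)[1L] != node_state[par])
      stop(sprintf("edge %d: first segment state '%s' differs from the state '%s' at its parent node (history discontinuity)",
                   k, names(m)[1L], node_state[par]))
    node_state[par] <- names(m)[1L]
    node_state[ch] <- names(m)[length(m)]
  }
  invisible(map)
}

#' Read / write mapped trees in the simmap-annotated Newick dialect
#'
#' Branch annotations have the form `{state,duration:state,duration:...}`
#' ordered rootward-to-tipward. Reading validates all mapped-tree
#' invariants (duration sums, continuity, alphabet); writing then reading
#' is the identity up to `1e-9` on durations. Parsing is delegated to the
#' standard simmap tooling; validation is ours, since silently inconsistent
#' maps are the main interop hazard.
#'
#' @param text simmap-annotated Newick string (or `file`).
#' @param file optional path to read from.
#' @param states optional regime alphabet to check against.
#' @return a validated `simmap` object.
#' @export
read_simmap <- function(text = NULL, file = NULL, states = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  obj <- tryCatch({
    if (is.null(file))
      phytools::read.simmap(text = text, format = "phylip",
                            version = 1, rev.order = FALSE)
    else
      phytools::read.simmap(file = file, format = "phylip",
                            version = 1, rev.order = FALSE)
  }, error = function(e) stop("failed to parse simmap input: ",
                              conditionMessage(e), call. = FALSE))
  if (inherits(obj, "multiSimmap")) {
    if (length(obj) != 1L) stop("input contains ", length(obj),
                                " mapped trees; expected exactly one")
    obj <- obj[[1L]]
  }
  validate_tree(obj)
  validate_simmap(obj, states = states)
  obj
}

#' @rdname read_simmap
#' @param map a `simmap` object to serialize.
#' @export
write_simmap <- function(map, file = NULL) {
  validate_simmap(map)
  tf <- if (is.null(file)) tempfile(fileext = ".tre") else file
  phytools::write.simmap(map, file = tf, version = 1,
                         map.order = "left-to-right", quiet = TRUE)
  if (is.null(file)) {
    on.exit(unlink(tf), add = TRUE)
    paste(readLines(tf), collapse = "\n")
  } else invisible(file)
}

#' Tip regime states of a mapped tree
#'
#' The state of each tip is the last (tipward) segment state of its
#' pendant branch.
#'
#' @param map a `simmap` object.
#' @return named character vector (names = tip labels).
#' @export
simmap_tip_states <- function(map) {
  n <- ape::Ntip(map)
  out <- character(n)
  for (k in seq_len(nrow(map$edge))) {
    ch <- map$edge[k, 2L]
    if (ch <= n) {
      m <- map$maps[[k]]
      out[ch] <- names(m)[length(m)]
    }
  }
  names(out) <- map$tip.label
  out
}

#' Node states of a mapped tree
#'
#' State at each node of the mapped history: for a non-root node, the
#' tipward end state of its parent branch; for the root, the rootward
#' start state of its child branches.
#'
#' @param map a `simmap` object.
#' @return character vector indexed by node id (tips then internals).
#' @export
simmap_node_states <- function(map) {
  n <- ape::Ntip(map)
  out <- character(n + map$Nnode)
  root <- n + 1L
  for (k in seq_len(nrow(map$edge))) {
    m <- map$maps[[k]]
    out[map$edge[k, 2L]] <- names(m)[length(m)]
    if (map$edge[k, 1L] == root && !nzchar(out[root]))
      out[root] <- names(m)[1L]
  }
  out
}

#' Count regime transitions on a mapped tree
#'
#' Tallies state-change events per ordered state pair over all branches.
#' A state regained after an excursion counts each event separately.
#'
#' @param map a `simmap` object.
#' @param states regime alphabet (defaults to `colnames(map$mapped.edge)`).
#' @return k x k integer matrix; `[i, j]` is the number of i -> j changes.
#' @export
count_transitions <- function(map, states = NULL) {
  if (is.null(states)) states <- colnames(map$mapped.edge)
  k <- length(states)
  out <- matrix(0L, k, k, dimnames = list(states, states))
  for (m in map$maps) {
    nm <- names(m)
    if (length(nm) > 1L)
      for (j in seq_len(length(nm) - 1L))
        out[nm[j], nm[j + 1L]] <- out[nm[j], nm[j + 1L]] + 1L
  }
  out
}

# Per-tip root-to-tip regime history of a mapped ultrametric tree.
# Returns a list (one per tip, in tip order) of data frames with columns
# state, t0, t1 (absolute times from the root, t0 < t1). Used by the OU
# weight-matrix machinery.
tip_histories <- function(map) {
  n <- ape::Ntip(map)
  depth <- node_depths(map)
  kids <- edge_children(map)
  out <- vector("list", n)
  walk <- function(node, hist) {
    for (k in kids[[node]]) {
      ch <- map$edge[k, 2L]
      m <- map$maps[[k]]
      t0 <- depth[node]
      seg <- data.frame(state = names(m),
                        t0 = t0 + cumsum(c(0, unname(m)[-length(m)])),
                        t1 = t0 + cumsum(unname(m)),
                        stringsAsFactors = FALSE)
      h2 <- rbind(hist, seg)
      if (ch <= n) out[[ch]] <<- h2 else walk(ch, h2)
    }
  }
  root <- n + 1L
  walk(root, data.frame(state = character(), t0 = numeric(), t1 = numeric(),
                        stringsAsFactors = FALSE))
  names(out) <- map$tip.label
  out
}
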