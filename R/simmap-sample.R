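#' Draw stochastic character maps of a discrete regime
#'
#' Samples full character histories conditional on the tip states and the
#' (fixed, empirical-Bayes) rate matrix: node states are drawn from their
#' joint conditional distribution given the tips by pruning + preorder
#' sampling, and each branch history is then drawn conditional on its
#' endpoint states by uniformization, which bounds the work per branch and
#' keeps runtime deterministic. Sampled maps satisfy all mapped-tree
#' invariants and are reproducible given `seed`.
#'
#' @param tree an [ape::phylo] object.
#' @param model an `mk_model` (e.g. from [fit_mk()]), or a rate matrix.
#' @param tip_states named character vector of tip states.
#' @param n_maps number of maps to draw.
#' @param seed optional integer seed.
#' @param root_prior root distribution (default: the model's).
#' @return a list of `simmap` objects (class `multiSimmap`-like plain list).
#' @export
sample_simmaps <- function(tree, model, tip_states, n_maps = 1L,
                           seed = NULL, root_prior = NULL) {
  validate_tree(tree)
  if (!inherits(model, "mk_model")) {
    Q <- as.matrix(model)
    model <- mk_model(colnames(Q), Q, root_prior = root_prior)
  }
  if (is.null(root_prior)) root_prior <- model$root_prior
  Q <- model$Q
  states <- model$states
  k <- length(states)
  if (!is.null(seed)) set.seed(seed)

  pr <- mk_pruning(tree, tip_states, Q, root_prior)
  L <- pr$partial
  Pmats <- pr$Pmats
  n <- ape::Ntip(tree)
  root <- n + 1L
  ord <- reorder_edges_preorder(tree)
  parent_of_edge <- tree$edge[, 1L]
  child_of_edge <- tree$edge[, 2L]
  el <- tree$edge.length

  # uniformization setup
  omega <- max(-diag(Q))
  Rmat <- if (omega > 0) diag(k) + Q / omega else diag(k)

  root_w <- root_prior * L[root, ]
  if (sum(root_w) <= 0) stop("data have zero likelihood under the model")
  root_w <- root_w / sum(root_w)

  tipmat <- tip_state_matrix(tree, tip_states, states)

  out <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    node_state <- integer(n + tree$Nnode)
    node_state[root] <- sample.int(k, 1L, prob = root_w)
    maps <- vector("list", nrow(tree$edge))
    for (e in ord) {
      par <- parent_of_edge[e]; ch <- child_of_edge[e]
      i <- node_state[par]
      w <- Pmats[[e]][i, ] * (if (ch <= n) tipmat[ch, ] else L[ch, ])
      if (sum(w) <= 0) stop("zero-probability endpoint pair during map sampling")
      j <- sample.int(k, 1L, prob = w)
      node_state[ch] <- j
      maps[[e]] <- sample_branch_history(i, j, el[e], Q, omega, Rmat,
                                         Pmats[[e]], states)
    }
    out[[m]] <- make_simmap_tree(tree, maps, states = states)
    out[[m]]$node.states <- states[node_state]
  }
  class(out) <- c("multiSimmap", "multiPhylo", class(out))
  out
}

# Sample one branch history conditional on endpoints (i -> j over time t)
# by uniformization. Returns a named duration vector rootward -> tipward.
sample_branch_history <- function(i, j, t, Q, omega, Rmat, P, states,
                                  max_retry = 5L) {
  k <- length(states)
  if (t == 0 || omega == 0) {
    if (i != j) stop("endpoint change on a zero-length/zero-rate branch")
    return(setNames(t, states[i]))
  }
  pij <- P[i, j]
  if (pij <= 0) stop("endpoint pair with zero path probability")
  mu <- omega * t
  # distribution of N, the number of uniformized (real + virtual) jumps:
  # P(N = r | i, j) prop-to dpois(r, mu) * (R^r)[i, j], truncated once the
  # accumulated mass covers P[i, j] to within a negligible tail
  rmax <- max(20L, ceiling(mu + 12 * sqrt(mu) + 10))
  Rpow <- vector("list", rmax + 1L)
  Rpow[[1L]] <- diag(k)
  probs <- numeric(rmax + 1L)
  probs[1L] <- dpois(0, mu) * (i == j)
  r_top <- 0L
  acc <- probs[1L]
  while (acc < pij * (1 - 1e-12) && r_top < rmax) {
    r_top <- r_top + 1L
    Rpow[[r_top + 1L]] <- Rpow[[r_top]] %*% Rmat
    probs[r_top + 1L] <- dpois(r_top, mu) * Rpow[[r_top + 1L]][i, j]
    acc <- acc + probs[r_top + 1L]
  }
  if (acc <= 0) stop("uniformization truncated after ", rmax, " jumps")
  r <- sample.int(r_top + 1L, 1L, prob = probs[seq_len(r_top + 1L)]) - 1L
  if (r == 0L) return(setNames(t, states[i]))
  # jump chain states: s_0 = i, s_r = j;
  # P(s_m = c | s_{m-1}, end) prop-to R[s_{m-1}, c] * (R^(r-m))[c, j]
  s <- integer(r + 1L)
  s[1L] <- i
  for (mdx in seq_len(r - 1L)) {
    w <- Rmat[s[mdx], ] * Rpow[[r - mdx + 1L]][, j]
    s[mdx + 1L] <- sample.int(k, 1L, prob = w)
  }
  s[r + 1L] <- j
  times <- sort(runif(r)) * t
  # collapse virtual jumps (state unchanged) into segments
  bounds <- c(0, times, t)
  seg_states <- states[s]
  keep <- c(TRUE, s[-1L] != s[-(r + 1L)])
  starts <- bounds[-length(bounds)][keep]
  st <- seg_states[keep]
  ends <- c(starts[-1L], t)
  setNames(ends - starts, st)
}

#' Summarize a set of stochastic maps
#'
#' Per-node state frequencies (the fraction of maps in which the node is
#' in each state -- the Bayesian posterior summary usually drawn as node
#' pies) and the mean number of transitions per ordered state pair across
#' maps.
#'
#' @param maps list of `simmap` objects over the same tree and alphabet.
#' @return object of class `transition_summary`: list with `node_freq`
#'   (nodes x states matrix of probabilities, rows sum to 1), `mean_counts`
#'   (states x states matrix of mean transition counts), `n_maps`.
#' @export
summarize_maps <- function(maps) {
  if (length(maps) == 0L) stop("need at least one map")
  ref <- maps[[1L]]
  states <- sort(unique(unlist(lapply(maps, function(m) colnames(m$mapped.edge)))))
  k <- length(states)
  nn <- ape::Ntip(ref) + ref$Nnode
  for (m in maps) {
    if (ape::Ntip(m) != ape::Ntip(ref) ||
        !identical(m$tip.label, ref$tip.label) ||
        !identical(m$edge, ref$edge))
      stop("maps are not all over the same tree")
  }
  freq <- matrix(0, nn, k, dimnames = list(NULL, states))
  counts <- matrix(0, k, k, dimnames = list(states, states))
  for (m in maps) {
    ns <- simmap_node_states(m)
    freq[cbind(seq_len(nn), match(ns, states))] <-
      freq[cbind(seq_len(nn), match(ns, states))] + 1
    cm <- count_transitions(m, states = states)
    counts <- counts + cm
  }
  structure(list(node_freq = freq / length(maps),
                 mean_counts = counts / length(maps),
                 n_maps = length(maps)),
            class = "transition_summary")
}

#' Write map summaries as TSV
#'
#' @param summary a `transition_summary`.
#' @param node_file,count_file output paths (either may be `NULL`).
#' @return invisibly, a list of the two data frames written.
#' @export
write_map_summary <- function(summary, node_file = NULL, count_file = NULL) {
  nf <- summary$node_freq
  node_df <- data.frame(node_id = rep(seq_len(nrow(nf)), ncol(nf)),
                        state = rep(colnames(nf), each = nrow(nf)),
                        frequency = as.vector(nf))
  mc <- summary$mean_counts
  count_df <- data.frame(from_state = rep(rownames(mc), ncol(mc)),
                         to_state = rep(colnames(mc), each = nrow(mc)),
                         mean_count = as.vector(mc))
  if (!is.null(node_file))
    write.table(node_df, node_file, sep = "\t", row.names = FALSE,
                quote = FALSE)
  if (!is.null(count_file))
    write.table(count_df, count_file, sep = "\t", row.names = FALSE,
                quote = FALSE)
  invisible(list(node_freq = node_df, mean_counts = count_df))
}
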