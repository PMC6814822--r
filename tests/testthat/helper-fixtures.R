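# Shared fixtures and independent oracles. Everything is generated in
# code; no stored data files.

cherry3 <- function() read_tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n, depth = 1) {
  txt <- paste0("(", paste0("t", seq_len(n), ":", depth, collapse = ","),
                ");")
  read_tree(text = txt)
}

random_yule <- function(n, depth = 10, seed = NULL) {
  simulate_tree(simulation_recipe(n_tips = n, depth = depth), seed = seed)
}

# brute-force phylogenetic covariance: sum of shared edges per tip pair
vcv_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  # edges on the root-to-tip path of each tip
  paths <- lapply(seq_len(n), function(tip) {
    p <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2L] == node)
      p <- c(p, e)
      node <- tree$edge[e, 1L]
    }
    p
  })
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  }
  C
}

# non-phylogenetic RMA oracle: sample SDs and correlation computed directly
flat_rma_oracle <- function(x, y) {
  b <- sign(cov(x, y)) * sd(y) / sd(x)
  r2 <- cor(x, y)^2
  list(slope = b, intercept = mean(y) - b * mean(x), r2 = r2)
}

# exhaustive Mk likelihood: sum over all ancestral state assignments
mk_loglik_enumerate <- function(tree, tip_states, Q, root_prior = NULL) {
  states <- colnames(Q)
  k <- length(states)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  root <- n + 1L
  Pm <- lapply(tree$edge.length, function(t) as.matrix(expm::expm(Q * t)))
  tip_idx <- match(tip_states[tree$tip.label], states)
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    state_of <- function(node) {
      if (node <= n) tip_idx[node] else assign_int[node - n]
    }
    p <- root_prior[state_of(root)]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Pm[[e]][state_of(tree$edge[e, 1L]), state_of(tree$edge[e, 2L])]
    }
    total <- total + p
  }
  log(total)
}

# exact marginal posterior of each internal node state by enumeration
node_posterior_enumerate <- function(tree, tip_states, Q, root_prior = NULL) {
  states <- colnames(Q)
  k <- length(states)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  root <- n + 1L
  Pm <- lapply(tree$edge.length, function(t) as.matrix(expm::expm(Q * t)))
  tip_idx <- match(tip_states[tree$tip.label], states)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  post <- matrix(0, nn, k, dimnames = list(NULL, states))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    a <- grid[g, ]
    state_of <- function(node) if (node <= n) tip_idx[node] else a[node - n]
    p <- root_prior[state_of(root)]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Pm[[e]][state_of(tree$edge[e, 1L]), state_of(tree$edge[e, 2L])]
    post[cbind(seq_len(nn), a)] <- post[cbind(seq_len(nn), a)] + p
    total <- total + p
  }
  post / total
}

# generic multivariate normal log-density oracle
mvn_logdens_oracle <- function(y, mean, V) {
  n <- length(y)
  r <- y - mean
  -0.5 * n * log(2 * pi) - 0.5 * determinant(V, logarithm = TRUE)$modulus -
    0.5 * sum(r * solve(V, r))
}

# a small painted 2-regime map on a fixed tree (deterministic)
two_regime_map <- function(tree, shift_edge, shift_frac = 0.5) {
  maps <- lapply(seq_len(nrow(tree$edge)),
                 function(e) setNames(tree$edge.length[e], "bg"))
  desc_nodes <- phytools::getDescendants(tree, tree$edge[shift_edge, 2L])
  for (e in which(tree$edge[, 2L] %in% desc_nodes))
    maps[[e]] <- setNames(tree$edge.length[e], "fg")
  el <- tree$edge.length[shift_edge]
  maps[[shift_edge]] <- c(bg = el * shift_frac, fg = el * (1 - shift_frac))
  make_simmap_tree(tree, maps, states = c("bg", "fg"))
}

# random ER rate matrix
er_Q <- function(q, states) {
  k <- length(states)
  Q <- matrix(q, k, k, dimnames = list(states, states))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
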