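#' Construct a continuous-time Markov (Mk) model of a discrete character
#'
#' @param states character vector, the state alphabet.
#' @param Q rate matrix (transitions/Myr): off-diagonals non-negative,
#'   rows summing to zero.
#' @param root_prior probability distribution over states at the root
#'   (default equal).
#' @param structure one of `"ER"` (one rate), `"SYM"` (symmetric rates),
#'   `"ARD"` (all rates different); informational once `Q` is given.
#' @return an object of class `mk_model`.
#' @export
mk_model <- function(states, Q, root_prior = NULL,
                     structure = c("ER", "SYM", "ARD")) {
  structure <- match.arg(structure)
  k <- length(states)
  if (k < 2L) stop("need at least two states")
  if (anyDuplicated(states)) stop("duplicate states")
  Q <- as.matrix(Q)
  if (!all(dim(Q) == k)) stop("Q must be ", k, " x ", k)
  dimnames(Q) <- list(states, states)
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-10 * max(1, max(abs(Q)))))
    stop("Q rows must sum to zero")
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  if (length(root_prior) != k || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-9)
    stop("root_prior must be a probability distribution over the states")
  structure(list(states = states, Q = Q,
                 root_prior = setNames(as.numeric(root_prior), states),
                 structure = structure),
            class = "mk_model")
}

# Transition-probability function for a rate matrix: returns P(t) = exp(Qt).
# Eigendecomposition is cached; falls back to expm() when the decomposition
# is ill-conditioned (near-defective Q).
mk_transition_fn <- function(Q) {
  k <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  Vi <- NULL
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      kap <- max(Mod(eg$vectors)) * max(Mod(Vi))
      use_eigen <- is.finite(kap) && kap < 1e8
    }
  }
  function(t) {
    if (t == 0) return(diag(k))
    P <- if (use_eigen) {
      Re(eg$vectors %*% (exp(eg$values * t) * Vi))
    } else {
      as.matrix(expm::expm(Q * t))
    }
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

# tip states (character vector named by tip label, or a tips x states
# likelihood matrix) -> tips x states 0/1 likelihood matrix in tip order
tip_state_matrix <- function(tree, tip_states, states) {
  n <- ape::Ntip(tree)
  if (is.matrix(tip_states)) {
    L <- tip_states[tree$tip.label, states, drop = FALSE]
    return(L)
  }
  x <- tip_states
  if (!is.null(names(x))) x <- x[tree$tip.label]
  if (length(x) != n) stop("need one state per tip")
  if (anyNA(x)) stop("missing tip state(s)")
  bad <- setdiff(unique(x), states)
  if (length(bad) > 0L)
    stop("tip state(s) not in the alphabet: ", paste(bad, collapse = ", "))
  L <- matrix(0, n, length(states), dimnames = list(tree$tip.label, states))
  L[cbind(seq_len(n), match(x, states))] <- 1
  L
}

# Felsenstein pruning: per-node conditional likelihoods, with per-node
# log-scaling to avoid underflow. Returns list(partial = matrix nodes x k
# of scaled conditionals, logscale = per-node accumulated log scale,
# Pmats = per-edge transition matrices).
mk_pruning <- function(tree, tip_states, Q, root_prior) {
  k <- ncol(Q)
  states <- colnames(Q)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  L <- matrix(1, nn, k)
  L[seq_len(n), ] <- tip_state_matrix(tree, tip_states, states)
  logscale <- numeric(nn)
  Pfun <- mk_transition_fn(Q)
  # cache transition matrices per unique branch length
  el <- tree$edge.length
  uel <- unique(el)
  Pcache <- lapply(uel, Pfun)
  Pmats <- Pcache[match(el, uel)]
  ord <- rev(reorder_edges_preorder(tree))  # postorder: children first
  for (kk in ord) {
    par <- tree$edge[kk, 1L]
    ch <- tree$edge[kk, 2L]
    msg <- Pmats[[kk]] %*% L[ch, ]
    L[par, ] <- L[par, ] * msg
    logscale[par] <- logscale[par] + logscale[ch]
    m <- max(L[par, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      L[par, ] <- L[par, ] / m
      logscale[par] <- logscale[par] + log(m)
    }
  }
  root <- n + 1L
  list(partial = L, logscale = logscale, Pmats = Pmats, root = root)
}

#' Mk log-likelihood of tip states on a tree
#'
#' Felsenstein pruning with per-branch transition probabilities
#' `P(t) = exp(Qt)` and summation over the root prior.
#'
#' @param tree an [ape::phylo] object.
#' @param tip_states named character vector of tip states (or a tips x
#'   states likelihood matrix for ambiguous tips).
#' @param Q rate matrix with state dimnames, or an `mk_model`.
#' @param root_prior distribution over states at the root (default equal).
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = NULL) {
  validate_tree(tree)
  if (inherits(Q, "mk_model")) {
    if (is.null(root_prior)) root_prior <- Q$root_prior
    Q <- Q$Q
  }
  k <- ncol(Q)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  pr <- mk_pruning(tree, tip_states, Q, root_prior)
  lik <- sum(root_prior * pr$partial[pr$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[pr$root]
}

# build Q from a parameter vector under a structure
mk_build_Q <- function(rates, k, structure, states) {
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (structure == "ER") {
    Q[] <- rates[1L]
  } else if (structure == "SYM") {
    Q[upper.tri(Q)] <- rates
    Q <- Q + t(Q)
  } else {
    idx <- which(row(Q) != col(Q))
    Q[idx[order(row(Q)[idx], col(Q)[idx])]] <- rates
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

mk_n_rates <- function(k, structure) {
  switch(structure, ER = 1L, SYM = k * (k - 1L) / 2L, ARD = k * (k - 1L))
}

#' Maximum-likelihood fit of an Mk model
#'
#' Estimates the transition rate(s) by bounded optimization of
#' [mk_loglik()] on the log-rate scale. With a constant character the rate
#' estimate sits at the lower optimization bound.
#'
#' @param tree an [ape::phylo] object.
#' @param tip_states named character vector of tip states.
#' @param structure `"ER"`, `"SYM"`, or `"ARD"`.
#' @param states optional alphabet (defaults to observed states).
#' @param root_prior root distribution (default equal).
#' @param rate_bounds lower/upper bounds on each rate (per Myr).
#' @return an `mk_model` with extra fields `lnL`, `convergence`.
#' @export
fit_mk <- function(tree, tip_states, structure = c("ER", "SYM", "ARD"),
                   states = NULL, root_prior = NULL,
                   rate_bounds = c(1e-8, 100)) {
  structure <- match.arg(structure)
  validate_tree(tree)
  if (is.null(states)) states <- sort(unique(unname(tip_states)))
  k <- length(states)
  if (k < 2L) stop("need at least two observed states to fit rates")
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  np <- mk_n_rates(k, structure)
  obj <- function(logr) {
    Q <- mk_build_Q(exp(logr), k, structure, states)
    ll <- mk_loglik(tree, tip_states, Q, root_prior)
    if (!is.finite(ll)) -1e10 else ll
  }
  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])
  # starting rate: one expected change per total tree length
  start <- log(max(1 / sum(tree$edge.length), rate_bounds[1L] * 10))
  if (np == 1L) {
    op <- optimize(function(lr) obj(lr), interval = c(lb, ub), maximum = TRUE,
                   tol = 1e-8)
    logr <- op$maximum; lnL <- op$objective
    # pin to the bound when the profile is flat toward it
    if (obj(lb) >= lnL - 1e-8) { logr <- lb; lnL <- obj(lb) }
    conv <- 0L
  } else {
    op <- optim(rep(start, np), obj, method = "L-BFGS-B", lower = lb,
                upper = ub, control = list(fnscale = -1, maxit = 500))
    if (op$convergence != 0L)
      stop("Mk optimization did not converge (code ", op$convergence,
           "); best lnL ", signif(op$value, 8))
    logr <- op$par; lnL <- op$value; conv <- op$convergence
  }
  out <- mk_model(states, mk_build_Q(exp(logr), k, structure, states),
                  root_prior = root_prior, structure = structure)
  out$lnL <- lnL
  out$convergence <- conv
  out
}
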