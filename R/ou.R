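#' Ornstein-Uhlenbeck regime weight matrix of a mapped tree
#'
#' For tip i at depth T with root-to-tip regime history split into
#' segments `[t1, t2]` (times measured from the root), the weight of
#' regime r is the sum over segments painted r of
#' `exp(-alpha (T - t2)) - exp(-alpha (T - t1))`: the fraction of the
#' tip's expected value contributed by that regime's optimum under an OU
#' process with attraction `alpha`. The residual root mass `exp(-alpha T)`
#' is allocated to the ancestral-most (root) regime, the non-stationary
#' root treatment in which the root optimum is merged with the root
#' regime's optimum. Every row sums to 1 exactly (telescoping).
#'
#' @param map a `simmap` object (ultrametric).
#' @param alpha attraction strength (1/Myr), `>= 0`.
#' @param regimes optional regime alphabet ordering the columns.
#' @return tips x regimes matrix of weights.
#' @export
ou_weight_matrix <- function(map, alpha, regimes = NULL) {
  if (alpha < 0) stop("`alpha` must be non-negative")
  cache <- ou_cache(map, regimes)
  ou_weights_from_cache(cache, alpha)
}

# Precompute everything alpha-independent about a mapped tree:
# shared-time matrix C, depths, patristic distances, flattened per-tip
# segment table, root regime. `map` may be a plain phylo (single regime).
ou_cache <- function(map, regimes = NULL) {
  validate_tree(map)
  n <- ape::Ntip(map)
  C <- ape::vcv.phylo(map)
  Tdep <- diag(C)
  D <- outer(Tdep, Tdep, "+") - 2 * C
  if (is.null(map$maps)) {
    regimes <- if (is.null(regimes)) "theta" else regimes
    segs <- data.frame(tip = seq_len(n), regime = 1L, t0 = 0, t1 = Tdep)
    root_regime <- 1L
  } else {
    if (is.null(regimes)) regimes <- colnames(map$mapped.edge)
    hist <- tip_histories(map)
    segs <- do.call(rbind, lapply(seq_len(n), function(i) {
      h <- hist[[map$tip.label[i]]]
      data.frame(tip = i, regime = match(h$state, regimes),
                 t0 = h$t0, t1 = h$t1)
    }))
    if (anyNA(segs$regime))
      stop("map uses states outside the supplied regime alphabet")
    root_regime <- segs$regime[segs$tip == 1L][1L]
  }
  list(n = n, C = C, Tdep = Tdep, D = D, segs = segs, regimes = regimes,
       root_regime = root_regime, tip_labels = rownames(C),
       seg_tip = segs$tip, seg_t0 = segs$t0, seg_t1 = segs$t1,
       seg_Tt = Tdep[segs$tip],
       seg_key = segs$tip + n * (segs$regime - 1L),
       ultrametric = diff(range(Tdep)) <= 1e-6 * max(Tdep))
}

ou_weights_from_cache <- function(cache, alpha) {
  n <- cache$n
  k <- length(cache$regimes)
  W <- matrix(0, n, k, dimnames = list(cache$tip_labels, cache$regimes))
  if (alpha == 0) {
    W[, cache$root_regime] <- 1
    return(W)
  }
  w_seg <- exp(-alpha * (cache$seg_Tt - cache$seg_t1)) -
    exp(-alpha * (cache$seg_Tt - cache$seg_t0))
  agg <- rowsum(w_seg, cache$seg_key)
  W[as.integer(rownames(agg))] <- agg
  W[, cache$root_regime] <- W[, cache$root_regime] + exp(-alpha * cache$Tdep)
  W
}

#' Ornstein-Uhlenbeck covariance matrix on a tree
#'
#' Non-stationary-root OU covariance:
#' `V[i, j] = sigma2 / (2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha t_ij))`
#' with `d_ij` the patristic distance and `t_ij` the shared time of tips
#' i, j. The `alpha -> 0` limit is handled analytically as `sigma2 * C`
#' (Brownian motion).
#'
#' @param tree an [ape::phylo] object (or `simmap`).
#' @param alpha attraction (1/Myr), `>= 0`.
#' @param sigma2 diffusion variance (percent^2/Myr), `> 0`.
#' @return n x n covariance matrix (percent^2).
#' @export
ou_vcv <- function(tree, alpha, sigma2) {
  if (alpha < 0) stop("`alpha` must be non-negative")
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  cache <- ou_cache(tree)
  sigma2 * ou_corr_from_cache(cache, alpha)
}

# V0 = V / sigma2, from cached depth/distance matrices
ou_corr_from_cache <- function(cache, alpha) {
  if (alpha < 1e-12) return(cache$C)
  exp(-alpha * cache$D) * (-expm1(-2 * alpha * cache$C)) / (2 * alpha)
}

#' Phylogenetic half-life
#'
#' `ln(2) / alpha`: the time for the expected trait value to move halfway
#' to its optimum. `alpha = 0` gives `Inf` (Brownian-like, no attraction).
#'
#' @param alpha OU attraction strength (1/Myr).
#' @return half-life in Myr.
#' @export
half_life <- function(alpha) {
  if (any(alpha < 0)) stop("`alpha` must be non-negative")
  ifelse(alpha == 0, Inf, log(2) / alpha)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2p + 2p(p + 1)/(n - p - 1)`.
#'
#' @param lnL log-likelihood.
#' @param p number of free parameters.
#' @param n number of tips.
#' @return AICc.
#' @export
aicc <- function(lnL, p, n) {
  if (any(n <= p + 1)) stop("AICc undefined for n <= p + 1")
  -2 * lnL + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Akaike weights from AICc values
#'
#' `w_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2))`, `Delta` relative to
#' the minimum.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return weights summing to 1.
#' @export
aicc_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

# profile log-likelihood machinery: given alpha, theta is GLS and sigma2
# has a closed-form ML profile. Returns list(lnL, theta, sigma2, ...).
ou_profile_eval <- function(cache, alpha, y, keep_cols) {
  V0 <- ou_corr_from_cache(cache, alpha)
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) {
    # condition guard: tiny diagonal jitter, then retry
    L <- tryCatch(chol(V0 + diag(1e-10 * mean(diag(V0)), cache$n)),
                  error = function(e) NULL)
    if (is.null(L)) return(NULL)
  }
  W <- ou_weights_from_cache(cache, alpha)[, keep_cols, drop = FALSE]
  n <- cache$n
  yt <- backsolve(L, y, transpose = TRUE)
  Wt <- backsolve(L, W, transpose = TRUE)
  A <- crossprod(Wt)
  b <- crossprod(Wt, yt)
  theta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(theta)) return(NULL)
  r <- yt - Wt %*% theta
  rss <- sum(r * r)
  if (rss <= 0) rss <- 1e-300
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(L)))
  lnL <- -0.5 * n * log(2 * pi) - 0.5 * n * log(sigma2) - 0.5 * logdet -
    0.5 * n
  list(lnL = lnL, theta = drop(theta), sigma2 = sigma2, alpha = alpha)
}

#' Fit a Brownian or Ornstein-Uhlenbeck model to a trait on a (mapped) tree
#'
#' Models: `BM1` (single-rate Brownian motion, parameters: root mean,
#' sigma2), `OU1` (single optimum theta, parameters alpha, sigma2, theta),
#' `OUM` (one optimum per mapped regime, shared alpha and sigma2). For OU
#' models theta is profiled by generalized least squares and sigma2 by its
#' closed-form maximum-likelihood expression, so the optimization is a
#' one-dimensional search over alpha (coarse log-grid spanning half-lives
#' from depth/100 to 10x depth, then Brent refinement). The root optimum
#' is merged into the ancestral-most regime's theta (non-stationary root).
#'
#' @param model_id `"BM1"`, `"OU1"`, or `"OUM"`.
#' @param map a `simmap` object (OUM) or any [ape::phylo] (BM1/OU1).
#' @param sdi named numeric vector of trait values (percent), names
#'   matching tip labels.
#' @param alpha_bounds optional lower/upper bounds on alpha (1/Myr).
#' @return an `ou_fit` list: `model`, `alpha`, `sigma2`, `theta` (named;
#'   for BM1 the single entry is the root mean), `lnL`, `p`, `n`, `aicc`,
#'   `regimes`.
#' @export
fit_model <- function(model_id = c("BM1", "OU1", "OUM"), map, sdi,
                      alpha_bounds = NULL) {
  model_id <- match.arg(model_id)
  cache <- ou_cache_for_model(model_id, map)
  fit_model_cached(model_id, cache, sdi, alpha_bounds)
}

ou_cache_for_model <- function(model_id, map) {
  if (model_id == "OUM") {
    if (is.null(map$maps)) stop("OUM requires a mapped tree")
    ou_cache(map)
  } else {
    tr <- map
    tr$maps <- NULL
    ou_cache(tr)
  }
}

fit_model_cached <- function(model_id, cache, sdi, alpha_bounds = NULL) {
  y <- match_trait(cache$tip_labels, sdi)
  n <- cache$n
  if (model_id == "BM1") {
    ev <- ou_profile_eval(cache, 0, y, 1L)
    p <- 2L
    if (n <= p + 1L) stop("too few tips for BM1 (n <= p + 1)")
    fit <- list(model = "BM1", alpha = 0, sigma2 = ev$sigma2,
                theta = setNames(ev$theta, "root_mean"), lnL = ev$lnL,
                p = p, n = n, aicc = aicc(ev$lnL, p, n),
                regimes = "root_mean")
    class(fit) <- "ou_fit"
    return(fit)
  }
  # OU1 / OUM
  keep_cols <- seq_along(cache$regimes)
  if (model_id == "OUM" && length(cache$regimes) > 1L) {
    # drop regimes carrying no weight anywhere (absent from histories)
    Wprobe <- ou_weights_from_cache(cache, 1 / max(cache$Tdep))
    occupied <- colSums(abs(Wprobe)) > 1e-10
    if (!all(occupied)) {
      warning("regime(s) absent from the mapped histories dropped: ",
              paste(cache$regimes[!occupied], collapse = ", "))
      keep_cols <- which(occupied)
    }
  }
  k <- length(keep_cols)
  p <- if (model_id == "OU1") 3L else 2L + k
  if (n <= p + 1L) stop("too few tips (n <= p + 1; AICc undefined)")
  Tmax <- max(cache$Tdep)
  lo <- if (is.null(alpha_bounds)) log(2) / (100 * Tmax) else alpha_bounds[1L]
  hi <- if (is.null(alpha_bounds)) 100 * log(2) / Tmax else alpha_bounds[2L]
  f <- function(a) {
    ev <- ou_profile_eval(cache, a, y, keep_cols)
    if (is.null(ev)) -Inf else ev$lnL
  }
  grid <- exp(seq(log(lo), log(hi), length.out = 12L))
  vals <- vapply(grid, f, numeric(1))
  if (all(!is.finite(vals))) stop("OU likelihood evaluation failed on the whole alpha grid")
  ibest <- which.max(vals)
  bl <- grid[max(1L, ibest - 1L)]
  bu <- grid[min(length(grid), ibest + 1L)]
  op <- optimize(function(la) f(exp(la)), interval = c(log(bl), log(bu)),
                 maximum = TRUE, tol = 1e-8)
  alpha_hat <- exp(op$maximum)
  if (op$objective < vals[ibest]) alpha_hat <- grid[ibest]
  ev <- ou_profile_eval(cache, alpha_hat, y, keep_cols)
  if (is.null(ev)) stop("OU fit failed at the optimum")
  theta <- setNames(ev$theta, cache$regimes[keep_cols])
  if (model_id == "OU1") names(theta) <- "theta"
  fit <- list(model = model_id, alpha = alpha_hat, sigma2 = ev$sigma2,
              theta = theta, lnL = ev$lnL, p = p, n = n,
              aicc = aicc(ev$lnL, p, n),
              regimes = names(theta))
  class(fit) <- "ou_fit"
  fit
}

match_trait <- function(tip_labels, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tip_labels))
      stop("unnamed trait vector of the wrong length")
    return(as.numeric(trait))
  }
  nm <- normalize_label(names(trait))
  idx <- match(normalize_label(tip_labels), nm)
  if (anyNA(idx))
    stop("trait values missing for tip(s): ",
         paste(tip_labels[is.na(idx)], collapse = ", "))
  as.numeric(trait[idx])
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, lnL = %.4f, AICc = %.4f\n",
              x$model, x$n, x$lnL, x$aicc))
  cat(sprintf("  alpha = %.6g /Myr (half-life %.4g Myr), sigma2 = %.6g\n",
              x$alpha, half_life(x$alpha), x$sigma2))
  cat("  theta (percent):\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Brownian-motion ancestral state estimates
#'
#' Generalized-least-squares (equivalently joint-ML) ancestral estimates
#' of a continuous trait at every internal node under Brownian motion,
#' with standard errors from the conditional variance. The root estimate
#' equals the GLS phylogenetic mean.
#'
#' @param tree an [ape::phylo] object.
#' @param trait named numeric vector over the tips.
#' @return data.frame with `node` (ape node id), `estimate`, `se`.
#' @export
bm_ancestral_states <- function(tree, trait) {
  validate_tree(tree)
  y <- match_trait(tree$tip.label, trait)
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  depth <- node_depths(tree)
  Dfull <- ape::dist.nodes(tree)
  share <- (outer(depth, depth, "+") - Dfull) / 2
  tips <- seq_len(n)
  anc <- n + seq_len(nn)
  C <- share[tips, tips]
  Cinv_y <- solve(C, y - 0)
  one <- rep(1, n)
  Cinv_1 <- solve(C, one)
  mu <- sum(Cinv_y) / sum(Cinv_1)
  resid <- y - mu
  Cinv_r <- solve(C, resid)
  sigma2 <- sum(resid * Cinv_r) / n
  S_at <- share[anc, tips, drop = FALSE]
  est <- mu + as.vector(S_at %*% Cinv_r)
  # conditional variance of each ancestral value given the tips
  CinvSt <- solve(C, t(S_at))
  cond <- depth[anc] - colSums(t(S_at) * CinvSt)
  cond[cond < 0] <- 0
  data.frame(node = anc, estimate = est, se = sqrt(sigma2 * cond))
}
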