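# bivariate Brownian log-likelihood profile in lambda: GLS means and ML
# evolutionary covariance given the lambda-transformed tree covariance
rma_lambda_loglik <- function(lam, X, C) {
  n <- nrow(X)
  Cl <- lambda_transform(C, lam)
  L <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(L)) return(list(lnL = -Inf))
  Xt <- backsolve(L, X, transpose = TRUE)
  onet <- backsolve(L, rep(1, n), transpose = TRUE)
  a <- crossprod(onet, Xt) / sum(onet * onet)
  Rt <- Xt - onet %*% a
  S <- crossprod(Rt)            # GLS residual cross-products
  R_ml <- S / n                 # ML scale for the likelihood
  detR <- R_ml[1, 1] * R_ml[2, 2] - R_ml[1, 2]^2
  # exactly collinear data: clamp the determinant so the slope and r2
  # are still returned (the likelihood degenerates but its argmax is
  # immaterial in that case)
  if (detR <= 0) detR <- 1e-300
  logdetC <- 2 * sum(log(diag(L)))
  m <- 2L
  lnL <- -0.5 * (n * m * log(2 * pi) + n * log(detR) + m * logdetC + n * m)
  list(lnL = lnL, a = drop(a), S = S)
}

#' Phylogenetic reduced major axis regression with Pagel's lambda
#'
#' Fits the RMA (standardized major axis) line of `y` on `x` under a
#' bivariate Brownian model whose residual covariance is the
#' lambda-transformed phylogenetic covariance; lambda is estimated
#' simultaneously by maximizing the bivariate log-likelihood on `[0, 1]`.
#' Phylogenetic means are generalized least squares; evolutionary
#' (co)variances are GLS residual cross-products divided by `n - 1`; the
#' slope is `sign(s_xy) * sqrt(s_yy / s_xx)`.
#'
#' For Rensch's-rule tests, `y` should be ln male mass and `x` ln female
#' mass, so that a slope above 1 means male-biased hyperallometry.
#'
#' @param tree an [ape::phylo] object.
#' @param x,y named numeric vectors over the tips (typically ln female
#'   and ln male body mass, g).
#' @param lambda optional fixed lambda; `NULL` (default) estimates it.
#' @param clade optional clade label carried into the result.
#' @return an `rma_result`: list with `slope`, `se`, `intercept`,
#'   `lambda`, `r2`, `lnL`, `n`, `clade`, and (after [test_slope()]) `T`,
#'   `df`, `P`.
#' @export
fit_phylo_rma <- function(tree, x, y, lambda = NULL, clade = "all") {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  if (n < 3L) stop("need at least 3 tips")
  xv <- match_trait(tree$tip.label, x)
  yv <- match_trait(tree$tip.label, y)
  X <- cbind(x = xv, y = yv)
  C <- phylo_vcv(tree)
  if (is.null(lambda)) {
    # bounded search with the endpoints checked too (boundary optima are
    # common: lambda-hat = 0 on star-like residuals, 1 on Brownian ones)
    op <- optimize(function(l) rma_lambda_loglik(l, X, C)$lnL,
                   interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, op$maximum, 1)
    lls <- vapply(cand, function(l) rma_lambda_loglik(l, X, C)$lnL,
                  numeric(1))
    lambda <- cand[which.max(lls)]
  } else {
    if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]")
  }
  ev <- rma_lambda_loglik(lambda, X, C)
  if (!is.finite(ev$lnL)) stop("degenerate data: singular evolutionary covariance")
  Svc <- ev$S / (n - 1)
  s_xx <- Svc[1, 1]; s_yy <- Svc[2, 2]; s_xy <- Svc[1, 2]
  if (s_xx <= 0) stop("degenerate x: zero evolutionary variance")
  if (s_yy <= 0) stop("degenerate y: zero evolutionary variance")
  b <- sign(s_xy) * sqrt(s_yy / s_xx)
  if (b == 0) b <- sqrt(s_yy / s_xx)  # zero covariance: conventional + sign
  r2 <- s_xy^2 / (s_xx * s_yy)
  # standard RMA slope standard error via r2
  se <- abs(b) * sqrt((1 - r2) / (n - 2))
  out <- list(slope = b, se = se, intercept = ev$a[2] - b * ev$a[1],
              lambda = lambda, r2 = r2, lnL = ev$lnL, n = n, clade = clade,
              means = ev$a, s_xx = s_xx, s_yy = s_yy, s_xy = s_xy)
  class(out) <- "rma_result"
  out
}

#' Test an RMA slope against a null value
#'
#' Two-sided test of the RMA slope against `b0` on the log-slope scale,
#' `T = |log(b) - log(b0)| / sqrt((1 - r2)/(n - 2))`, referred to a t
#' distribution with Clarke's effective degrees of freedom
#' `df = 2 + (n - 2)/(1 + r2/2)` (non-integer in general). `b = b0`
#' gives `T = 0`, `P = 1`.
#'
#' @param result an `rma_result`.
#' @param b0 null slope (default 1, isometry / Rensch null).
#' @return the `rma_result` augmented with `T`, `df`, `P`, `b0`.
#' @export
test_slope <- function(result, b0 = 1) {
  if (!inherits(result, "rma_result")) stop("`result` must be an rma_result")
  b <- result$slope
  if (b <= 0 && b0 > 0)
    stop("slope is non-positive; the log-scale test against a positive null is undefined")
  df <- 2 + (result$n - 2) / (1 + result$r2 / 2)
  if (result$r2 >= 1 - 1e-12) {
    # perfectly collinear data: the statistic degenerates to 0/0 at the
    # null and infinity elsewhere
    Tstat <- if (abs(log(b) - log(b0)) < 1e-12) 0 else Inf
  } else {
    Tstat <- abs(log(abs(b)) - log(abs(b0))) /
      sqrt((1 - result$r2) / (result$n - 2))
  }
  P <- 2 * pt(Tstat, df = df, lower.tail = FALSE)
  result$T <- Tstat
  result$df <- df
  result$P <- P
  result$b0 <- b0
  result
}

#' Classify a Rensch trend from a tested RMA fit
#'
#' `positive` if `P < alpha` and slope above the null (male-biased SSD
#' increasing with size), `negative` if `P < alpha` and slope below,
#' `none` otherwise.
#'
#' @param result an `rma_result` that has been through [test_slope()].
#' @param alpha significance threshold (default 0.05).
#' @return one of `"positive"`, `"negative"`, `"none"`.
#' @export
classify_rensch <- function(result, alpha = 0.05) {
  if (is.null(result$P)) stop("run test_slope() first")
  if (result$P < alpha) {
    if (result$slope > result$b0) "positive" else "negative"
  } else "none"
}

#' Per-clade phylogenetic RMA fits
#'
#' Runs [fit_phylo_rma()] + [test_slope()] on the full tree and on the
#' subtree induced by each clade (pruning the tree to the clade's
#' species). Clades with fewer than 3 species are skipped with a warning;
#' a clade whose fit fails (e.g. all-identical x) is reported as failed
#' while the others are still returned.
#'
#' @param tree an [ape::phylo] object.
#' @param x,y named trait vectors (see [fit_phylo_rma()]).
#' @param clades named character/factor vector mapping each species to a
#'   clade.
#' @param b0 null slope.
#' @param alpha significance threshold.
#' @return data.frame with one row per clade (global fit first, labelled
#'   `"all"`): clade, n, slope, se, lambda, r2, T, df, P, rensch_call.
#' @export
rma_by_clade <- function(tree, x, y, clades, b0 = 1, alpha = 0.05) {
  validate_tree(tree)
  if (is.null(names(clades))) stop("`clades` must be named by species")
  species <- intersect(tree$tip.label, names(clades))
  rows <- list()
  as_row <- function(fit) {
    data.frame(clade = fit$clade, n = fit$n, slope = fit$slope,
               se = fit$se, lambda = fit$lambda, r2 = fit$r2,
               T = fit$T, df = fit$df, P = fit$P,
               rensch_call = classify_rensch(fit, alpha),
               stringsAsFactors = FALSE)
  }
  global <- test_slope(fit_phylo_rma(tree, x, y, clade = "all"), b0 = b0)
  rows[["all"]] <- as_row(global)
  for (cl in sort(unique(as.character(clades[species])))) {
    sp <- species[as.character(clades[species]) == cl]
    if (length(sp) < 3L) {
      warning("clade '", cl, "' has fewer than 3 species; skipped")
      next
    }
    res <- tryCatch({
      sub <- prune_to_taxa(tree, sp)
      test_slope(fit_phylo_rma(sub, x[sp], y[sp], clade = cl), b0 = b0)
    }, error = function(e) e)
    rows[[cl]] <- if (inherits(res, "error")) {
      warning("clade '", cl, "' fit failed: ", conditionMessage(res))
      data.frame(clade = cl, n = length(sp), slope = NA_real_,
                 se = NA_real_, lambda = NA_real_, r2 = NA_real_,
                 T = NA_real_, df = NA_real_, P = NA_real_,
                 rensch_call = NA_character_, stringsAsFactors = FALSE)
    } else as_row(res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a per-clade RMA table as TSV
#' @param table output of [rma_by_clade()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_rma_table <- function(table, file) {
  write.table(table, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.rma_result <- function(x, ...) {
  cat(sprintf("Phylogenetic RMA (%s): slope = %.4f +- %.4f, lambda = %.3f, r2 = %.3f, n = %d\n",
              x$clade, x$slope, x$se, x$lambda, x$r2, x$n))
  if (!is.null(x$P))
    cat(sprintf("  H0 slope = %g: T = %.4f, df = %.2f, P = %.4g (%s)\n",
                x$b0, x$T, x$df, x$P, classify_rensch(x)))
  invisible(x)
}
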