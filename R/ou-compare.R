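# mean vector and covariance matrix implied by a fitted model on a cache
ou_mean_cov <- function(fit, cache) {
  if (fit$model == "BM1") {
    m <- rep(unname(fit$theta[1L]), cache$n)
    V <- fit$sigma2 * cache$C
  } else {
    keep <- if (fit$model == "OU1") seq_along(cache$regimes)
            else match(names(fit$theta), cache$regimes)
    W <- ou_weights_from_cache(cache, fit$alpha)[, keep, drop = FALSE]
    m <- as.vector(W %*% unname(fit$theta))
    V <- fit$sigma2 * ou_corr_from_cache(cache, fit$alpha)
  }
  list(mean = m, cov = V)
}

# one multivariate-normal draw given a precomputed upper Cholesky factor
mvn_draw <- function(mean, cholV) {
  mean + as.vector(crossprod(cholV, rnorm(length(mean))))
}

#' Compare trait-evolution models across stochastic map replicates
#'
#' Fits `BM1` and `OU1` once (they do not depend on the regime maps) and
#' one `OUM` model per map in each supplied map set, then computes
#' per-map AICc weights across all models and averages the weights over
#' maps. The mean AICc, mean-AICc differences, mean weights, and the
#' per-map best-model tally are reported. Per-map weights are averaged
#' (rather than weights recomputed from mean AICc); both quantities are
#' retained in the returned object.
#'
#' @param map_sets named list; each element is a list of `simmap` objects
#'   over the same tree (one OUM model, named `OUM_<set name>`, per set).
#'   All sets must have the same number of maps.
#' @param sdi named trait vector (percent).
#' @param tree optional tree for the BM1/OU1 fits (default: first map).
#' @return a `model_comparison`: list with `table` (data.frame: model,
#'   mean_aicc, delta_aicc, mean_weight, weight_of_mean_aicc, n_best),
#'   `per_map_aicc`, `per_map_weights`, `best_model`, `n_maps`.
#' @export
compare_models <- function(map_sets, sdi, tree = NULL) {
  if (is.null(names(map_sets)) || any(!nzchar(names(map_sets))))
    stop("`map_sets` must be a named list of map sets")
  map_sets <- lapply(map_sets, function(s) {
    if (inherits(s, "phylo")) list(s) else unclass(s)
  })
  n_maps <- unique(vapply(map_sets, length, integer(1)))
  if (length(n_maps) != 1L)
    stop("all map sets must contain the same number of maps")
  if (is.null(tree)) tree <- map_sets[[1L]][[1L]]
  models <- c("BM1", "OU1", paste0("OUM_", names(map_sets)))

  fixed_bm <- fit_model("BM1", tree, sdi)
  fixed_ou <- fit_model("OU1", tree, sdi)
  caches <- lapply(map_sets, function(s) lapply(s, ou_cache))

  aic <- matrix(NA_real_, n_maps, length(models),
                dimnames = list(NULL, models))
  aic[, "BM1"] <- fixed_bm$aicc
  aic[, "OU1"] <- fixed_ou$aicc
  fits_last <- list(BM1 = fixed_bm, OU1 = fixed_ou)
  for (s in seq_along(map_sets)) {
    col <- paste0("OUM_", names(map_sets)[s])
    for (i in seq_len(n_maps)) {
      f <- tryCatch(
        suppressWarnings(fit_model_cached("OUM", caches[[s]][[i]], sdi)),
        error = function(e) NULL)
      if (!is.null(f)) {
        aic[i, col] <- f$aicc
        fits_last[[col]] <- f
      }
    }
  }
  ok <- complete.cases(aic)
  if (sum(!ok) > 0L)
    warning(sum(!ok), " map(s) dropped due to fit failures")
  if (mean(!ok) > 0.10)
    stop("more than 10% of per-map fits failed (",
         sum(!ok), "/", n_maps, ")")
  aic_ok <- aic[ok, , drop = FALSE]
  w <- t(apply(aic_ok, 1L, aicc_weights))
  mean_aicc <- colMeans(aic_ok)
  delta <- mean_aicc - min(mean_aicc)
  mean_w <- colMeans(w)
  best_tally <- table(factor(models[apply(aic_ok, 1L, which.min)],
                             levels = models))
  tab <- data.frame(model = models,
                    mean_aicc = unname(mean_aicc),
                    delta_aicc = unname(delta),
                    mean_weight = unname(mean_w),
                    weight_of_mean_aicc = unname(aicc_weights(mean_aicc)),
                    n_best = as.integer(best_tally))
  structure(list(table = tab,
                 per_map_aicc = aic_ok,
                 per_map_weights = w,
                 best_model = models[which.max(mean_w)],
                 n_maps = nrow(aic_ok),
                 fits = fits_last),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison over", x$n_maps, "stochastic maps\n")
  tab <- x$table
  tab[, -1L] <- lapply(tab[, -1L], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  cat("Best model (highest mean AICc weight):", x$best_model, "\n")
  invisible(x)
}

#' Write a model comparison as TSV
#' @param comparison a `model_comparison`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_model_comparison <- function(comparison, file) {
  write.table(comparison$table, file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' Parametric-bootstrap confidence intervals for OU/BM parameters
#'
#' Simulates trait vectors from the fitted model's Gaussian
#' `(W theta, V)`, refits the same model on the same map, and reports
#' percentile intervals of the parameter draws. Replicates whose refit
#' fails are dropped; more than 20% failures is an error.
#'
#' @param fit an `ou_fit`.
#' @param map the `simmap` (or tree) the model was fitted on.
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @param level confidence level (default 0.95).
#' @return a `bootstrap_ci`: list with `table` (data.frame: parameter,
#'   point, lower, upper), `draws` (replicates x parameters), `n_ok`,
#'   `level`, `seed`.
#' @export
parametric_bootstrap <- function(fit, map, n_reps = 1000L, seed = NULL,
                                 level = 0.95) {
  if (!inherits(fit, "ou_fit")) stop("`fit` must be an ou_fit")
  if (!is.null(seed)) set.seed(seed)
  cache <- ou_cache_for_model(fit$model, map)
  mc <- ou_mean_cov(fit, cache)
  Lc <- chol(mc$cov)
  pnames <- c("alpha", "sigma2", paste0("theta_", names(fit$theta)))
  draws <- matrix(NA_real_, n_reps, length(pnames),
                  dimnames = list(NULL, pnames))
  for (r in seq_len(n_reps)) {
    ystar <- setNames(mvn_draw(mc$mean, Lc), cache$tip_labels)
    f <- tryCatch(
      suppressWarnings(fit_model_cached(fit$model, cache, ystar)),
      error = function(e) NULL)
    if (is.null(f)) next
    th <- f$theta[names(fit$theta)]
    draws[r, ] <- c(f$alpha, f$sigma2, unname(th))
  }
  ok <- complete.cases(draws)
  if (mean(!ok) > 0.20)
    stop("more than 20% of bootstrap refits failed (", sum(!ok), "/",
         n_reps, ")")
  d <- draws[ok, , drop = FALSE]
  a <- (1 - level) / 2
  point <- c(fit$alpha, fit$sigma2, unname(fit$theta))
  tab <- data.frame(parameter = pnames,
                    point = point,
                    lower = apply(d, 2L, quantile, probs = a),
                    upper = apply(d, 2L, quantile, probs = 1 - a),
                    row.names = NULL)
  structure(list(table = tab, draws = d, n_ok = sum(ok), level = level,
                 seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("Parametric bootstrap: %d successful replicates, %.0f%% CIs\n",
              x$n_ok, 100 * x$level))
  tab <- x$table
  tab[, -1L] <- lapply(tab[, -1L], function(v) signif(v, 5))
  print(tab, row.names = FALSE)
  invisible(x)
}
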