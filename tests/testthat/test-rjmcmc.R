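test_that("prior log-density is exchangeable and properly normalized over K", {
  tr <- random_yule(10, depth = 10, seed = 71)
  y <- setNames(rnorm(10, 20, 10), tr$tip.label)
  hyper <- rjmcmc_hyperprior(tr, y)
  B <- nrow(tr$edge)
  base <- list(branches = 3L, pos = 0.5, theta = 25, theta0 = 20,
               alpha = 0.2, sigma2 = 50)
  moved <- base; moved$branches <- 11L
  expect_equal(prior_logdensity(base, tr, hyper),
               prior_logdensity(moved, tr, hyper))
  # duplicate branches are impossible
  dup <- base
  dup$branches <- c(3L, 3L); dup$pos <- c(0.2, 0.8); dup$theta <- c(1, 2)
  expect_equal(prior_logdensity(dup, tr, hyper), -Inf)
  # K = 0 config carries only the scalar-parameter terms
  k0 <- list(branches = integer(0), pos = numeric(0), theta = numeric(0),
             theta0 = 20, alpha = 0.2, sigma2 = 50)
  manual <- dpois(0, 15, log = TRUE) - log(sum(dpois(0:B, 15))) +
    dnorm(20, hyper$theta_mean, hyper$theta_sd, log = TRUE) +
    dlnorm(0.2, hyper$alpha_meanlog, hyper$alpha_sdlog, log = TRUE) +
    dlnorm(50, hyper$sigma2_meanlog, hyper$sigma2_sdlog, log = TRUE)
  expect_equal(prior_logdensity(k0, tr, hyper), manual)
  # marginal P(K) sums to 1 after truncation
  pk <- dpois(0:B, 15) / sum(dpois(0:B, 15))
  expect_equal(sum(pk), 1)
})

test_that("chains are exactly reproducible given the seed", {
  tr <- random_yule(15, depth = 10, seed = 72)
  y <- setNames(rnorm(15, 20, 10), tr$tip.label)
  r1 <- run_rjmcmc(tr, y, n_gens = 2000, thin = 10, n_chains = 2, seed = 99)
  r2 <- run_rjmcmc(tr, y, n_gens = 2000, thin = 10, n_chains = 2, seed = 99)
  expect_identical(r1$chains[[1]]$lnL, r2$chains[[1]]$lnL)
  expect_identical(r1$chains[[2]]$K, r2$chains[[2]]$K)
  expect_identical(r1$chains[[1]]$shifts, r2$chains[[1]]$shifts)
})

test_that("posterior summaries follow their counting definitions", {
  tr <- random_yule(15, depth = 10, seed = 73)
  y <- setNames(rnorm(15, 20, 10), tr$tip.label)
  run <- run_rjmcmc(tr, y, n_gens = 5000, thin = 10, n_chains = 2,
                    seed = 74)
  post <- summarize_posterior(run, burn_in = 0.30, pp_threshold = 0.5)
  expect_true(all(post$pp >= 0 & post$pp <= 1))
  # sum of per-branch pp equals the mean K over retained samples
  expect_equal(sum(post$pp), mean(unlist(post$K_trace)), tolerance = 1e-9)
  # reported shifts all exceed the threshold strictly
  if (nrow(post$shifts) > 0)
    expect_true(all(post$shifts$pp > 0.5))
  # boundary: pp exactly below threshold is not reported
  expect_false(any(post$shifts$pp <= 0.5))
})

test_that("gelman_rubin distinguishes converged from divergent chains", {
  x <- rnorm(5000)
  expect_equal(as.numeric(gelman_rubin(list(x, x))), 1, tolerance = 1e-9)
  set.seed(75)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_lt(as.numeric(gelman_rubin(list(a, b))), 1.01)
  expect_gt(as.numeric(gelman_rubin(list(a, b + 10))), 1.5)
  # agreement with the reference implementation
  if (requireNamespace("coda", quietly = TRUE)) {
    ml <- coda::mcmc.list(coda::mcmc(a), coda::mcmc(b))
    ref <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
    expect_equal(as.numeric(gelman_rubin(list(a, b))), ref,
                 tolerance = 0.01)
  }
  const <- rep(1, 100)
  gr <- gelman_rubin(list(const, const))
  expect_equal(as.numeric(gr), 1)
  expect_true(attr(gr, "degenerate"))
})

test_that("effective_sample_size calibrates on iid and AR(1) traces", {
  set.seed(76)
  iid <- rnorm(2000)
  ess <- as.numeric(effective_sample_size(iid))
  expect_gt(ess, 1600)
  expect_lte(ess, 2400)
  # AR(1), rho = 0.9: ESS ~ n (1 - rho)/(1 + rho) ~ 105
  rho <- 0.9
  ar <- numeric(2000)
  for (i in 2:2000) ar[i] <- rho * ar[i - 1] + rnorm(1)
  ess_ar <- as.numeric(effective_sample_size(ar))
  target <- 2000 * (1 - rho) / (1 + rho)
  expect_gt(ess_ar, target / 2)
  expect_lt(ess_ar, target * 2)
  # anti-correlated trace is capped at n, not inflated beyond it
  alt <- rep(c(-1, 1), 10)
  ess_alt <- as.numeric(effective_sample_size(alt))
  expect_lte(ess_alt, 20)
  # constant trace flagged degenerate
  ess_const <- effective_sample_size(rep(2, 50))
  expect_true(attr(ess_const, "degenerate"))
  expect_error(effective_sample_size(1:5), "short")
})

test_that("fixed-dimension theta sampling matches the conjugate posterior", {
  # K fixed at 1 (birth/death/relocate disabled), alpha and sigma2 fixed:
  # the shift optimum has a conjugate normal posterior we can compute
  tr <- random_yule(5, depth = 10, seed = 77)
  sim_edge <- which(tr$edge[, 2] > ape::Ntip(tr))[1]
  m <- two_regime_map(tr, sim_edge, shift_frac = 0.5)
  y <- simulate_trait(m, simulation_recipe(n_tips = 5,
                                           states = c("bg", "fg"),
                                           trait_model = "OUM", alpha = 0.3,
                                           sigma2 = 20,
                                           theta = c(bg = 0, fg = 30)),
                      seed = 78)
  # run with only theta moves, from a fixed 1-shift state
  hyper <- rjmcmc_hyperprior(tr, y)
  run <- run_rjmcmc(tr, y, n_gens = 4e4, thin = 4, n_chains = 2, seed = 79,
                    hyper = hyper,
                    move_weights = c(birth = 0, death = 0, relocate = 0,
                                     theta = 1, alpha = 0, sigma2 = 0))
  # with birth disabled the chain stays at K = 0; theta0 then has a
  # conjugate normal posterior under the OU covariance
  cache <- ssdevol:::ou_cache(tr)
  a0 <- exp(hyper$alpha_meanlog); s20 <- exp(hyper$sigma2_meanlog)
  V <- s20 * ssdevol:::ou_corr_from_cache(cache, a0)
  W <- rep(1, 5)   # single-regime weights
  Vi <- solve(V)
  prec <- sum(W * (Vi %*% W)) + 1 / hyper$theta_sd^2
  mean_post <- (sum(W * (Vi %*% y[cache$tip_labels])) +
                  hyper$theta_mean / hyper$theta_sd^2) / prec
  draws <- c(run$chains[[1]]$theta0, run$chains[[2]]$theta0)
  draws <- draws[-(1:2000)]
  expect_equal(mean(draws), mean_post, tolerance = 4 / sqrt(prec))
  ks <- suppressWarnings(ks.test(draws[seq(1, length(draws), by = 10)],
                                 "pnorm", mean_post, sqrt(1 / prec)))
  expect_gt(ks$p.value, 0.01)
})
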