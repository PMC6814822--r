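test_that("OU weight matrix rows sum to 1 and respect limits", {
  tr <- random_yule(20, depth = 10, seed = 41)
  sim <- simulate_regimes(tr, er_Q(0.1, c("A", "B", "C")), "A", seed = 42)
  for (a in c(0, 1e-4, 0.1, 2, 50)) {
    W <- ou_weight_matrix(sim$map, a)
    expect_equal(unname(rowSums(W)), rep(1, 20), tolerance = 1e-12)
    expect_gte(min(W), -1e-12)
  }
  # single-regime map: all weight on that regime
  mono <- make_simmap_tree(tr, lapply(tr$edge.length, function(l) c(A = l)))
  W1 <- ou_weight_matrix(mono, 0.5)
  expect_equal(unname(W1[, "A"]), rep(1, 20))
  # strong attraction: weight concentrates on each tip's terminal regime
  Wbig <- ou_weight_matrix(sim$map, 1000 / 10)
  term <- simmap_tip_states(sim$map)
  for (i in seq_len(20))
    expect_gte(Wbig[i, term[tr$tip.label[i]]], 0.999)
})

test_that("OU weights match fine-grained quadrature on a 3-segment history", {
  tr <- read_tree(text = "(A:1,B:1);")
  maps <- list(c(r1 = 0.3, r2 = 0.45, r1 = 0.25), c(r1 = 1))
  m <- make_simmap_tree(tr, maps, states = c("r1", "r2"))
  alpha <- 1.3
  W <- ou_weight_matrix(m, alpha)
  # quadrature: weight_r = int_0^T alpha exp(-alpha (T - s)) 1[regime(s) = r] ds
  ss <- seq(0, 1, length.out = 1e5 + 1)[-1] - 0.5e-5
  regime <- ifelse(ss < 0.3 | ss >= 0.75, "r1", "r2")
  wq <- alpha * exp(-alpha * (1 - ss)) * 1e-5
  quad_r1 <- sum(wq[regime == "r1"]) + exp(-alpha)  # root mass to r1
  quad_r2 <- sum(wq[regime == "r2"])
  expect_equal(W["A", "r1"], quad_r1, tolerance = 1e-6)
  expect_equal(W["A", "r2"], quad_r2, tolerance = 1e-6)
})

test_that("ou_vcv matches closed forms and the Brownian limit", {
  tr <- random_yule(10, depth = 10, seed = 43)
  C <- phylo_vcv(tr)
  V0 <- ou_vcv(tr, 1e-12, 3.5)
  expect_lt(max(abs(V0 - 3.5 * C)) / max(abs(3.5 * C)), 1e-6)

  st <- star_tree(2, depth = 7)
  V <- ou_vcv(st, 0.4, 2)
  expect_equal(unname(diag(V)),
               rep(2 / (2 * 0.4) * (1 - exp(-2 * 0.4 * 7)), 2))
  expect_equal(V[1, 2], 0)
})

test_that("OU covariance matches Euler-Maruyama simulation moments", {
  tr <- read_tree(text = "((A:3,B:3):2,(C:4,D:4):1);")
  alpha <- 0.2; sigma2 <- 10
  V <- ou_vcv(tr, alpha, sigma2)
  set.seed(44)
  nsim <- 2e4
  dt <- 5 / 2000
  # simulate along the tree, sharing the path down to each split
  sim_edge <- function(x0, len) {
    nst <- round(len / dt)
    x <- x0
    for (s in seq_len(nst))
      x <- x - alpha * x * dt + sqrt(sigma2 * dt) * rnorm(nsim)
    x
  }
  root <- rep(0, nsim)
  n12 <- sim_edge(root, 2)
  a <- sim_edge(n12, 3); b <- sim_edge(n12, 3)
  n34 <- sim_edge(root, 1)
  cc <- sim_edge(n34, 4); d <- sim_edge(n34, 4)
  X <- cbind(A = a, B = b, C = cc, D = d)
  Vhat <- cov(X)
  se <- (diag(V) %o% diag(V))^0.5 / sqrt(nsim) * 2  # rough elementwise SE
  expect_true(all(abs(Vhat - V) < 3 * se + 0.05))
})

test_that("model likelihoods match a generic MVN oracle on small trees", {
  # OU1 and BM1 on a 5-tip instance
  tr <- random_yule(5, depth = 8, seed = 45)
  y <- setNames(c(10, 35, 22, 5, 28), tr$tip.label)
  for (model in c("OU1", "BM1")) {
    fit <- fit_model(model, tr, y)
    cache <- ssdevol:::ou_cache_for_model(model, tr)
    mc <- ssdevol:::ou_mean_cov(fit, cache)
    expect_equal(fit$lnL,
                 as.numeric(mvn_logdens_oracle(y[cache$tip_labels],
                                               mc$mean, mc$cov)),
                 tolerance = 1e-8)
  }
  # two-regime OUM needs a few more tips for AICc to exist
  tr2 <- random_yule(10, depth = 8, seed = 46)
  sim <- simulate_regimes(tr2, er_Q(0.15, c("A", "B")), "A", seed = 47)
  set.seed(48)
  y2 <- setNames(rnorm(10, 20, 10), tr2$tip.label)
  fit2 <- fit_model("OUM", sim$map, y2)
  cache2 <- ssdevol:::ou_cache(sim$map)
  mc2 <- ssdevol:::ou_mean_cov(fit2, cache2)
  expect_equal(fit2$lnL,
               as.numeric(mvn_logdens_oracle(y2[cache2$tip_labels],
                                             mc2$mean, mc2$cov)),
               tolerance = 1e-8)
})

test_that("model classes collapse into each other at their boundaries", {
  tr <- random_yule(30, depth = 10, seed = 47)
  set.seed(48)
  y <- setNames(rnorm(30, 20, 8), tr$tip.label)
  # OUM on a single-regime map equals OU1
  mono <- make_simmap_tree(tr, lapply(tr$edge.length, function(l) c(A = l)))
  f_oum <- fit_model("OUM", mono, y)
  f_ou1 <- fit_model("OU1", tr, y)
  expect_equal(f_oum$lnL, f_ou1$lnL, tolerance = 1e-6)
  # BM1 equals OU1 evaluated at alpha ~ 0 with matched sigma2 and mean
  bm <- fit_model("BM1", tr, y)
  cache <- ssdevol:::ou_cache_for_model("OU1", tr)
  ev <- ssdevol:::ou_profile_eval(cache, 1e-12,
                                  y[cache$tip_labels], 1L)
  expect_equal(bm$lnL, ev$lnL, tolerance = 1e-4)
})

test_that("fitting is invariant to tip order and location shifts", {
  tr <- random_yule(25, depth = 10, seed = 49)
  sim <- simulate_regimes(tr, er_Q(0.08, c("A", "B")), "A", seed = 50)
  y <- simulate_trait(sim$map,
                      simulation_recipe(n_tips = 25, states = c("A", "B"),
                                        trait_model = "OUM", alpha = 0.2,
                                        sigma2 = 20,
                                        theta = c(A = 10, B = 40)),
                      seed = 51)
  f1 <- fit_model("OUM", sim$map, y)
  f2 <- fit_model("OUM", sim$map, y[rev(names(y))])
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-8)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
  # location shift moves theta by the shift, lnL unchanged
  f3 <- fit_model("OUM", sim$map, y + 100)
  expect_equal(f3$lnL, f1$lnL, tolerance = 1e-6)
  expect_equal(unname(f3$theta - f1$theta), rep(100, 2), tolerance = 1e-4)
})

test_that("AICc and weights follow their definitions", {
  expect_equal(aicc(-100, 3, 166), 200 + 6 + 24 / 162)
  expect_error(aicc(-100, 3, 4), "undefined")
  expect_equal(aicc_weights(c(10, 10, 10)), rep(1 / 3, 3))
  set.seed(52)
  w <- aicc_weights(runif(7, 100, 140))
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
})

test_that("half_life follows ln(2)/alpha", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(2 * log(2)), 0.5)
  expect_equal(half_life(0), Inf)
  set.seed(53)
  a <- exp(runif(20, -5, 3))
  expect_equal(half_life(a) * a, rep(log(2), 20))
})

test_that("Brownian ancestral states are exact in degenerate and small cases", {
  tr <- random_yule(12, depth = 10, seed = 54)
  const <- setNames(rep(7.5, 12), tr$tip.label)
  anc <- bm_ancestral_states(tr, const)
  expect_equal(anc$estimate, rep(7.5, nrow(anc)), tolerance = 1e-10)

  set.seed(55)
  y <- setNames(rnorm(12, 10, 5), tr$tip.label)
  anc2 <- bm_ancestral_states(tr, y)
  # root estimate equals the GLS phylogenetic mean
  C <- phylo_vcv(tr)
  one <- rep(1, 12)
  mu <- sum(solve(C, y[tr$tip.label])) / sum(solve(C, one))
  expect_equal(anc2$estimate[anc2$node == 13], mu, tolerance = 1e-10)
  # matches the reference ML reconstruction
  ref <- ape::ace(y[tr$tip.label], tr, method = "ML")
  expect_equal(anc2$estimate, unname(ref$ace), tolerance = 1e-4)

  # 3-tip brute force: grid over the two internal values
  tr3 <- cherry3()
  y3 <- setNames(c(1, 3, 10), c("A", "B", "C"))
  anc3 <- bm_ancestral_states(tr3, y3)
  # joint Brownian density maximized over (root, internal) by optim
  nll <- function(par) {
    root <- par[1]; v <- par[2]
    # edges: root->v (1), v->A (1), v->B (1), root->C (2); unit rate
    -sum(dnorm(c(v - root, y3["A"] - v, y3["B"] - v, y3["C"] - root),
               0, sqrt(c(1, 1, 1, 2)), log = TRUE))
  }
  opt <- optim(c(5, 5), nll)
  expect_equal(sort(anc3$estimate), sort(opt$par), tolerance = 1e-3)
})
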