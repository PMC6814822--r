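test_that("perfect linear data give exact slopes", {
  tr <- random_yule(15, depth = 10, seed = 3)
  x <- setNames(rnorm(15, 8, 1), tr$tip.label)
  f1 <- fit_phylo_rma(tr, x, x)
  expect_equal(f1$slope, 1, tolerance = 1e-8)
  expect_equal(f1$r2, 1, tolerance = 1e-8)
  expect_equal(f1$intercept, 0, tolerance = 1e-6)
  f2 <- fit_phylo_rma(tr, x, 2 * x)
  expect_equal(f2$slope, 2, tolerance = 1e-8)
})

test_that("slope is scale-equivariant and inverts under x-y swap", {
  tr <- random_yule(30, depth = 10, seed = 4)
  set.seed(5)
  x <- setNames(rnorm(30, 8, 0.8), tr$tip.label)
  y <- setNames(1.1 * x + rnorm(30, 0, 0.3), tr$tip.label)
  base <- fit_phylo_rma(tr, x, y)
  for (k in c(0.5, 2, 10)) {
    fk <- fit_phylo_rma(tr, x, k * y)
    expect_equal(fk$slope, k * base$slope, tolerance = 1e-8)
  }
  swapped <- fit_phylo_rma(tr, y, x)
  expect_equal(swapped$slope, 1 / base$slope, tolerance = 1e-8)
})

test_that("lambda = 0 fit equals the flat-covariance oracle", {
  tr <- random_yule(40, depth = 10, seed = 6)
  set.seed(7)
  x <- setNames(rnorm(40), tr$tip.label)
  y <- setNames(0.9 * x + rnorm(40, 0, 0.5), tr$tip.label)
  fit <- fit_phylo_rma(tr, x, y, lambda = 0)
  oracle <- flat_rma_oracle(x[tr$tip.label], y[tr$tip.label])
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-8)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-8)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-8)
})

test_that("star-tree fit agrees with the non-phylogenetic oracle at scale", {
  st <- star_tree(500)
  set.seed(8)
  x <- setNames(rnorm(500, 8, 1), st$tip.label)
  y <- setNames(1.05 * x + rnorm(500, 0, 0.4), st$tip.label)
  fit <- fit_phylo_rma(st, x, y)
  oracle <- flat_rma_oracle(x[st$tip.label], y[st$tip.label])
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-6)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-6)
})

test_that("fit matches the reference phylogenetic RMA implementation", {
  tr <- random_yule(60, depth = 20, seed = 9)
  set.seed(10)
  C <- phylo_vcv(tr)
  L <- chol(lambda_transform(C, 0.7))
  x <- setNames(8 + as.vector(crossprod(L, rnorm(60))) * 0.1, tr$tip.label)
  y <- setNames(0.3 + 1.02 * x +
                  as.vector(crossprod(L, rnorm(60))) * 0.03, tr$tip.label)
  ours <- test_slope(fit_phylo_rma(tr, x, y))
  ref <- phytools::phyl.RMA(x, y, tr, method = "lambda")
  expect_equal(ours$slope, unname(ref$RMA.beta[2]), tolerance = 1e-4)
  expect_equal(ours$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(ours$r2, unname(ref$test["r2"]), tolerance = 1e-4)
  expect_equal(ours$T, unname(ref$test["T"]), tolerance = 1e-3)
  expect_equal(ours$df, unname(ref$test["df"]), tolerance = 1e-3)
  expect_equal(ours$P, unname(ref$test["P"]), tolerance = 1e-3)
})

test_that("slope test handles the exact null and classifies Rensch trends", {
  res <- structure(list(slope = 1, r2 = 0.9, n = 50, clade = "x"),
                   class = "rma_result")
  tested <- test_slope(res)
  expect_equal(tested$T, 0)
  expect_equal(tested$P, 1)
  expect_equal(classify_rensch(tested), "none")

  # strong positive allometry with small SE is significant
  res2 <- structure(list(slope = 1.10, r2 = 0.97, n = 33, clade = "x"),
                    class = "rma_result")
  t2 <- test_slope(res2)
  expect_lt(t2$P, 0.05)
  expect_equal(classify_rensch(t2), "positive")

  res3 <- structure(list(slope = 0.83, r2 = 0.97, n = 9, clade = "x"),
                    class = "rma_result")
  t3 <- test_slope(res3)
  expect_lt(t3$P, 0.05)
  expect_equal(classify_rensch(t3), "negative")

  # effective df is non-integer, about 0.68 n at high r2
  expect_equal(t2$df, 2 + 31 / (1 + 0.97 / 2))
  neg <- structure(list(slope = -0.5, r2 = 0.5, n = 20, clade = "x"),
                   class = "rma_result")
  expect_error(test_slope(neg), "non-positive")
})

test_that("rma_by_clade returns per-clade and global fits", {
  tr <- random_yule(24, depth = 10, seed = 11)
  set.seed(12)
  x <- setNames(rnorm(24, 8, 1), tr$tip.label)
  y <- setNames(x, tr$tip.label)   # exact y = x in every clade
  clades <- setNames(rep(c("c1", "c2"), each = 12), tr$tip.label)
  tab <- rma_by_clade(tr, x, y, clades)
  expect_equal(tab$clade, c("all", "c1", "c2"))
  expect_equal(tab$slope, rep(1, 3), tolerance = 1e-6)

  # singleton clade skipped with a warning; others still fit
  clades2 <- clades
  clades2[1] <- "singleton"
  expect_warning(tab2 <- rma_by_clade(tr, x, y, clades2),
                 "fewer than 3")
  expect_false("singleton" %in% tab2$clade)

  # single clade equals the global fit
  one <- setNames(rep("only", 24), tr$tip.label)
  tab3 <- rma_by_clade(tr, x, y, one)
  expect_equal(tab3$slope[tab3$clade == "only"],
               tab3$slope[tab3$clade == "all"], tolerance = 1e-10)
})

test_that("lambda is recovered across its range", {
  # moderate version of the recovery experiment (the acceptance suite
  # runs the full 50-replicate design)
  for (lam_true in c(0, 1)) {
    tr <- random_yule(150, depth = 10, seed = 40 + lam_true)
    C <- lambda_transform(phylo_vcv(tr), lam_true)
    L <- chol(C + diag(1e-10, 150))
    set.seed(50 + lam_true)
    lams <- replicate(10, {
      x <- as.vector(crossprod(L, rnorm(150)))
      y <- x + as.vector(crossprod(L, rnorm(150)))
      names(x) <- names(y) <- tr$tip.label
      fit_phylo_rma(tr, x, y)$lambda
    })
    expect_lt(abs(mean(lams) - lam_true), 0.1)
  }
})
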