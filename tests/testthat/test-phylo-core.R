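test_that("read_tree parses well-formed trees and preserves branch lengths", {
  t1 <- read_tree(text = "(A:1,B:1);")
  expect_s3_class(t1, "phylo")
  expect_equal(ape::Ntip(t1), 2L)
  expect_equal(tree_depth(t1), 1)

  t2 <- read_tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(t2), 3L)
  expect_true(is_ultrametric_tree(t2))
  expect_equal(tree_depth(t2), 2)

  t3 <- read_tree(text = "(A:1.23456789012345,B:1.23456789012345);")
  expect_equal(t3$edge.length, rep(1.23456789012345, 2))
})

test_that("read_tree rejects malformed input", {
  expect_error(read_tree(text = "(A:1,B);"), "branch length")
  expect_error(read_tree(text = "(A:1,B:1"), "parse|semicolon")
  expect_error(read_tree(text = "(A:1,A:1);"), "duplicate")
  expect_error(read_tree(text = "(A:1,B:-1);"), "negative")
})

test_that("read_tree reads NEXUS", {
  nex <- c("#NEXUS", "BEGIN TREES;",
           "TREE t1 = ((A:1,B:1):1,C:2);", "END;")
  tr <- read_tree(text = paste(nex, collapse = "\n"), format = "nexus")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tree_depth(tr), 2)
})

test_that("phylo_vcv matches closed forms and the edge-enumeration oracle", {
  st <- star_tree(3, depth = 5)
  C <- phylo_vcv(st)
  expect_equal(unname(diag(C)), rep(5, 3))
  expect_equal(max(abs(C[upper.tri(C)])), 0)

  C2 <- phylo_vcv(cherry3())
  expect_equal(C2["A", "B"], 1)
  expect_equal(C2["A", "C"], 0)
  expect_equal(unname(diag(C2)), rep(2, 3))

  tr <- random_yule(20, depth = 12, seed = 101)
  expect_matrix_equal(phylo_vcv(tr), vcv_oracle(tr), tol = 1e-10)
})

test_that("phylo_vcv is symmetric PSD with depth diagonal on random trees", {
  for (s in 1:20) {
    tr <- random_yule(sample(5:40, 1), depth = runif(1, 1, 100), seed = s)
    C <- phylo_vcv(tr)
    expect_equal(C, t(C))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    expect_lt(diff(range(diag(C))), 1e-9 * max(diag(C)))
  }
})

test_that("lambda_transform scales off-diagonals only", {
  C <- phylo_vcv(cherry3())
  expect_equal(lambda_transform(C, 1), C)
  C0 <- lambda_transform(C, 0)
  expect_equal(max(abs(C0[upper.tri(C0)])), 0)
  expect_equal(diag(C0), diag(C))
  expect_equal(lambda_transform(C, 0.5)["A", "B"], 0.5)
  expect_error(lambda_transform(C, 1.5), "\\[0, 1\\]")
  expect_error(lambda_transform(C, -0.1), "\\[0, 1\\]")
  expect_equal(lambda_transform(C, 1.5, allow_above_one = TRUE)["A", "B"],
               1.5)
})

test_that("prune_to_taxa preserves depths and patristic distances", {
  tr <- cherry3()
  sub <- prune_to_taxa(tr, c("A", "B"))
  expect_equal(sort(sub$tip.label), c("A", "B"))
  expect_equal(unname(diag(phylo_vcv(sub))), rep(2, 2))

  expect_equal(ape::Ntip(prune_to_taxa(tr, tr$tip.label)), 3L)
  expect_error(prune_to_taxa(tr, c("X", "Y")), "none of")

  big <- random_yule(20, depth = 30, seed = 7)
  keep <- sample(big$tip.label, 8)
  sub2 <- prune_to_taxa(big, keep)
  d_full <- ape::cophenetic.phylo(big)[keep, keep]
  d_sub <- ape::cophenetic.phylo(sub2)[keep, keep]
  expect_matrix_equal(d_sub, d_full, tol = 1e-9)
  expect_setequal(attr(sub2, "dropped"), setdiff(big$tip.label, keep))
})

test_that("simmap text round trip is the identity on segments", {
  tr <- read_tree(text = "(A:1,B:1);")
  m <- make_simmap_tree(tr, list(c(s1 = 0.5, s2 = 0.5), c(s1 = 1)))
  txt <- write_simmap(m)
  back <- read_simmap(text = txt)
  expect_equal(back$maps[[1]], c(s1 = 0.5, s2 = 0.5), tolerance = 1e-9)

  rec <- simulation_recipe(n_tips = 50, depth = 20,
                           Q = er_Q(0.05, c("A", "B")))
  tree <- simulate_tree(rec, seed = 5)
  sim <- simulate_regimes(tree, rec$Q, "A", seed = 6)
  txt2 <- write_simmap(sim$map)
  back2 <- read_simmap(text = txt2)
  for (e in seq_along(sim$map$maps)) {
    expect_equal(names(back2$maps[[e]]), names(sim$map$maps[[e]]))
    expect_lt(max(abs(back2$maps[[e]] - sim$map$maps[[e]])) /
                max(tree$edge.length), 1e-9)
  }
})

test_that("simmap validation rejects broken maps", {
  tr <- read_tree(text = "(A:1,B:1);")
  # durations not summing to the branch length
  expect_error(make_simmap_tree(tr, list(c(s1 = 0.4), c(s1 = 1))),
               "durations sum")
  # history discontinuity: parent branch ends in s1, child starts in s2
  tr2 <- cherry3()
  expect_error(
    make_simmap_tree(tr2, list(c(s1 = 1), c(s2 = 1), c(s1 = 1), c(s1 = 2))),
    "discontinuity")
  # state outside the declared alphabet
  expect_error(
    make_simmap_tree(tr, list(c(s1 = 1), c(s9 = 1)), states = "s1"),
    "alphabet")
  # in the text dialect the branch length IS the segment sum, so the
  # readable inconsistency is a history discontinuity at the root
  expect_error(read_simmap(text = "(A:{s1,1},B:{s2,1});"),
               "discontinuity")
})

test_that("simmap continuity holds after simulation and sampling", {
  rec <- simulation_recipe(n_tips = 25, depth = 15,
                           Q = er_Q(0.08, c("A", "B", "C")),
                           states = c("A", "B", "C"))
  tree <- simulate_tree(rec, seed = 11)
  sim <- simulate_regimes(tree, rec$Q, "A", seed = 12)
  expect_silent(validate_simmap(sim$map))
  mk <- mk_model(c("A", "B", "C"), er_Q(0.08, c("A", "B", "C")))
  maps <- sample_simmaps(tree, mk, sim$tip_states, n_maps = 5, seed = 13)
  for (m in maps) expect_silent(validate_simmap(m))
})
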