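test_that("tree-aware integration solves hand-checkable instances", {
  triv <- solve_pcti(clone_tree(vertices = "1"), make_U(1, "1"),
                     clone_tree(vertices = "1"), make_U(1, "1"))
  expect_equal(triv$clones, "1|1")
  expect_equal(triv$total_correction, 0, tolerance = 1e-9)

  # only the feature-2-first chain is consistent with the 0.3/0.7 split
  T1 <- chain_tree(1:2); T2 <- chain_tree(1:2)
  U1 <- make_U(c(0.5, 0.5), c("1", "2"))
  U2 <- make_U(c(0.3, 0.7), c("1", "2"))
  sol <- solve_pcti(T1, U1, T2, U2)
  expect_equal(sol$total_correction, 0, tolerance = 1e-9)
  expect_equal(tree_key(sol$tree),
               tree_key(clone_tree(rbind(c("1|1", "1|2"), c("1|2", "2|2")))))
  expect_equal(unname(sol$proportions[1, c("1|1", "1|2", "2|2")]),
               c(0.3, 0.2, 0.5), tolerance = 1e-6)

  # two samples pulling in different directions: J = 0.4, two co-optima
  U1m <- make_U(c(0.5, 0.5, 0.2, 0.8), c("1", "2"))
  U2m <- make_U(c(0.3, 0.7, 0.9, 0.1), c("1", "2"))
  solm <- solve_pcti(T1, U1m, T2, U2m)
  expect_equal(solm$total_correction, 0.4, tolerance = 1e-6)
  expect_equal(solm$n_optimal_supports, 2L)
})

test_that("solver matches the enumerate-and-score oracle on random instances", {
  withr::local_seed(61)
  for (rep in 1:15) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1); m <- sample(1:3, 1)
    h <- sample(c(0, 0.1, 0.3), 1)
    b <- simulate_instance(simulation_config(n1, n2, m = m, h = h,
                                             seed = sample.int(1e6, 1)))
    sol <- solve_pcti(b$inputs$tree1, b$inputs$props1,
                      b$inputs$tree2, b$inputs$props2)
    bf <- pcti_brute_force(b$inputs$tree1, b$inputs$props1,
                           b$inputs$tree2, b$inputs$props2)
    expect_equal(sol$total_correction, bf$J, tolerance = 1e-5)
  }
})

test_that("solutions satisfy the structural refinement laws", {
  withr::local_seed(67)
  for (rep in 1:10) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    b <- simulate_instance(simulation_config(n1, n2, m = 2, h = 0.1,
                                             seed = sample.int(1e6, 1)))
    sol <- solve_pcti(b$inputs$tree1, b$inputs$props1,
                      b$inputs$tree2, b$inputs$props2)
    # root pairing, single-coordinate changes, vertex count n1 + n2 - 1
    expect_equal(sol$tree$root, paired_label(b$inputs$tree1$root,
                                             b$inputs$tree2$root))
    expect_length(sol$clones, n1 + n2 - 1)
    expect_true(check_refinement(sol$tree, b$inputs$tree1,
                                 b$inputs$tree2)$pass)
    expect_equal(consistency_error(sol$proportions, b$inputs$props1,
                                   b$inputs$props2),
                 sol$total_correction, tolerance = 1e-5)
  }
})

test_that("the correction is invariant under relabeling and sample order", {
  b <- simulate_instance(simulation_config(3, 3, m = 3, h = 0.2, seed = 17))
  sol <- solve_pcti(b$inputs$tree1, b$inputs$props1,
                    b$inputs$tree2, b$inputs$props2)

  relab <- c("1" = "x", "2" = "y", "3" = "z")
  U1r <- b$inputs$props1
  colnames(U1r) <- relab[colnames(U1r)]
  T1r <- clone_tree(matrix(relab[b$inputs$tree1$edges], ncol = 2))
  solr <- solve_pcti(T1r, U1r, b$inputs$tree2, b$inputs$props2)
  expect_equal(solr$total_correction, sol$total_correction,
               tolerance = 1e-6)

  perm <- c(3, 1, 2)
  solp <- solve_pcti(b$inputs$tree1, b$inputs$props1[perm, ],
                     b$inputs$tree2, b$inputs$props2[perm, ])
  expect_equal(solp$total_correction, sol$total_correction,
               tolerance = 1e-6)
})

test_that("noise-free instances integrate with zero correction", {
  withr::local_seed(71)
  for (rep in 1:5) {
    b <- simulate_instance(simulation_config(sample(2:4, 1), sample(2:4, 1),
                                             m = sample(1:5, 1), h = 0,
                                             seed = sample.int(1e6, 1)))
    sol <- solve_pcti(b$inputs$tree1, b$inputs$props1,
                      b$inputs$tree2, b$inputs$props2)
    expect_equal(sol$total_correction, 0, tolerance = 1e-8)
  }
})

test_that("candidate-tree selection recovers the generating tree", {
  b <- simulate_instance(simulation_config(3, 3, m = 5, h = 0, seed = 29))
  T1 <- b$inputs$tree1; T2 <- b$inputs$tree2
  U1 <- b$inputs$props1; U2 <- b$inputs$props2

  one <- select_best_input_tree(list(T2), T1, U1, U2)
  expect_equal(one$best_index, 1L)

  # truth admits J = 0; a rewired candidate generally does not
  cands <- enumerate_candidate_trees(T2$vertices, T2$root)
  pick <- select_best_input_tree(cands, T1, U1, U2)
  expect_equal(pick$solution$total_correction, 0, tolerance = 1e-8)
  expect_true(tree_key(T2) %in%
                vapply(cands[pick$ties], tree_key, ""))
  expect_error(select_best_input_tree(list(), T1, U1, U2), "empty")
})

test_that("candidate enumeration follows the labeled-tree count", {
  expect_length(enumerate_candidate_trees("a", "a"), 1L)
  expect_length(enumerate_candidate_trees(c("a", "b"), "a"), 1L)
  t3 <- enumerate_candidate_trees(c("a", "b", "c"), "a")
  expect_length(t3, 3L)   # 3^(3-2)
  t4 <- enumerate_candidate_trees(as.character(1:4), "1")
  expect_length(t4, 16L)  # 4^(4-2)
  expect_false(anyDuplicated(vapply(t4, tree_key, "")) > 0)
  for (tr in t4) expect_equal(tr$root, "1")

  expect_error(enumerate_candidate_trees(as.character(1:7), "1", cap = 100),
               "cap")
  expect_warning(
    tt <- enumerate_candidate_trees(as.character(1:7), "1", cap = 100,
                                    truncate = TRUE),
    "truncating")
  expect_length(tt, 100L)
})
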