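test_that("random clone trees have the forced structure at tiny sizes", {
  withr::local_seed(73)
  expect_equal(simulate_clone_tree(1, 1)$vertices, "1|1")
  t21 <- simulate_clone_tree(2, 1)
  expect_equal(tree_key(t21), tree_key(clone_tree(rbind(c("1|1", "2|1")))))

  for (rep in 1:20) {
    tr <- simulate_clone_tree(3, 3)
    expect_length(tr$vertices, 5L)
    expect_equal(nrow(tr$edges), 4L)
    expect_false(anyDuplicated(tr$vertices) > 0)
    # two feature-1 and two feature-2 events
    T1 <- collapse_to_feature_tree(tr, 1)
    T2 <- collapse_to_feature_tree(tr, 2)
    expect_length(T1$vertices, 3L)
    expect_length(T2$vertices, 3L)
    expect_true(check_refinement(tr, T1, T2)$pass)
  }
})

test_that("collapsing contracts the other feature's events", {
  chain <- clone_tree(rbind(c("1|1", "1|2"), c("1|2", "2|2")))
  expect_equal(tree_key(collapse_to_feature_tree(chain, 1)),
               tree_key(chain_tree(1:2)))
  expect_equal(tree_key(collapse_to_feature_tree(chain, 2)),
               tree_key(chain_tree(1:2)))

  single <- clone_tree(rbind(c("1|1", "2|1")))
  expect_equal(tree_key(collapse_to_feature_tree(single, 1)),
               tree_key(chain_tree(1:2)))
  expect_equal(collapse_to_feature_tree(single, 2)$vertices, "1")

  branchy <- clone_tree(rbind(c("1|1", "2|1"), c("1|1", "1|2")))
  expect_equal(tree_key(collapse_to_feature_tree(branchy, 2)),
               tree_key(chain_tree(1:2)))
})

test_that("proportions are Dirichlet rows on the simplex", {
  withr::local_seed(79)
  expect_equal(unname(simulate_proportions("1|1", m = 3)[, 1]), rep(1, 3))
  U <- simulate_proportions(paste0("c", 1:4), m = 10000)
  expect_equal(unname(rowSums(U)), rep(1, 10000), tolerance = 1e-9)
  # symmetric Dirichlet(1) mean is 1/4; SE of the mean ~ sqrt(3/80)/100
  se <- sqrt(3 / 80) / sqrt(10000)
  expect_true(all(abs(colMeans(U) - 0.25) < 3 * se))
})

test_that("noise is a convex mixture fixing the simplex", {
  withr::local_seed(83)
  U <- simulate_proportions(paste0("c", 1:3), m = 4)
  expect_identical(add_noise(U, 0), U)
  noisy <- add_noise(U, 0.3)
  expect_equal(unname(rowSums(noisy)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(noisy >= 0))
  # h bounds the per-row displacement: |(1-h)u + hd - u| <= 2h
  expect_true(all(rowSums(abs(noisy - U)) <= 2 * 0.3 + 1e-12))
})

test_that("bundles are reproducible and exactly consistent at h = 0", {
  cfg <- simulation_config(3, 4, m = 3, h = 0, seed = 123)
  b1 <- simulate_instance(cfg)
  b2 <- simulate_instance(cfg)
  expect_identical(b1, b2)

  expect_length(b1$truth$clones, 3 + 4 - 1)
  expect_equal(project_proportions(b1$truth$proportions, 1,
                                   colnames(b1$inputs$props1)),
               b1$inputs$props1)
  expect_equal(project_proportions(b1$truth$proportions, 2,
                                   colnames(b1$inputs$props2)),
               b1$inputs$props2)
  expect_equal(consistency_error(b1$truth$proportions, b1$inputs$props1,
                                 b1$inputs$props2), 0)
})

test_that("input deviation from the truth grows with the noise level", {
  withr::local_seed(89)
  hs <- c(0, 0.05, 0.1, 0.15)
  avg <- vapply(hs, function(h) {
    errs <- vapply(1:30, function(rep) {
      b <- simulate_instance(simulation_config(3, 3, m = 2, h = h,
                                               seed = sample.int(1e6, 1)))
      consistency_error(b$truth$proportions, b$inputs$props1,
                        b$inputs$props2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(avg) >= 0))
  expect_equal(avg[1], 0)
})

test_that("3-partition containers validate their invariants", {
  expect_error(three_partition_instance(c(10, 15, 15), 40), "strictly inside")
  expect_error(three_partition_instance(c(11, 14, 16), 40), "sum to B")
  expect_error(three_partition_instance(c(11, 14, 15, 12, 13, 15), 40,
                                        known_partition = c(1, 1, 2, 2, 1, 2)),
               "sum to B")
  inst <- three_partition_instance(c(11, 14, 15, 12, 13, 15), 40)
  expect_equal(inst$q, 2L)
})

test_that("tree-aware reductions add a zero-proportion root and stars", {
  inst <- three_partition_instance(c(11, 14, 15, 12, 13, 15), 40)
  red <- reduce_3partition_to_pcti(inst)
  expect_equal(unname(red$U1[1, ]),
               c(0, 0.1375, 0.175, 0.1875, 0.15, 0.1625, 0.1875))
  expect_equal(unname(red$U2[1, ]), c(0, 0.5, 0.5))
  expect_equal(red$T1$root, "0")
  expect_equal(red$T2$root, "0")
  expect_true(all(red$T1$edges[, 1] == "0"))
  expect_equal(nrow(red$T1$edges), 6L)
  expect_equal(nrow(red$T2$edges), 2L)
  expect_equal(sum(red$U1), 1)
  expect_equal(sum(red$U2), 1)
})
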