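test_that("greedy trivial solution reproduces hand-executed updates", {
  g <- greedy_trivial_solution(make_U(1, "1"), make_U(1, "1"))
  expect_equal(unname(g$proportions[1, "1|1"]), 1)

  U1 <- make_U(c(0.5, 0.5), c("1", "2"))
  g2 <- greedy_trivial_solution(U1, make_U(c(0.3, 0.7), c("1", "2")),
                                order = c("1|1", "1|2", "2|1", "2|2"))
  expect_equal(unname(g2$proportions[1, c("1|1", "1|2", "2|1", "2|2")]),
               c(0.3, 0.2, 0.0, 0.5))

  g3 <- greedy_trivial_solution(U1, make_U(c(0.5, 0.5), c("1", "2")),
                                order = c("1|2", "2|1", "1|1", "2|2"))
  expect_equal(unname(g3$proportions[1, c("1|2", "2|1", "1|1", "2|2")]),
               c(0.5, 0.5, 0, 0))

  expect_error(greedy_trivial_solution(U1, U1, order = c("1|1", "2|2")),
               "full product")
})

test_that("greedy solutions are consistent for random inputs and orders", {
  withr::local_seed(23)
  for (rep in 1:200) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1); m <- sample(1:3, 1)
    U1 <- rand_dirichlet_U(m, as.character(1:n1))
    U2 <- rand_dirichlet_U(m, as.character(1:n2))
    ord <- expand.grid(i = as.character(1:n1), j = as.character(1:n2),
                       stringsAsFactors = FALSE)
    ord <- ord[sample(nrow(ord)), ]
    g <- greedy_trivial_solution(U1, U2, order = paired_label(ord$i, ord$j))
    expect_equal(consistency_error(g$proportions, U1, U2), 0,
                 tolerance = 1e-12)
  }
})

test_that("fixed clone sets are tested for consistent proportions", {
  U1 <- make_U(c(0.5, 0.5), c("1", "2"))
  U2 <- make_U(c(0.6, 0.4), c("1", "2"))

  # the full product is always feasible
  full <- c("1|1", "1|2", "2|1", "2|2")
  expect_true(consistent_proportions_for_clone_set(full, U1, U2)$feasible)

  # max flow value 0.9 < 1
  expect_false(consistent_proportions_for_clone_set(c("1|1", "2|2"),
                                                    U1, U2)$feasible)

  # unique solution of the marginal equations
  fit <- consistent_proportions_for_clone_set(c("1|1", "2|1", "2|2"), U1, U2)
  expect_true(fit$feasible)
  expect_equal(unname(fit$proportions[1, c("1|1", "2|1", "2|2")]),
               c(0.5, 0.1, 0.4), tolerance = 1e-9)
  expect_equal(consistency_error(fit$proportions, U1, U2), 0,
               tolerance = 1e-9)
})

test_that("flow and LP feasibility agree for single-sample instances", {
  withr::local_seed(37)
  n_checked <- 0L
  for (rep in 1:100) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    U1 <- rand_dirichlet_U(1, as.character(1:n1))
    U2 <- rand_dirichlet_U(1, as.character(1:n2))
    pairs <- expand.grid(i = as.character(1:n1), j = as.character(1:n2),
                         stringsAsFactors = FALSE)
    keep <- sort(sample(nrow(pairs), sample(2:nrow(pairs), 1)))
    clones <- paired_label(pairs$i[keep], pairs$j[keep])
    f1 <- consistent_proportions_for_clone_set(clones, U1, U2,
                                               method = "flow")
    f2 <- consistent_proportions_for_clone_set(clones, U1, U2,
                                               method = "lp")
    expect_identical(f1$feasible, f2$feasible)
    if (f1$feasible) {
      expect_equal(consistency_error(f1$proportions, U1, U2), 0,
                   tolerance = 1e-6)
      expect_equal(consistency_error(f2$proportions, U1, U2), 0,
                   tolerance = 1e-6)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10L)  # both branches genuinely exercised
  expect_error(consistent_proportions_for_clone_set(
    "1|1", rand_dirichlet_U(2, "1"), rand_dirichlet_U(2, "1"),
    method = "flow"), "single sample")
})

test_that("multi-sample feasibility requires every sample to fit", {
  U1 <- make_U(c(0.5, 0.5, 0.2, 0.8), c("1", "2"))
  # the diagonal would force U1 == U2 in every sample
  U2 <- make_U(c(0.5, 0.5, 0.1, 0.9), c("1", "2"))
  expect_false(consistent_proportions_for_clone_set(c("1|1", "2|2"),
                                                    U1, U2)$feasible)
  # chain support works iff U2[p, 1] <= U1[p, 1] in every sample: here yes
  fit <- consistent_proportions_for_clone_set(c("1|1", "1|2", "2|2"), U1, U2)
  expect_true(fit$feasible)
  expect_equal(consistency_error(fit$proportions, U1, U2), 0,
               tolerance = 1e-6)
  # ... but not when sample 2 flips the inequality
  U2b <- make_U(c(0.5, 0.5, 0.3, 0.7), c("1", "2"))
  expect_false(consistent_proportions_for_clone_set(c("1|1", "1|2", "2|2"),
                                                    U1, U2b)$feasible)
})
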