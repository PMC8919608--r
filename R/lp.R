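# Small dense LPs for proportion correction, solved with the two-phase
# simplex method in boot::simplex. Problem sizes here are tiny (tens of
# variables), where a dense tableau is the right tool.

# Constraint matrices of the per-sample correction LP for a fixed clone
# set: minimize the L1 deviation of the marginals of u from the two target
# rows, subject to u >= 0 supported on the given pairs and sum(u) = 1.
# Variables are [u (k), corrections (n1 + n2)]; only the right-hand sides
# change across samples.
.correction_lp_matrices <- function(pairs, clones1, clones2) {
  k <- nrow(pairs)
  n1 <- length(clones1)
  n2 <- length(clones2)
  P1 <- matrix(0, n1, k)
  P1[cbind(match(pairs[, 1L], clones1), seq_len(k))] <- 1
  P2 <- matrix(0, n2, k)
  P2[cbind(match(pairs[, 2L], clones2), seq_len(k))] <- 1
  P <- rbind(P1, P2)
  nc <- n1 + n2
  list(k = k, nc = nc,
       obj = c(rep(0, k), rep(1, nc)),
       # marginal - correction <= target ; marginal + correction >= target
       A1 = cbind(P, -diag(nc)),
       A2 = cbind(P, diag(nc)),
       A3 = matrix(c(rep(1, k), rep(0, nc)), 1L))
}

.correction_lp_sample <- function(lp, a, b) {
  targ <- c(a, b)
  res <- boot::simplex(a = lp$obj, A1 = lp$A1, b1 = targ, A2 = lp$A2,
                       b2 = targ, A3 = lp$A3, b3 = 1, maxi = FALSE,
                       n.iter = 50L + 10L * (lp$k + lp$nc))
  if (res$solved == -1L) {
    stop("internal error: correction LP reported infeasible")
  }
  list(value = unname(res$value), u = unname(res$soln[seq_len(lp$k)]))
}

# Minimum total correction J over all proportion matrices supported on the
# given clone set, plus an attaining U. Decomposes per sample because each
# sample's proportions enter J independently. When the partial sum over
# samples already exceeds `cutoff`, scoring aborts and the partial J (a
# valid lower bound on the support's correction) is returned with
# `aborted = TRUE`.
.min_correction <- function(pairs, U1, U2, cutoff = Inf) {
  samples <- rownames(U1)
  U <- matrix(0, length(samples), nrow(pairs),
              dimnames = list(samples,
                              paired_label(pairs[, 1L], pairs[, 2L])))
  lp <- .correction_lp_matrices(pairs, colnames(U1), colnames(U2))
  J <- 0
  for (p in samples) {
    fit <- .correction_lp_sample(lp, U1[p, ], U2[p, ])
    J <- J + fit$value
    U[p, ] <- fit$u
    if (J > cutoff) return(list(J = J, U = NULL, aborted = TRUE))
  }
  list(J = J, U = U, aborted = FALSE)
}

# Single-sample transportation feasibility as a maximum flow problem:
# source -> feature-1 clones (capacity a_i) -> pair arcs -> feature-2
# clones (capacity b_j) -> sink. A consistent single-sample assignment
# exists iff the maximum flow value is 1.
.flow_feasible_sample <- function(pairs, a, b, tolerance = .FRAC_TOL) {
  n1 <- length(a)
  n2 <- length(b)
  k <- nrow(pairs)
  # vertex ids: 1 = source, 2..(n1+1) = feature-1, then feature-2, sink last
  v1 <- 1L + match(pairs[, 1L], names(a))
  v2 <- 1L + n1 + match(pairs[, 2L], names(b))
  sink <- n1 + n2 + 2L
  from <- c(rep(1L, n1), v1, (1L + n1) + seq_len(n2))
  to <- c(1L + seq_len(n1), v2, rep(sink, n2))
  cap <- c(unname(a), rep(1, k), unname(b))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  fl <- igraph::max_flow(g, source = 1L, target = sink, capacity = cap)
  u <- fl$flow[n1 + seq_len(k)]
  names(u) <- paired_label(pairs[, 1L], pairs[, 2L])
  list(feasible = fl$value >= 1 - tolerance, u = u)
}

#' Consistent proportions for a fixed paired clone set
#'
#' Decides whether a fixed set of paired clones admits proportions `U` that
#' are exactly consistent with the inputs `U1` and `U2`, and constructs
#' such a `U` when it exists. For a single sample this is a maximum-flow
#' computation on the bipartite network whose arcs are the selected pairs
#' and whose capacities are the two marginal rows; with several samples the
#' same question is answered per sample by a linear program (the samples
#' decouple once the clone set is fixed), feasible exactly when the minimum
#' attainable correction is zero.
#'
#' @param clones Character vector of paired labels `"i|j"`, or a
#'   two-column character matrix of (first, second) coordinates.
#' @param U1,U2 Input proportion matrices for the two features (identical
#'   sample sets).
#' @param method `"auto"` (flow for one sample, LP otherwise), `"flow"`
#'   (single sample only) or `"lp"`.
#' @param tolerance Feasibility tolerance on proportion fractions.
#' @return A list with `feasible` (logical) and, when feasible,
#'   `proportions`: a consistent proportion matrix over `clones` (otherwise
#'   `NULL`).
#' @examples
#' U1 <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("1", "2")))
#' U2 <- matrix(c(0.6, 0.4), 1, dimnames = list("s1", c("1", "2")))
#' consistent_proportions_for_clone_set(c("1|1", "2|1", "2|2"), U1, U2)
#' @export
consistent_proportions_for_clone_set <- function(clones, U1, U2,
                                                 method = c("auto", "flow", "lp"),
                                                 tolerance = .FRAC_TOL) {
  method <- match.arg(method)
  .check_same_samples(U1, U2)
  U2 <- U2[rownames(U1), , drop = FALSE]
  pairs <- if (is.matrix(clones)) clones else .split_pairs(clones)
  if (!all(pairs[, 1L] %in% colnames(U1)) ||
      !all(pairs[, 2L] %in% colnames(U2))) {
    stop("`clones` mentions a clone absent from U1 or U2")
  }
  m <- nrow(U1)
  if (method == "flow" && m > 1L) {
    stop("the flow construction applies to a single sample; use method = \"lp\"")
  }
  if (method == "auto") method <- if (m == 1L) "flow" else "lp"
  labels <- paired_label(pairs[, 1L], pairs[, 2L])
  if (method == "flow") {
    fit <- .flow_feasible_sample(pairs,
                                 stats::setNames(U1[1L, ], colnames(U1)),
                                 stats::setNames(U2[1L, ], colnames(U2)),
                                 tolerance)
    if (!fit$feasible) return(list(feasible = FALSE, proportions = NULL))
    U <- matrix(fit$u, 1L, dimnames = list(rownames(U1), labels))
    return(list(feasible = TRUE, proportions = U))
  }
  thr <- tolerance * nrow(U1) * nrow(pairs)
  fit <- .min_correction(pairs, U1, U2, cutoff = thr)
  if (fit$aborted || fit$J > thr) {
    return(list(feasible = FALSE, proportions = NULL))
  }
  list(feasible = TRUE, proportions = fit$U)
}

#' Greedy consistent proportions on the full paired clone set
#'
#' The full product \eqn{\Pi_1 \times \Pi_2} always admits consistent
#' proportions; this constructs one greedily. Pairs are visited in the
#' given order and each pair `(i, j)` receives, per sample, the minimum of
#' the remaining masses of clone `i` in `U1` and clone `j` in `U2`, after
#' which both masses are decremented. The result is always exactly
#' consistent, whatever the order, which makes this the trivial (maximally
#' unparsimonious) solution to the clone integration problem.
#'
#' @param U1,U2 Input proportion matrices (identical sample sets).
#' @param order Optional visit order: a character vector of `"i|j"` labels
#'   or a two-column matrix covering all of \eqn{\Pi_1 \times \Pi_2}
#'   exactly once. Defaults to row-major order (feature-1 clone outermost).
#' @return A list of class `pci_solution` with `clones` (all pairs, in
#'   visit order), `proportions`, `objective` (number of clones with
#'   positive proportion) and `optimal = FALSE`.
#' @examples
#' U1 <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("1", "2")))
#' U2 <- matrix(c(0.3, 0.7), 1, dimnames = list("s1", c("1", "2")))
#' greedy_trivial_solution(U1, U2)$proportions
#' @export
greedy_trivial_solution <- function(U1, U2, order = NULL) {
  .check_same_samples(U1, U2)
  U2 <- U2[rownames(U1), , drop = FALSE]
  cl1 <- colnames(U1)
  cl2 <- colnames(U2)
  full <- cbind(first = rep(cl1, each = length(cl2)),
                second = rep(cl2, times = length(cl1)))
  if (is.null(order)) {
    pairs <- full
  } else {
    pairs <- if (is.matrix(order)) order else .split_pairs(order)
    if (!setequal(paired_label(pairs[, 1L], pairs[, 2L]),
                  paired_label(full[, 1L], full[, 2L])) ||
        nrow(pairs) != nrow(full)) {
      stop("`order` must cover the full product of clone sets exactly once")
    }
  }
  rem1 <- U1
  rem2 <- U2
  labels <- paired_label(pairs[, 1L], pairs[, 2L])
  U <- matrix(0, nrow(U1), nrow(pairs),
              dimnames = list(rownames(U1), labels))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    take <- pmin(rem1[, i], rem2[, j])
    U[, k] <- take
    rem1[, i] <- rem1[, i] - take
    rem2[, j] <- rem2[, j] - take
  }
  structure(list(clones = labels, proportions = U,
                 objective = sum(colSums(U) > 0), optimal = FALSE),
            class = "pci_solution")
}
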