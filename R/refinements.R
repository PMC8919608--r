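# A refinement of clone trees T1, T2 is fully determined by its
# edge-realization assignment: each edge (i,i') of T1 is realized at
# exactly one feature-2 clone j (giving refinement edge (i,j)->(i',j)),
# and each edge (j,j') of T2 at exactly one feature-1 clone i. An
# assignment is valid iff every realization's parent vertex exists in the
# resulting vertex set and the n1+n2-1 vertex labels are distinct; the
# parent pointers then decrease strictly in the product ancestry order, so
# the result is automatically a tree rooted at (r(T1), r(T2)).
#
# A vertex (i, j) exists iff it is the root, or the in-edge of i in T1 is
# realized at j, or the in-edge of j in T2 is realized at i. Processing T1
# edges root-down and then T2 edges root-down, the first condition is
# already decided when needed while the second becomes a (at most one per
# T2 edge) forced requirement, which keeps the search duplicate-free and
# heavily pruned.

.refinement_guard <- function(T1, T2, max_edges = 12L) {
  k <- nrow(T1$edges) + nrow(T2$edges)
  if (k > max_edges) {
    stop(sprintf(
      "combined edge count %d exceeds the enumeration guard (%d); use solve_pcti()",
      k, max_edges))
  }
  invisible(k)
}

# Build the refinement clone_tree for a complete assignment.
.assignment_tree <- function(T1, T2, phi1, phi2) {
  root <- paired_label(T1$root, T2$root)
  e1 <- T1$edges
  e2 <- T2$edges
  edges <- rbind(
    if (nrow(e1) > 0L)
      cbind(paired_label(e1[, 1L], phi1[e1[, 2L]]),
            paired_label(e1[, 2L], phi1[e1[, 2L]])),
    if (nrow(e2) > 0L)
      cbind(paired_label(phi2[e2[, 2L]], e2[, 1L]),
            paired_label(phi2[e2[, 2L]], e2[, 2L])))
  if (is.null(edges)) return(clone_tree(vertices = root))
  clone_tree(edges, root = root)
}

#' Enumerate all refinements of two clone trees
#'
#' Generates every clone tree on `n1 + n2 - 1` paired clones that refines
#' `T1` and `T2` (see [check_refinement()]), without duplicates, by
#' depth-first search over edge-realization assignments with constraint
#' propagation. The number of refinements grows quickly with the combined
#' edge count (two chains of four edges each already admit 139), hence the
#' guard.
#'
#' @param T1,T2 Input `clone_tree`s.
#' @param max_edges Guard on `(n1 - 1) + (n2 - 1)`.
#' @return A list of `clone_tree`s with paired vertex labels.
#' @examples
#' T1 <- clone_tree(rbind(c("1", "2")))
#' T2 <- clone_tree(rbind(c("1", "2")))
#' length(enumerate_refinements(T1, T2)) # 3
#' @export
enumerate_refinements <- function(T1, T2, max_edges = 12L) {
  .refinement_guard(T1, T2, max_edges)
  out <- list()
  .refinement_dfs(T1, T2, function(phi1, phi2) {
    out[[length(out) + 1L]] <<- .assignment_tree(T1, T2, phi1, phi2)
    TRUE
  })
  out
}

# DFS engine: calls `emit(phi1, phi2)` for every valid assignment; stops
# early if emit returns FALSE. phi1 is named by T1 children, phi2 by T2
# children.
.refinement_dfs <- function(T1, T2, emit) {
  r1 <- T1$root; r2 <- T2$root
  e1 <- T1$edges[.edges_root_down(T1), , drop = FALSE]
  e2 <- T2$edges[.edges_root_down(T2), , drop = FALSE]
  k1 <- nrow(e1); k2 <- nrow(e2)
  n <- length(T1$vertices) + length(T2$vertices) - 1L
  phi1 <- stats::setNames(rep(NA_character_, k1), e1[, 2L])
  phi2 <- stats::setNames(rep(NA_character_, k2), e2[, 2L])
  alive <- TRUE

  step2 <- function(t, phi2, req2) {
    if (!alive) return(invisible(NULL))
    if (t > k2) {
      if (!emit(phi1, phi2)) alive <<- FALSE
      return(invisible(NULL))
    }
    j <- e2[t, 1L]; j2 <- e2[t, 2L]
    cand <- if (!is.na(req2[j2])) req2[[j2]] else T1$vertices
    for (i in cand) {
      ok <- (i == r1 && j == r2) ||
        (i != r1 && phi1[[i]] == j) ||
        (j != r2 && phi2[[j]] == i)
      if (!ok) next
      # Distinctness of the new vertex (i, j2): feature-2 realization
      # children have pairwise distinct second coordinates and cannot be
      # the root, so the only possible clash is with the feature-1
      # realization child (i, phi1[i]).
      if (i != r1 && phi1[[i]] == j2) next
      phi2_t <- phi2
      phi2_t[j2] <- i
      step2(t + 1L, phi2_t, req2)
      if (!alive) return(invisible(NULL))
    }
    invisible(NULL)
  }

  step1 <- function(t, req2) {
    if (!alive) return(invisible(NULL))
    if (t > k1) {
      step2(1L, phi2, req2)
      return(invisible(NULL))
    }
    i <- e1[t, 1L]; i2 <- e1[t, 2L]
    for (j in T2$vertices) {
      req2_t <- req2
      if ((i == r1 && j == r2) || (i != r1 && phi1[[i]] == j)) {
        # parent vertex (i, j) already guaranteed
      } else if (j != r2) {
        if (!is.na(req2_t[j]) && req2_t[[j]] != i) next
        req2_t[j] <- i
      } else {
        next
      }
      phi1[i2] <<- j
      step1(t + 1L, req2_t)
      phi1[i2] <<- NA_character_
      if (!alive) return(invisible(NULL))
    }
    invisible(NULL)
  }

  if (n == 1L) {
    emit(phi1, phi2)
    return(invisible(NULL))
  }
  step1(1L, stats::setNames(rep(NA_character_, length(T2$vertices)),
                            T2$vertices))
  invisible(NULL)
}

#' Minimal correction attainable on a fixed refinement
#'
#' With the clone set fixed to the vertices of `T`, the smallest total
#' correction \eqn{J} is a linear program per sample: minimize the L1
#' deviation of both marginals of `U` from `U1` and `U2` over proportion
#' rows supported on `V(T)`. The tree topology itself does not enter
#' \eqn{J}; only its vertex set does.
#'
#' @param T A paired `clone_tree` (typically from
#'   [enumerate_refinements()] or [solve_pcti()]).
#' @param U1,U2 Input proportion matrices (identical sample sets).
#' @return A list with `J` (minimal total correction) and `proportions`
#'   (an attaining proportion matrix over `V(T)`).
#' @examples
#' T <- clone_tree(rbind(c("1|1", "1|2"), c("1|2", "2|2")))
#' U1 <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("1", "2")))
#' U2 <- matrix(c(0.3, 0.7), 1, dimnames = list("s1", c("1", "2")))
#' score_refinement(T, U1, U2)$J # 0
#' @export
score_refinement <- function(T, U1, U2) {
  .check_same_samples(U1, U2)
  U2 <- U2[rownames(U1), , drop = FALSE]
  pairs <- .split_pairs(T$vertices)
  if (!all(pairs[, 1L] %in% colnames(U1)) ||
      !all(pairs[, 2L] %in% colnames(U2))) {
    stop("vertices of `T` mention clones absent from U1 or U2")
  }
  fit <- .min_correction(pairs, U1, U2)
  list(J = fit$J, proportions = fit$U)
}

#' Brute-force oracle for parsimonious clone tree integration
#'
#' Enumerates every refinement of `T1` and `T2` (guarded; see
#' [enumerate_refinements()]) and scores each with [score_refinement()],
#' returning the minimum-correction refinement and the number of
#' co-optimal ones. Intended as an independent oracle for [solve_pcti()]
#' at small sizes, and as the exhaustive `--enumerate` workflow.
#'
#' @param T1,T2 Input `clone_tree`s.
#' @param U1,U2 Input proportion matrices.
#' @param max_edges Enumeration guard on the combined input edge count.
#' @param tolerance Corrections within `tolerance` of the minimum count as
#'   co-optimal.
#' @return A list with `J`, `tree`, `proportions`, `n_optimal` (number of
#'   co-optimal refinements), `n_refinements` (number scored) and
#'   `optimal_trees` (list of all co-optimal refinements).
#' @export
pcti_brute_force <- function(T1, U1, T2, U2, max_edges = 12L,
                             tolerance = .FRAC_TOL) {
  trees <- enumerate_refinements(T1, T2, max_edges = max_edges)
  scores <- vapply(trees, function(tr) score_refinement(tr, U1, U2)$J,
                   numeric(1))
  best <- which.min(scores)
  opt <- which(scores <= scores[best] + tolerance)
  list(J = scores[best], tree = trees[[best]],
       proportions = score_refinement(trees[[best]], U1, U2)$proportions,
       n_optimal = length(opt), n_refinements = length(trees),
       optimal_trees = trees[opt])
}
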