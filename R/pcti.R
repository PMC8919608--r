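#' Integrate two clone trees with minimal proportion correction (exact)
#'
#' Solves the parsimonious clone tree integration problem: among all
#' refinements `T` of the input clone trees `T1` and `T2`, find the one
#' (with proportions `U` supported on `V(T)`) minimizing the total
#' absolute correction \eqn{J(U, U_1, U_2)} of the input proportions.
#' Every refinement has exactly `n1 + n2 - 1` clones and root
#' `(r(T1), r(T2))`; a refinement always exists, so the problem is always
#' feasible, and `J = 0` exactly when some refinement's clone set admits
#' consistent proportions.
#'
#' The solver searches the edge-realization assignment space exhaustively
#' (each input edge is realized at exactly one clone of the other feature;
#' these realizations are the integral variables of the problem's natural
#' MILP formulation), propagating the vertex-existence constraints, and
#' scores each distinct candidate clone set once by per-sample linear
#' programs — the objective depends on the refinement only through its
#' vertex set. The problem is NP-hard, but clonal deconvolution instances
#' (up to roughly a dozen clones per feature) stay well within reach.
#'
#' @param T1,T2 Input `clone_tree`s; `V(T1)` must equal the clone set of
#'   `U1`, likewise `T2` and `U2`.
#' @param U1,U2 Input proportion matrices (identical sample sets).
#' @param options A [solver_options()] list; on timeout the incumbent is
#'   returned with `optimal = FALSE`.
#' @return A list of class `pcti_solution`: `clones` (paired labels),
#'   `tree` (refined `clone_tree`), `proportions`, `total_correction`
#'   (the minimized `J`), `optimal`, `n_optimal_supports` (number of
#'   distinct optimal clone sets seen) and `n_supports_scored`.
#' @examples
#' T1 <- clone_tree(rbind(c("1", "2")))
#' T2 <- clone_tree(rbind(c("1", "2")))
#' U1 <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("1", "2")))
#' U2 <- matrix(c(0.3, 0.7), 1, dimnames = list("s1", c("1", "2")))
#' solve_pcti(T1, U1, T2, U2)$total_correction # 0
#' @export
solve_pcti <- function(T1, U1, T2, U2, options = solver_options()) {
  U1 <- validate_proportion_matrix(U1, tolerance = options$tolerance)
  U2 <- validate_proportion_matrix(U2, tolerance = options$tolerance)
  .check_same_samples(U1, U2)
  U2 <- U2[rownames(U1), , drop = FALSE]
  if (!setequal(T1$vertices, colnames(U1))) {
    stop("V(T1) must equal the clone set of U1")
  }
  if (!setequal(T2$vertices, colnames(U2))) {
    stop("V(T2) must equal the clone set of U2")
  }
  r1 <- T1$root; r2 <- T2$root
  e1 <- T1$edges[.edges_root_down(T1), , drop = FALSE]
  e2 <- T2$edges[.edges_root_down(T2), , drop = FALSE]
  k1 <- nrow(e1); k2 <- nrow(e2)
  n <- k1 + k2 + 1L
  deadline <- proc.time()[[3L]] + options$time_limit
  timed_out <- FALSE

  cache <- new.env(parent = emptyenv())   # support key -> J
  best <- NULL                            # list(J, U, phi1, phi2)
  n_best <- 0L
  score_leaf <- function(phi1, phi2) {
    verts <- c(paired_label(r1, r2),
               if (k1 > 0L) paired_label(e1[, 2L], phi1[e1[, 2L]]),
               if (k2 > 0L) paired_label(phi2[e2[, 2L]], e2[, 2L]))
    key <- paste(sort(verts), collapse = ";")
    if (!is.null(cache[[key]])) return(invisible(NULL))
    cutoff <- if (is.null(best)) Inf else best$J + options$tolerance
    fit <- .min_correction(.split_pairs(verts), U1, U2, cutoff = cutoff)
    cache[[key]] <- fit$J
    if (fit$aborted) return(invisible(NULL))
    if (is.null(best) || fit$J < best$J - options$tolerance) {
      best <<- list(J = fit$J, U = fit$U, phi1 = phi1, phi2 = phi2)
      n_best <<- 1L
    } else if (fit$J <= best$J + options$tolerance) {
      n_best <<- n_best + 1L
      if (fit$J < best$J) {
        best$J <<- fit$J
        best$U <<- fit$U
        best$phi1 <<- phi1
        best$phi2 <<- phi2
      }
    }
    invisible(NULL)
  }

  # DFS over realizations, feature-2 edges first (root-down), deferring
  # vertex-existence requirements onto the feature-1 realizations. This
  # mirrors (transposed) the enumeration in enumerate_refinements(), which
  # serves as its independent oracle in the test-suite.
  phi1 <- stats::setNames(rep(NA_character_, k1), if (k1) e1[, 2L])
  phi2 <- stats::setNames(rep(NA_character_, k2), if (k2) e2[, 2L])

  walk1 <- function(t, phi1) {
    if (timed_out) return(invisible(NULL))
    if (proc.time()[[3L]] > deadline && !is.null(best)) {
      timed_out <<- TRUE
      return(invisible(NULL))
    }
    if (t > k1) {
      score_leaf(phi1, phi2)
      return(invisible(NULL))
    }
    i <- e1[t, 1L]; i2 <- e1[t, 2L]
    cand <- if (!is.na(req1[i2])) req1[[i2]] else T2$vertices
    for (j in cand) {
      ok <- (i == r1 && j == r2) ||
        (i != r1 && phi1[[i]] == j) ||
        (j != r2 && phi2[[j]] == i)
      if (!ok) next
      # clash of new vertex (i2, j) with the feature-2 child (phi2[j], j)
      if (j != r2 && phi2[[j]] == i2) next
      phi1_t <- phi1
      phi1_t[i2] <- j
      walk1(t + 1L, phi1_t)
      if (timed_out) return(invisible(NULL))
    }
    invisible(NULL)
  }

  req1 <- stats::setNames(rep(NA_character_, k1), if (k1) e1[, 2L])
  walk2 <- function(t) {
    if (timed_out) return(invisible(NULL))
    if (t > k2) {
      walk1(1L, phi1)
      return(invisible(NULL))
    }
    j <- e2[t, 1L]; j2 <- e2[t, 2L]
    for (i in T1$vertices) {
      undo <- FALSE
      if ((i == r1 && j == r2) || (j != r2 && phi2[[j]] == i)) {
        # parent vertex (i, j) already guaranteed
      } else if (i != r1) {
        if (!is.na(req1[i]) && req1[[i]] != j) next
        if (is.na(req1[i])) {
          req1[i] <<- j
          undo <- TRUE
        }
      } else {
        next
      }
      phi2[j2] <<- i
      walk2(t + 1L)
      phi2[j2] <<- NA_character_
      if (undo) req1[i] <<- NA_character_
      if (timed_out) return(invisible(NULL))
    }
    invisible(NULL)
  }

  walk2(1L)
  stopifnot(!is.null(best))
  tree <- .assignment_tree(T1, T2, best$phi1, best$phi2)
  U <- best$U[, tree$vertices, drop = FALSE]
  # post-conditions: a genuine refinement whose recomputed correction
  # matches the optimized objective
  chk <- check_refinement(tree, T1, T2)
  if (!chk$pass) {
    stop("internal error: solver output is not a refinement: ",
         paste(chk$violations, collapse = "; "))
  }
  J_re <- consistency_error(U, U1, U2)
  if (abs(J_re - best$J) > 1e-5) {
    stop(sprintf("internal error: recomputed correction %.8f != objective %.8f",
                 J_re, best$J))
  }
  structure(list(clones = tree$vertices, tree = tree, proportions = U,
                 total_correction = best$J, optimal = !timed_out,
                 n_optimal_supports = n_best,
                 n_supports_scored = length(ls(cache))),
            class = "pcti_solution")
}

#' @export
print.pcti_solution <- function(x, ...) {
  cat(sprintf(
    "clone tree integration: %d clones, total correction J = %.6g%s\n",
    length(x$clones), x$total_correction,
    if (isTRUE(x$optimal)) " (optimal)" else " (incumbent)"))
  print(x$tree)
  invisible(x)
}

#' Select the input tree with the smallest correction
#'
#' When one feature's clone tree is unknown (as for CNA clones produced by
#' copy-number deconvolution without tree output), a standard workflow is
#' to enumerate candidate trees on that feature's clones, integrate each
#' against the known tree, and keep the candidate whose optimal total
#' correction `J` is smallest.
#'
#' @param candidates Nonempty list of `clone_tree`s on the feature-2
#'   clones (vertex set must equal the clone set of `U2`).
#' @param T1 Known feature-1 `clone_tree`.
#' @param U1,U2 Input proportion matrices.
#' @param options A [solver_options()] list (applied per candidate).
#' @param tolerance Candidates within `tolerance` of the best `J` are
#'   reported as ties.
#' @return A list with `best_index`, `best_tree`, `solution` (the
#'   [solve_pcti()] result for the winner), `J_values` (per candidate) and
#'   `ties` (indices achieving the minimum within `tolerance`).
#' @export
select_best_input_tree <- function(candidates, T1, U1, U2,
                                   options = solver_options(),
                                   tolerance = .FRAC_TOL) {
  if (length(candidates) == 0L) stop("empty candidate list")
  sols <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    if (!setequal(candidates[[k]]$vertices, colnames(U2))) {
      stop(sprintf("candidate %d vertex set does not match the clones of U2",
                   k))
    }
    sols[[k]] <- solve_pcti(T1, U1, candidates[[k]], U2, options = options)
  }
  J <- vapply(sols, `[[`, numeric(1), "total_correction")
  best <- which.min(J)
  list(best_index = best, best_tree = candidates[[best]],
       solution = sols[[best]], J_values = J,
       ties = which(J <= J[best] + tolerance))
}

#' Enumerate rooted labeled trees on a clone set
#'
#' Generates all rooted labeled trees on the given clones with the given
#' root, as candidates for [select_best_input_tree()]. Labeled trees on
#' `k` vertices are in bijection with Pruefer sequences, so there are
#' `k^(k-2)` of them (1 for `k <= 2`); each is decoded and oriented away
#' from the root.
#'
#' @param clone_ids Character vector of clone labels (`k >= 1`).
#' @param root_id Root label, an element of `clone_ids`.
#' @param cap Maximum number of trees to generate.
#' @param truncate If `TRUE`, stop at `cap` trees with a warning instead
#'   of erroring when `k^(k-2) > cap`.
#' @return A list of `clone_tree`s.
#' @examples
#' length(enumerate_candidate_trees(c("0", "1", "2"), "0")) # 3
#' @export
enumerate_candidate_trees <- function(clone_ids, root_id, cap = 10000L,
                                      truncate = FALSE) {
  clone_ids <- as.character(clone_ids)
  k <- length(clone_ids)
  stopifnot(k >= 1L, root_id %in% clone_ids, !anyDuplicated(clone_ids))
  if (k == 1L) return(list(clone_tree(vertices = clone_ids)))
  if (k == 2L) {
    return(list(clone_tree(rbind(c(root_id, setdiff(clone_ids, root_id))))))
  }
  total <- k^(k - 2L)
  if (total > cap) {
    if (!truncate) {
      stop(sprintf("%d labeled trees exceed cap = %d; set truncate = TRUE",
                   total, cap))
    }
    warning(sprintf("truncating enumeration at %d of %d labeled trees",
                    cap, total))
  }
  n_seq <- min(total, cap)
  root <- match(root_id, clone_ids)
  out <- vector("list", n_seq)
  digits <- rep(1L, k - 2L)
  for (s in seq_len(n_seq)) {
    out[[s]] <- .rooted_tree_from_prufer(digits, k, root, clone_ids)
    # next Pruefer sequence in base-k counting order
    d <- 1L
    while (d <= k - 2L) {
      digits[d] <- digits[d] + 1L
      if (digits[d] <= k) break
      digits[d] <- 1L
      d <- d + 1L
    }
  }
  out
}

# Decode a Pruefer sequence into an undirected labeled tree, then orient
# the edges away from the chosen root.
.rooted_tree_from_prufer <- function(seq, k, root, labels) {
  deg <- rep(1L, k)
  for (a in seq) deg[a] <- deg[a] + 1L
  adj <- vector("list", k)
  add_edge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (a in seq) {
    leaf <- which(deg == 1L)[1L]
    add_edge(leaf, a)
    deg[leaf] <- 0L
    deg[a] <- deg[a] - 1L
  }
  last <- which(deg == 1L)
  add_edge(last[1L], last[2L])
  # BFS orientation from the root
  parent <- rep(NA_integer_, k)
  seen <- rep(FALSE, k)
  queue <- root
  seen[root] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  kids <- which(!is.na(parent))
  clone_tree(cbind(labels[parent[kids]], labels[kids]), root = labels[root])
}
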