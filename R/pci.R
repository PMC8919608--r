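#' Options for the exact solvers
#'
#' @param time_limit Wall-clock budget in seconds; when exceeded the solver
#'   returns its incumbent flagged `optimal = FALSE`.
#' @param tolerance Absolute tolerance on proportion fractions.
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(time_limit = Inf, tolerance = .FRAC_TOL) {
  stopifnot(time_limit > 0, tolerance >= 0)
  structure(list(time_limit = time_limit, tolerance = tolerance),
            class = "solver_options")
}

#' @export
print.pci_solution <- function(x, ...) {
  cat(sprintf("clone integration: %d clones%s\n", length(x$clones),
              if (isTRUE(x$optimal)) " (optimal)" else ""))
  cat("  ", paste(x$clones, collapse = ", "), "\n")
  invisible(x)
}

# Pairs with a zero-support coordinate are forced to zero proportion in
# every sample, so minimal solutions never need them.
.positive_pairs <- function(U1, U2) {
  cl1 <- colnames(U1)[colSums(U1) > 0]
  cl2 <- colnames(U2)[colSums(U2) > 0]
  cbind(first = rep(cl1, each = length(cl2)),
        second = rep(cl2, times = length(cl1)))
}

#' Minimize the number of integrated clones (exact)
#'
#' Solves the parsimonious clone integration problem: find the smallest set
#' \eqn{\Pi \subseteq \Pi_1 \times \Pi_2} of paired clones admitting
#' proportions exactly consistent with `U1` and `U2`. The search is an
#' iterative-deepening branch and bound over pair subsets, starting from
#' the support lower bound `max(S(U1), S(U2))`: partial selections are
#' pruned when the remaining capacity cannot cover every clone with
#' positive support, and complete selections are tested for feasibility by
#' maximum flow (one sample) or per-sample linear programs. The problem is
#' NP-hard, but the clone counts arising in clonal deconvolution keep this
#' search small.
#'
#' @param U1,U2 Input proportion matrices (identical sample sets).
#' @param options A [solver_options()] list.
#' @return A list of class `pci_solution`: `clones` (paired labels),
#'   `proportions` (consistent matrix over them), `objective`
#'   (`length(clones)`) and `optimal` (`FALSE` only on timeout).
#' @examples
#' U1 <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("1", "2")))
#' U2 <- matrix(c(0.6, 0.4), 1, dimnames = list("s1", c("1", "2")))
#' solve_pci(U1, U2)$objective # 3
#' @export
solve_pci <- function(U1, U2, options = solver_options()) {
  U1 <- validate_proportion_matrix(U1, tolerance = options$tolerance)
  U2 <- validate_proportion_matrix(U2, tolerance = options$tolerance)
  .check_same_samples(U1, U2)
  U2 <- U2[rownames(U1), , drop = FALSE]
  pairs <- .positive_pairs(U1, U2)
  np <- nrow(pairs)
  pos1 <- unique(pairs[, 1L])
  pos2 <- unique(pairs[, 2L])
  lb <- max(support(U1), support(U2))
  deadline <- proc.time()[[3L]] + options$time_limit
  feasible_set <- function(idx) {
    consistent_proportions_for_clone_set(pairs[idx, , drop = FALSE],
                                         U1, U2,
                                         tolerance = options$tolerance)
  }
  found <- NULL
  timed_out <- FALSE
  for (k in lb:np) {
    # DFS over index combinations with covering prune: the pairs still
    # selectable must be able to cover every positive-support clone.
    rec <- function(start, chosen, cov1, cov2) {
      if (!is.null(found) || timed_out) return(invisible(NULL))
      if (proc.time()[[3L]] > deadline) {
        timed_out <<- TRUE
        return(invisible(NULL))
      }
      slots <- k - length(chosen)
      if (slots == 0L) {
        fit <- feasible_set(chosen)
        if (fit$feasible) found <<- list(idx = chosen, fit = fit)
        return(invisible(NULL))
      }
      need <- max(length(pos1) - sum(cov1), length(pos2) - sum(cov2))
      if (need > slots || np - start + 1L < slots) return(invisible(NULL))
      for (t in start:(np - slots + 1L)) {
        c1 <- cov1; c2 <- cov2
        c1[pairs[t, 1L]] <- TRUE
        c2[pairs[t, 2L]] <- TRUE
        rec(t + 1L, c(chosen, t), c1, c2)
        if (!is.null(found) || timed_out) return(invisible(NULL))
      }
      invisible(NULL)
    }
    rec(1L, integer(0),
        stats::setNames(logical(length(pos1)), pos1),
        stats::setNames(logical(length(pos2)), pos2))
    if (!is.null(found) || timed_out) break
  }
  if (is.null(found)) {
    # Timeout before any feasible subset: fall back to the always-feasible
    # greedy trivial solution as the incumbent.
    sol <- greedy_trivial_solution(U1, U2)
    sol$optimal <- FALSE
    return(sol)
  }
  sel <- pairs[found$idx, , drop = FALSE]
  structure(list(clones = paired_label(sel[, 1L], sel[, 2L]),
                 proportions = found$fit$proportions,
                 objective = nrow(sel),
                 optimal = !timed_out),
            class = "pci_solution")
}

#' Brute-force oracle for parsimonious clone integration
#'
#' Enumerates subsets of the full pair set \eqn{\Pi_1 \times \Pi_2} by
#' increasing size, starting at the support lower bound, and returns the
#' first size admitting consistent proportions
#' (via [consistent_proportions_for_clone_set()]). Intended as an
#' independent correctness oracle for [solve_pci()] at small sizes.
#'
#' @param U1,U2 Input proportion matrices.
#' @param max_pairs Enumeration guard: error if `n1 * n2` exceeds this.
#' @param all If `TRUE`, also collect every feasible subset of the optimal
#'   size (the optimal solution is generally not unique).
#' @return A list with `size`, `clones` (one witness), `proportions`, and,
#'   when `all = TRUE`, `witnesses` (list of label vectors).
#' @export
pci_brute_force <- function(U1, U2, max_pairs = 20L, all = FALSE) {
  U1 <- validate_proportion_matrix(U1)
  U2 <- validate_proportion_matrix(U2)
  .check_same_samples(U1, U2)
  U2 <- U2[rownames(U1), , drop = FALSE]
  cl1 <- colnames(U1)
  cl2 <- colnames(U2)
  if (length(cl1) * length(cl2) > max_pairs) {
    stop(sprintf(
      "%d candidate pairs exceed the enumeration guard (%d); use solve_pci()",
      length(cl1) * length(cl2), max_pairs))
  }
  full <- cbind(first = rep(cl1, each = length(cl2)),
                second = rep(cl2, times = length(cl1)))
  pos1 <- cl1[colSums(U1) > 0]
  pos2 <- cl2[colSums(U2) > 0]
  lb <- max(support(U1), support(U2))
  for (k in lb:nrow(full)) {
    hits <- list()
    for (idx in utils::combn(nrow(full), k, simplify = FALSE)) {
      sub <- full[idx, , drop = FALSE]
      # a positive-support clone outside every pair can never be consistent
      if (!all(pos1 %in% sub[, 1L]) || !all(pos2 %in% sub[, 2L])) next
      fit <- consistent_proportions_for_clone_set(sub, U1, U2)
      if (fit$feasible) {
        hits[[length(hits) + 1L]] <-
          list(clones = paired_label(sub[, 1L], sub[, 2L]),
               proportions = fit$proportions)
        if (!all) break
      }
    }
    if (length(hits) > 0L) {
      out <- list(size = k, clones = hits[[1L]]$clones,
                  proportions = hits[[1L]]$proportions)
      if (all) out$witnesses <- lapply(hits, `[[`, "clones")
      return(out)
    }
  }
  stop("internal error: no feasible subset found (the full set is always feasible)")
}
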