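#' Clone recall against ground truth
#'
#' Fraction of ground-truth paired clones recovered by a solution:
#' `|intersect(predicted, truth)| / |truth|`. Identity of paired clones is
#' exact label equality of both coordinates. Not symmetric in its
#' arguments (it does not penalize predicted clones absent from the
#' truth).
#'
#' @param predicted,truth Character vectors of paired clone labels
#'   (`"i|j"`); `truth` must be nonempty.
#' @return Fraction in `[0, 1]`.
#' @examples
#' clone_recall(c("1|1", "2|2"), c("1|1", "2|1", "2|2")) # 2/3
#' @export
clone_recall <- function(predicted, truth) {
  if (length(truth) == 0L) stop("ground-truth clone set is empty")
  length(intersect(unique(predicted), unique(truth))) / length(unique(truth))
}

#' Parent-child distance between two clone trees
#'
#' The size of the symmetric difference of the directed edge sets divided
#' by the size of their union: 0 for identical edge sets, 1 for disjoint
#' ones. Edges are compared as ordered (parent, child) label pairs; no
#' harmonization of differing vertex sets is attempted. Two edgeless
#' trees are at distance 0 when their roots agree (and incomparable
#' otherwise).
#'
#' @param T,T_star The two `clone_tree`s.
#' @return Fraction in `[0, 1]`.
#' @examples
#' A <- clone_tree(rbind(c("r", "a"), c("r", "b")))
#' B <- clone_tree(rbind(c("r", "a"), c("a", "b")))
#' parent_child_distance(A, B) # 2/3
#' @export
parent_child_distance <- function(T, T_star) {
  e1 <- .edge_keys(T)
  e2 <- .edge_keys(T_star)
  if (length(e1) == 0L && length(e2) == 0L) {
    if (T$root != T_star$root) {
      stop("both trees are edgeless with different roots; distance undefined")
    }
    return(0)
  }
  un <- union(e1, e2)
  length(setdiff(un, intersect(e1, e2))) / length(un)
}

#' Simulate-and-solve study over a parameter grid
#'
#' Generates `reps` instances per combination of clone count and noise
#' level with [simulate_instance()], integrates each with [solve_pcti()],
#' and evaluates clone recall and parent-child distance against the
#' ground truth. This is the harness behind the package's simulation
#' results.
#'
#' @param n_values Integer vector; each entry is used as both features'
#'   clone count (`n1 = n2`).
#' @param h_values Noise levels.
#' @param m Number of samples.
#' @param reps Instances per `(n, h)` combination.
#' @param seed Base seed; instance `k` of the grid uses `seed * 1000 + k`
#'   (kept within integer range).
#' @param options [solver_options()] passed to the solver.
#' @return A data frame with one row per instance: `n1`, `n2`, `m`, `h`,
#'   `rep`, `seed`, `recall`, `parent_child_distance`, `J`, `optimal`.
#' @export
run_simulation_study <- function(n_values = c(3, 5), h_values = c(0, 0.05, 0.1),
                                 m = 5, reps = 10, seed = 1L,
                                 options = solver_options()) {
  grid <- expand.grid(rep = seq_len(reps), h = h_values, n = n_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    inst_seed <- (abs(seed) * 1009L + k * 7919L) %% .Machine$integer.max
    cfg <- simulation_config(grid$n[k], grid$n[k], m = m, h = grid$h[k],
                             seed = inst_seed)
    bundle <- simulate_instance(cfg)
    sol <- solve_pcti(bundle$inputs$tree1, bundle$inputs$props1,
                      bundle$inputs$tree2, bundle$inputs$props2,
                      options = options)
    rows[[k]] <- data.frame(
      n1 = cfg$n1, n2 = cfg$n2, m = cfg$m, h = cfg$h, rep = grid$rep[k],
      seed = inst_seed,
      recall = clone_recall(sol$clones, bundle$truth$clones),
      parent_child_distance = parent_child_distance(sol$tree,
                                                    bundle$truth$tree),
      J = sol$total_correction,
      optimal = sol$optimal)
  }
  do.call(rbind, rows)
}
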