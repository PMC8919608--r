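#' Simulation configuration
#'
#' @param n1,n2 Number of clones for feature 1 (e.g. SNV clones) and
#'   feature 2 (e.g. CNA clones); both at least 1.
#' @param m Number of samples.
#' @param h Noise level in `[0, 1]`: each input proportion row is the
#'   convex mixture `(1 - h) * truth + h * fresh Dirichlet draw`; `h = 0`
#'   means noise-free inputs, `h = 1` inputs unrelated to the truth.
#' @param seed Integer seed making the whole bundle reproducible.
#' @param concentration Symmetric Dirichlet concentration for clone
#'   proportions (1 = uniform on the simplex).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n1, n2, m, h = 0, seed = 1L,
                              concentration = 1) {
  stopifnot(n1 >= 1, n2 >= 1, m >= 1, h >= 0, h <= 1, concentration > 0)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 m = as.integer(m), h = h, seed = as.integer(seed),
                 concentration = concentration),
            class = "simulation_config")
}

#' Simulate a ground-truth integrated clone tree
#'
#' Grows a random rooted tree on `n1 + n2 - 1` vertices by iteratively
#' attaching each new vertex to a parent chosen uniformly among the
#' existing vertices (a growing random network). The `n1 + n2 - 2` edges
#' carry distinct mutation events — feature-1 events `2..n1` and feature-2
#' events `2..n2` — assigned to edges in uniformly random order. Clone
#' labels propagate from the root `(1, 1)`: a child copies its parent's
#' pair with the event's coordinate overwritten, which yields pairwise
#' distinct paired labels.
#'
#' Uses the current RNG state; seed control lives in
#' [simulate_instance()].
#'
#' @param n1,n2 Clone counts per feature.
#' @return A paired `clone_tree` on `n1 + n2 - 1` vertices.
#' @export
simulate_clone_tree <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  n <- n1 + n2 - 1L
  events <- rbind(
    if (n1 > 1L) cbind(feature = 1L, value = 2:n1),
    if (n2 > 1L) cbind(feature = 2L, value = 2:n2))
  if (n == 1L) return(clone_tree(vertices = paired_label("1", "1")))
  events <- events[sample.int(nrow(events)), , drop = FALSE]
  labels <- matrix(NA_character_, n, 2L)
  labels[1L, ] <- c("1", "1")
  parent <- integer(n)
  for (t in seq_len(n - 1L)) {
    parent[t + 1L] <- sample.int(t, 1L)
    lab <- labels[parent[t + 1L], ]
    lab[events[t, "feature"]] <- as.character(events[t, "value"])
    labels[t + 1L, ] <- lab
  }
  verts <- paired_label(labels[, 1L], labels[, 2L])
  clone_tree(cbind(verts[parent[-1L]], verts[-1L]), root = verts[1L])
}

#' Collapse a paired clone tree onto one feature
#'
#' Contracts every edge of the paired tree whose mutation event belongs to
#' the other feature (i.e. whose endpoints share the same coordinate in
#' the chosen feature), yielding the clone tree of that feature alone.
#' This is the inverse of refinement: collapsing any refinement of
#' `(T1, T2)` onto feature 1 or 2 recovers `T1` or `T2`.
#'
#' @param T A paired `clone_tree`.
#' @param feature 1 or 2.
#' @return A `clone_tree` on that feature's clones.
#' @examples
#' T <- clone_tree(rbind(c("1|1", "1|2"), c("1|2", "2|2")))
#' collapse_to_feature_tree(T, 1) # 1 -> 2
#' @export
collapse_to_feature_tree <- function(T, feature) {
  stopifnot(feature %in% c(1, 2))
  comp <- .split_pairs(T$vertices)[, feature]
  names(comp) <- T$vertices
  if (nrow(T$edges) == 0L) return(clone_tree(vertices = unname(comp)))
  pc <- comp[T$edges[, 1L]]
  cc <- comp[T$edges[, 2L]]
  keep <- pc != cc
  if (!any(keep)) return(clone_tree(vertices = comp[[T$root]]))
  edges <- unique(cbind(unname(pc[keep]), unname(cc[keep])))
  out <- clone_tree(edges, root = comp[[T$root]])
  if (length(out$vertices) != length(unique(comp))) {
    stop("internal error: collapsing did not yield a tree on the feature's clones")
  }
  out
}

# Rows drawn from a symmetric Dirichlet by gamma normalization.
.rdirichlet_rows <- function(n, k, concentration = 1) {
  if (k == 1L) return(matrix(1, n, 1L))
  x <- matrix(stats::rgamma(n * k, shape = concentration), n, k)
  x / rowSums(x)
}

#' Simulate clone proportions
#'
#' Draws each sample's clone proportion row independently from a symmetric
#' Dirichlet distribution (all concentration parameters equal, default 1).
#' Uses the current RNG state.
#'
#' @param clones Character vector of clone labels.
#' @param m Number of samples.
#' @param concentration Dirichlet concentration parameter.
#' @return An `m x length(clones)` proportion matrix.
#' @export
simulate_proportions <- function(clones, m, concentration = 1) {
  U <- .rdirichlet_rows(m, length(clones), concentration)
  dimnames(U) <- list(paste0("sample_", seq_len(m)), clones)
  U
}

#' Perturb a proportion matrix with Dirichlet noise
#'
#' Each row becomes the convex mixture `(1 - h) * row + h * d` where `d`
#' is a fresh draw from the same symmetric Dirichlet; rows stay on the
#' simplex exactly. `h = 0` returns the input unchanged and `h = 1` pure
#' noise. Uses the current RNG state.
#'
#' @param U A proportion matrix.
#' @param h Noise level in `[0, 1]`.
#' @param concentration Dirichlet concentration of the noise draw.
#' @return A proportion matrix of the same shape.
#' @export
add_noise <- function(U, h, concentration = 1) {
  stopifnot(h >= 0, h <= 1)
  if (h == 0) return(U)
  D <- .rdirichlet_rows(nrow(U), ncol(U), concentration)
  out <- (1 - h) * U + h * D
  dimnames(out) <- dimnames(U)
  out
}

#' Simulate a complete ground-truth instance
#'
#' Three-step generation of an integration instance with known ground
#' truth: (1) grow a random integrated clone tree `T*` on `n1 + n2 - 1`
#' paired clones ([simulate_clone_tree()]) and collapse it to the two
#' input trees `T1`, `T2`; (2) draw ground-truth proportions `U*` from a
#' symmetric Dirichlet ([simulate_proportions()]); (3) project `U*` onto
#' each feature and perturb both projections with Dirichlet noise at level
#' `h` ([add_noise()]). At `h = 0` the inputs are exactly consistent with
#' the truth, so integration can recover it with zero correction.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulation_bundle` with elements `truth`
#'   (`clones`, `tree`, `proportions`), `inputs` (`tree1`, `props1`,
#'   `tree2`, `props2`) and `config`. Identical configs yield identical
#'   bundles.
#' @examples
#' bundle <- simulate_instance(simulation_config(3, 3, m = 2, h = 0, seed = 7))
#' bundle$truth$tree
#' @export
simulate_instance <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    tree <- simulate_clone_tree(config$n1, config$n2)
    T1 <- collapse_to_feature_tree(tree, 1)
    T2 <- collapse_to_feature_tree(tree, 2)
    U <- simulate_proportions(tree$vertices, config$m, config$concentration)
    U1 <- project_proportions(U, 1, as.character(seq_len(config$n1)))
    U2 <- project_proportions(U, 2, as.character(seq_len(config$n2)))
    structure(list(
      truth = list(clones = tree$vertices, tree = tree, proportions = U),
      inputs = list(tree1 = T1,
                    props1 = add_noise(U1, config$h, config$concentration),
                    tree2 = T2,
                    props2 = add_noise(U2, config$h, config$concentration)),
      config = config), class = "simulation_bundle")
  })
}

#' A 3-partition problem instance
#'
#' Container for instances of the NP-complete 3-partition problem: can a
#' multiset `A` of `3q` integers, each strictly between `B/4` and `B/2`
#' and summing to `B * q`, be split into `q` triples each summing to `B`?
#' Reductions from this problem generate adversarial integration
#' instances whose optima certify the solvers' exactness.
#'
#' @param A Integer multiset of length `3q`.
#' @param B Target sum per group.
#' @param known_partition Optional grouping `sigma` (integer vector in
#'   `[q]` per element) recorded for fixtures; validated to sum to `B` per
#'   group when given.
#' @return A list of class `three_partition_instance` with `A`, `B`, `q`.
#' @examples
#' three_partition_instance(c(11, 14, 15, 12, 13, 15), 40)
#' @export
three_partition_instance <- function(A, B, known_partition = NULL) {
  stopifnot(length(A) %% 3 == 0, length(A) >= 3)
  q <- length(A) %/% 3L
  if (any(A <= B / 4 | A >= B / 2)) {
    stop("every element must lie strictly inside (B/4, B/2)")
  }
  if (sum(A) != B * q) stop("elements must sum to B * q")
  if (!is.null(known_partition)) {
    stopifnot(length(known_partition) == length(A),
              all(known_partition %in% seq_len(q)))
    sums <- tapply(A, known_partition, sum)
    if (any(sums != B)) stop("known_partition groups do not each sum to B")
  }
  structure(list(A = as.integer(A), B = as.integer(B), q = q,
                 known_partition = known_partition),
            class = "three_partition_instance")
}

#' Reduce a 3-partition instance to a clone integration instance
#'
#' Builds the single-sample instance whose minimum integrated clone count
#' is `3q` exactly when the 3-partition instance is solvable: feature-1
#' clones `1..3q` with proportions `a_i / (B q)` and feature-2 clones
#' `1..q` with proportions `1/q` each.
#'
#' @param instance A [three_partition_instance()].
#' @return A list with proportion matrices `U1` and `U2`.
#' @export
reduce_3partition_to_pci <- function(instance) {
  stopifnot(inherits(instance, "three_partition_instance"))
  A <- instance$A; B <- instance$B; q <- instance$q
  U1 <- matrix(A / (B * q), 1L,
               dimnames = list("sample_1", as.character(seq_along(A))))
  U2 <- matrix(rep(1 / q, q), 1L,
               dimnames = list("sample_1", as.character(seq_len(q))))
  list(U1 = validate_proportion_matrix(U1),
       U2 = validate_proportion_matrix(U2))
}

#' Reduce a 3-partition instance to a clone tree integration instance
#'
#' Extends the clone integration reduction with a zero-proportion normal
#' clone `0` on each side and star clone trees rooted at it. A refinement
#' on `4q + 1` clones with zero total correction exists exactly when the
#' 3-partition instance is solvable.
#'
#' @param instance A [three_partition_instance()].
#' @return A list with `T1`, `U1`, `T2`, `U2`.
#' @export
reduce_3partition_to_pcti <- function(instance) {
  stopifnot(inherits(instance, "three_partition_instance"))
  base <- reduce_3partition_to_pci(instance)
  U1 <- cbind(`0` = 0, base$U1)
  U2 <- cbind(`0` = 0, base$U2)
  star <- function(leaves) clone_tree(cbind("0", leaves), root = "0")
  list(T1 = star(colnames(base$U1)), U1 = validate_proportion_matrix(U1),
       T2 = star(colnames(base$U2)), U2 = validate_proportion_matrix(U2))
}
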