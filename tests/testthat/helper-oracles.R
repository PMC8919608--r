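# Shared fixtures and independent oracles, built in code.

make_U <- function(vals, clones, samples = NULL) {
  U <- matrix(vals, ncol = length(clones), byrow = TRUE)
  rownames(U) <- if (is.null(samples)) paste0("s", seq_len(nrow(U))) else samples
  colnames(U) <- clones
  U
}

chain_tree <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 1L) return(clone_tree(vertices = labels))
  clone_tree(cbind(labels[-length(labels)], labels[-1L]))
}

star_tree <- function(root, leaves) {
  clone_tree(cbind(as.character(root), as.character(leaves)))
}

# Canonical key of a tree: its sorted directed edge list (root implied).
tree_key <- function(tree) {
  if (nrow(tree$edges) == 0L) return(tree$root)
  paste(sort(paste(tree$edges[, 1L], tree$edges[, 2L], sep = ">")),
        collapse = ";")
}

# Exhaustive refinement oracle: try every assignment of each input edge to
# a clone of the other feature, keep the candidates that form a valid
# refinement. Independent of the package's pruned DFS.
cartesian_refinements <- function(T1, T2) {
  kids1 <- T1$edges[, 2L]
  kids2 <- T2$edges[, 2L]
  par1 <- if (length(kids1)) setNames(T1$edges[, 1L], kids1)
  par2 <- if (length(kids2)) setNames(T2$edges[, 1L], kids2)
  choices <- c(rep(list(T2$vertices), length(kids1)),
               rep(list(T1$vertices), length(kids2)))
  if (length(choices) == 0L) {
    return(list(list(tree = clone_tree(
      vertices = paired_label(T1$root, T2$root)))))
  }
  grid <- do.call(expand.grid,
                  c(choices, list(stringsAsFactors = FALSE)))
  out <- list()
  for (g in seq_len(nrow(grid))) {
    row <- as.character(grid[g, ])
    phi1 <- row[seq_along(kids1)]
    phi2 <- row[length(kids1) + seq_along(kids2)]
    verts <- c(paired_label(T1$root, T2$root),
               if (length(kids1)) paired_label(kids1, phi1),
               if (length(kids2)) paired_label(phi2, kids2))
    if (anyDuplicated(verts)) next
    edges <- rbind(
      if (length(kids1)) cbind(paired_label(par1[kids1], phi1),
                               paired_label(kids1, phi1)),
      if (length(kids2)) cbind(paired_label(phi2, par2[kids2]),
                               paired_label(phi2, kids2)))
    if (!all(edges[, 1L] %in% verts)) next
    tree <- tryCatch(clone_tree(edges), error = function(e) NULL)
    if (is.null(tree)) next
    if (!check_refinement(tree, T1, T2)$pass) next
    out[[length(out) + 1L]] <- list(tree = tree)
  }
  out
}

# Grid-search oracle for the minimal single-sample correction on a small
# support (<= 3 clones): evaluate J on a simplex lattice.
grid_min_J <- function(pairs, a, b, step = 0.02) {
  k <- nrow(pairs)
  stopifnot(k <= 3L)
  Jof <- function(u) {
    p1 <- tapply(u, factor(pairs[, 1L], levels = names(a)), sum,
                 default = 0)
    p2 <- tapply(u, factor(pairs[, 2L], levels = names(b)), sum,
                 default = 0)
    sum(abs(p1 - a)) + sum(abs(p2 - b))
  }
  grid <- seq(0, 1, by = step)
  best <- Inf
  if (k == 1L) return(Jof(1))
  if (k == 2L) {
    for (x in grid) best <- min(best, Jof(c(x, 1 - x)))
    return(best)
  }
  for (x in grid) for (y in grid[grid <= 1 - x + 1e-12]) {
    best <- min(best, Jof(c(x, y, 1 - x - y)))
  }
  best
}

rand_dirichlet_U <- function(m, clones) {
  U <- matrix(rgamma(m * length(clones), 1), m)
  U <- U / rowSums(U)
  dimnames(U) <- list(paste0("s", seq_len(m)), clones)
  U
}
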