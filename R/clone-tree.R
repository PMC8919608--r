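#' Construct a rooted clone tree
#'
#' A clone tree is a rooted tree whose vertices are clone labels: the root
#' is the normal clone and each edge is a mutation event giving rise to the
#' child clone. The constructor validates that every non-root vertex has
#' exactly one parent, that there is a single root, and that all vertices
#' are reachable from it.
#'
#' @param edges A two-column character matrix or data frame of
#'   `parent -> child` edges, or `NULL` for a single-vertex tree.
#' @param vertices Optional character vector of vertex labels; required for
#'   a single-vertex tree, otherwise defaults to the labels appearing in
#'   `edges`.
#' @param root Optional root label; by default inferred as the unique
#'   vertex that never appears as a child.
#'
#' @return An object of class `clone_tree`: a list with elements
#'   `vertices` (character), `edges` (two-column character matrix with
#'   columns `parent`, `child`) and `root`.
#'
#' @examples
#' clone_tree(rbind(c("1", "2"), c("1", "3")))
#' clone_tree(vertices = "1") # single clone
#' @export
clone_tree <- function(edges = NULL, vertices = NULL, root = NULL) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      (is.data.frame(edges) && nrow(edges) == 0L)) {
    if (is.null(vertices) && is.null(root)) {
      stop("an edgeless clone tree needs its single vertex label")
    }
    if (is.null(vertices)) vertices <- root
    vertices <- as.character(vertices)
    if (length(vertices) != 1L) {
      stop("a clone tree without edges must have exactly one vertex")
    }
    edges <- matrix(character(0), 0L, 2L,
                    dimnames = list(NULL, c("parent", "child")))
    tree <- structure(list(vertices = vertices, edges = edges,
                           root = vertices),
                      class = "clone_tree")
    return(tree)
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child")))
  if (anyNA(edges) || any(edges == "")) stop("empty vertex label in edges")
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L], sep = "\r"))) {
    stop("duplicate edge")
  }
  verts <- unique(c(edges[, 1L], edges[, 2L], as.character(vertices)))
  dup_child <- edges[duplicated(edges[, 2L]), 2L]
  if (length(dup_child) > 0L) {
    stop(sprintf("vertex '%s' has more than one parent", dup_child[1L]))
  }
  roots <- setdiff(verts, edges[, 2L])
  if (length(roots) == 0L) stop("no root vertex: the edge set contains a cycle")
  if (length(roots) > 1L) {
    stop(sprintf("multiple root candidates: %s",
                 paste(sort(roots), collapse = ", ")))
  }
  if (!is.null(root) && root != roots) {
    stop(sprintf("declared root '%s' does not match inferred root '%s'",
                 root, roots))
  }
  # Reachability from the root: since every non-root vertex has one parent,
  # unreached vertices indicate a cycle detached from the root component.
  kids <- split(edges[, 2L], factor(edges[, 1L], levels = verts))
  seen <- stats::setNames(logical(length(verts)), verts)
  queue <- roots
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (seen[[v]]) next
    seen[[v]] <- TRUE
    queue <- c(queue, kids[[v]])
  }
  if (!all(seen)) {
    stop(sprintf("vertices not reachable from the root (cycle): %s",
                 paste(sort(names(seen)[!seen]), collapse = ", ")))
  }
  structure(list(vertices = verts, edges = edges, root = roots),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone tree: %d vertices, %d edges, root '%s'\n",
              length(x$vertices), nrow(x$edges), x$root))
  if (nrow(x$edges) > 0L) {
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L], collapse = "\n"),
        "\n")
  }
  invisible(x)
}

# Named parent lookup: parents[child] for every non-root vertex.
.tree_parents <- function(tree) {
  stats::setNames(tree$edges[, 1L], tree$edges[, 2L])
}

# Edges as "parent\rchild" keys for set arithmetic.
.edge_keys <- function(tree) {
  if (nrow(tree$edges) == 0L) return(character(0))
  paste(tree$edges[, 1L], tree$edges[, 2L], sep = "\r")
}

# Edges in root-down (BFS) order; used by solvers that need parents
# processed before children.
.edges_root_down <- function(tree) {
  if (nrow(tree$edges) == 0L) return(integer(0))
  depth <- stats::setNames(rep(NA_integer_, length(tree$vertices)),
                           tree$vertices)
  depth[tree$root] <- 0L
  parents <- .tree_parents(tree)
  for (v in names(parents)) {
    if (is.na(depth[[v]])) {
      chain <- v
      while (is.na(depth[[chain[1L]]]) && chain[1L] %in% names(parents)) {
        chain <- c(parents[[chain[1L]]], chain)
      }
      for (k in seq_along(chain)[-1L]) {
        depth[[chain[k]]] <- depth[[chain[k - 1L]]] + 1L
      }
    }
  }
  order(depth[tree$edges[, 2L]])
}

#' Check that a paired clone tree refines two input clone trees
#'
#' A tree `T` on paired clones refines input trees `T1` and `T2` when
#' (i) every edge of `T1` is realized by exactly one edge of `T` (with the
#' second coordinate held fixed), (ii) every edge of `T2` is realized by
#' exactly one edge of `T` (first coordinate fixed), and (iii) every edge
#' of `T` changes exactly one coordinate, along an edge of the
#' corresponding input tree. Equivalently, contracting the feature-2
#' changes of `T` yields `T1` and contracting the feature-1 changes yields
#' `T2`. The root of a refinement is the pair of input roots.
#'
#' @param T A `clone_tree` whose vertex labels are paired (`"i|j"`).
#' @param T1,T2 The two input `clone_tree`s.
#' @return A list with `pass` (logical) and `violations` (character vector
#'   describing each violated condition; empty when `pass` is `TRUE`).
#' @examples
#' T1 <- clone_tree(rbind(c("1", "2")))
#' T2 <- clone_tree(rbind(c("1", "2")))
#' T <- clone_tree(rbind(c("1|1", "1|2"), c("1|2", "2|2")))
#' check_refinement(T, T1, T2)$pass # TRUE
#' @export
check_refinement <- function(T, T1, T2) {
  viol <- character(0)
  comp <- .split_pairs(T$vertices)
  bad_v <- !(comp[, 1L] %in% T1$vertices & comp[, 2L] %in% T2$vertices)
  if (any(bad_v)) {
    viol <- c(viol, sprintf("vertex (%s) not in V(T1) x V(T2)",
                            T$vertices[bad_v]))
  }
  expected_root <- paired_label(T1$root, T2$root)
  if (T$root != expected_root) {
    viol <- c(viol, sprintf("root is (%s), expected (%s)",
                            T$root, expected_root))
  }
  e1_keys <- .edge_keys(T1)
  e2_keys <- .edge_keys(T2)
  realized1 <- stats::setNames(integer(length(e1_keys)), e1_keys)
  realized2 <- stats::setNames(integer(length(e2_keys)), e2_keys)
  if (nrow(T$edges) > 0L) {
    pc <- .split_pairs(T$edges[, 1L])
    cc <- .split_pairs(T$edges[, 2L])
    for (k in seq_len(nrow(T$edges))) {
      i <- pc[k, 1L]; j <- pc[k, 2L]
      i2 <- cc[k, 1L]; j2 <- cc[k, 2L]
      lbl <- sprintf("(%s)->(%s)", T$edges[k, 1L], T$edges[k, 2L])
      if (i != i2 && j != j2) {
        viol <- c(viol, sprintf(
          "condition (iii): edge %s changes both coordinates", lbl))
      } else if (i == i2 && j == j2) {
        viol <- c(viol, sprintf("condition (iii): edge %s changes nothing",
                                lbl))
      } else if (j == j2) {
        key <- paste(i, i2, sep = "\r")
        if (!key %in% e1_keys) {
          viol <- c(viol, sprintf(
            "condition (iii): edge %s uses (%s,%s) which is not in E(T1)",
            lbl, i, i2))
        } else realized1[[key]] <- realized1[[key]] + 1L
      } else {
        key <- paste(j, j2, sep = "\r")
        if (!key %in% e2_keys) {
          viol <- c(viol, sprintf(
            "condition (iii): edge %s uses (%s,%s) which is not in E(T2)",
            lbl, j, j2))
        } else realized2[[key]] <- realized2[[key]] + 1L
      }
    }
  }
  off1 <- realized1 != 1L
  if (any(off1)) {
    viol <- c(viol, sprintf(
      "condition (i): edge (%s) of T1 realized %d times (expected 1)",
      gsub("\r", ",", names(realized1)[off1]), realized1[off1]))
  }
  off2 <- realized2 != 1L
  if (any(off2)) {
    viol <- c(viol, sprintf(
      "condition (ii): edge (%s) of T2 realized %d times (expected 1)",
      gsub("\r", ",", names(realized2)[off2]), realized2[off2]))
  }
  list(pass = length(viol) == 0L, violations = viol)
}
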