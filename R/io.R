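# TSV dialects: a proportion matrix is a tab-separated table whose first
# column is "sample" and whose remaining headers are clone labels; a clone
# tree is a two-column "parent<TAB>child" edge list (a single-vertex tree
# is one line holding just the vertex label). Paired clones serialize as
# "i|j", which is why "|" is reserved and rejected in input labels.

#' Read and write proportion matrices
#'
#' @param path File path of a tab-separated table with first column
#'   `sample` and one column per clone.
#' @param tolerance,renormalize Passed to [validate_proportion_matrix()].
#' @param paired If `TRUE`, clone labels are paired (`"i|j"`) and the `|`
#'   character is allowed (used when reading back solution matrices).
#' @return `read_proportion_matrix()`: a validated proportion matrix.
#' @export
read_proportion_matrix <- function(path, tolerance = 1e-6,
                                   renormalize = FALSE, paired = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2L || names(df)[1L] != "sample") {
    stop(sprintf("'%s': expected a header starting with 'sample'", path))
  }
  for (col in names(df)[-1L]) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(x) && !anyNA(df[[col]])) {
      stop(sprintf("'%s': non-numeric entries in column '%s'", path, col))
    }
    df[[col]] <- x
  }
  clones <- names(df)[-1L]
  if (!paired && any(grepl("|", clones, fixed = TRUE))) {
    stop(sprintf("'%s': clone labels must not contain '|'", path))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$sample
  validate_proportion_matrix(vals, tolerance = tolerance,
                             renormalize = renormalize)
}

#' @rdname read_proportion_matrix
#' @param U A proportion matrix.
#' @export
write_proportion_matrix <- function(U, path) {
  df <- data.frame(sample = rownames(U), check.names = FALSE)
  for (cl in colnames(U)) df[[cl]] <- sprintf("%.12g", U[, cl])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write clone trees as edge lists
#'
#' @param path File path: a two-column tab-separated `parent child` edge
#'   list without header, or a single line with one label for a
#'   single-vertex tree. The root is inferred as the unique vertex never
#'   appearing as a child.
#' @param paired If `TRUE`, vertex labels are paired (`"i|j"`) and the
#'   `|` character is allowed.
#' @return `read_clone_tree()`: a `clone_tree`.
#' @export
read_clone_tree <- function(path, paired = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("'%s': empty tree file", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(lines) == 1L && nf == 1L) {
    v <- trimws(fields[[1L]])
    if (!paired && grepl("|", v, fixed = TRUE)) {
      stop(sprintf("'%s': clone labels must not contain '|'", path))
    }
    return(clone_tree(vertices = v))
  }
  bad <- which(nf != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("'%s' line %d: expected 'parent<TAB>child'", path, bad[1L]))
  }
  edges <- t(vapply(fields, trimws, character(2)))
  if (!paired && any(grepl("|", edges, fixed = TRUE))) {
    stop(sprintf("'%s': clone labels must not contain '|'", path))
  }
  clone_tree(edges)
}

#' @rdname read_clone_tree
#' @param tree A `clone_tree`.
#' @export
write_clone_tree <- function(tree, path) {
  if (nrow(tree$edges) == 0L) {
    writeLines(tree$root, path)
  } else {
    utils::write.table(tree$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write an integration solution to a directory
#'
#' Serializes a [solve_pci()] or [solve_pcti()] result: `clones.txt` (one
#' paired label per line), `proportions.tsv` (the integrated proportion
#' matrix), for tree-aware solutions `tree.tsv` (edge list with `"i|j"`
#' vertices) and `corrections.tsv` (per sample and input clone signed
#' deviations of the solution's marginals from the inputs), and
#' `manifest.json` recording the objective and solver status.
#'
#' @param solution A `pci_solution` or `pcti_solution`.
#' @param dir Output directory (created if needed).
#' @param U1,U2 Optional input matrices; when given, the correction table
#'   and recomputed objective are included in the output.
#' @return Invisibly, the vector of files written.
#' @export
write_solution <- function(solution, dir, U1 = NULL, U2 = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "clones.txt")
  writeLines(solution$clones, f)
  files <- c(files, f)
  f <- file.path(dir, "proportions.tsv")
  write_proportion_matrix(solution$proportions, f)
  files <- c(files, f)
  is_pcti <- inherits(solution, "pcti_solution")
  if (is_pcti) {
    f <- file.path(dir, "tree.tsv")
    write_clone_tree(solution$tree, f)
    files <- c(files, f)
  }
  manifest <- list(
    solution_class = class(solution)[1L],
    n_clones = length(solution$clones),
    objective = if (is_pcti) solution$total_correction else solution$objective,
    optimal = isTRUE(solution$optimal),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  if (!is.null(U1) && !is.null(U2)) {
    manifest$recomputed_correction <-
      consistency_error(solution$proportions, U1, U2)
    P1 <- project_proportions(solution$proportions, 1, colnames(U1))
    P2 <- project_proportions(solution$proportions, 2, colnames(U2))
    corr <- rbind(
      data.frame(feature = 1L, sample = rep(rownames(U1), ncol(U1)),
                 clone = rep(colnames(U1), each = nrow(U1)),
                 deviation = as.vector(P1 - U1[rownames(P1), , drop = FALSE])),
      data.frame(feature = 2L, sample = rep(rownames(U2), ncol(U2)),
                 clone = rep(colnames(U2), each = nrow(U2)),
                 deviation = as.vector(P2 - U2[rownames(P2), , drop = FALSE])))
    f <- file.path(dir, "corrections.tsv")
    utils::write.table(corr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
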