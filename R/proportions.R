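#' Validate (and optionally renormalize) a clone proportion matrix
#'
#' A proportion matrix for `n` clones over `m` samples has nonnegative
#' entries and unit row sums: row `p` gives the fraction of cells of sample
#' `p` belonging to each clone. This is the container for the per-feature
#' inputs `U1`, `U2` as well as integrated proportions `U`.
#'
#' @param raw A numeric matrix or data frame; rows are samples, columns are
#'   clones. Row and column names are used as sample and clone labels; if
#'   absent, labels `sample_1, ...` and `1, 2, ...` are filled in.
#' @param tolerance Maximum allowed absolute deviation of a row sum from 1.
#' @param renormalize If `TRUE`, rows whose sums deviate from 1 by at most
#'   `tolerance` are rescaled to sum to exactly 1.
#'
#' @return A validated numeric matrix with unique `rownames` (samples) and
#'   `colnames` (clones).
#'
#' @examples
#' validate_proportion_matrix(rbind(c(0.5, 0.5), c(0.2, 0.8)))
#'
#' @export
validate_proportion_matrix <- function(raw, tolerance = 1e-6,
                                       renormalize = FALSE) {
  if (is.data.frame(raw)) raw <- as.matrix(raw)
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("`raw` must be a numeric matrix or data frame")
  }
  if (nrow(raw) < 1L || ncol(raw) < 1L) {
    stop("proportion matrix must have at least one sample and one clone")
  }
  if (is.null(rownames(raw))) {
    rownames(raw) <- paste0("sample_", seq_len(nrow(raw)))
  }
  if (is.null(colnames(raw))) colnames(raw) <- as.character(seq_len(ncol(raw)))
  if (anyDuplicated(rownames(raw))) stop("duplicate sample labels")
  if (anyDuplicated(colnames(raw))) stop("duplicate clone labels")
  if (anyNA(raw)) stop("proportion matrix contains missing values")
  neg <- which(raw < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative proportion for sample '%s', clone '%s'",
                 rownames(raw)[neg[1L, 1L]], colnames(raw)[neg[1L, 2L]]))
  }
  rs <- rowSums(raw)
  off <- which(abs(rs - 1) > tolerance)
  if (length(off) > 0L) {
    stop(sprintf("row sum %.8g of sample '%s' deviates from 1 by more than %g",
                 rs[off[1L]], rownames(raw)[off[1L]], tolerance))
  }
  if (renormalize) raw <- raw / rs
  raw
}

#' Support of a proportion matrix
#'
#' The support `S(U)` is the number of clones with nonzero proportion in at
#' least one sample. Any integrated clone set must contain at least
#' `max(S(U1), S(U2))` paired clones, which is the lower bound used by the
#' exact solvers.
#'
#' @param U A proportion matrix (see [validate_proportion_matrix()]).
#' @return Integer count of clones with positive total proportion.
#' @examples
#' support(matrix(c(0.5, 0.5, 0), 1)) # 2
#' @export
support <- function(U) {
  sum(colSums(U) > 0)
}

.split_pairs <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop(sprintf("'%s' is not a paired clone label of the form \"i|j\"",
                 labels[which(bad)[1L]]))
  }
  cbind(first = vapply(parts, `[[`, "", 1L),
        second = vapply(parts, `[[`, "", 2L))
}

#' Build and split paired clone labels
#'
#' Integrated clones are pairs `(i, j)` of a feature-1 clone `i` and a
#' feature-2 clone `j`, serialized as the string `"i|j"`. `paired_label()`
#' builds such labels and `paired_components()` recovers the two
#' coordinates (the projections onto each feature's clone set).
#'
#' @param first,second Clone labels in the first/second feature's clone set.
#' @param labels Character vector of `"i|j"` paired labels.
#' @return `paired_label()`: character vector of labels.
#'   `paired_components()`: a two-column character matrix with columns
#'   `first` and `second`.
#' @examples
#' paired_label("2", "1")
#' paired_components(c("1|1", "2|1"))
#' @export
paired_label <- function(first, second) {
  if (any(grepl("|", c(first, second), fixed = TRUE))) {
    stop("clone labels must not contain the reserved character '|'")
  }
  paste0(first, "|", second)
}

#' @rdname paired_label
#' @export
paired_components <- function(labels) {
  .split_pairs(labels)
}

#' Project integrated clone proportions onto one feature's clones
#'
#' Sums the columns of `U` over all paired clones sharing the same
#' coordinate in the chosen feature, i.e. computes the marginal proportion
#' matrix over the feature-1 clones (`feature = 1`) or feature-2 clones
#' (`feature = 2`). Target clones absent from every pair get a zero column.
#'
#' @param U Proportion matrix whose columns are paired clone labels
#'   (`"i|j"`).
#' @param feature 1 or 2: which coordinate to project onto.
#' @param target_clones Optional character vector fixing the output clone
#'   set and column order; defaults to the coordinates present in `U`, in
#'   order of first appearance.
#' @return Proportion matrix over the target clones (same samples).
#' @examples
#' U <- matrix(c(0.2, 0.3, 0.5), 1, dimnames = list("s1", c("1|1", "1|2", "2|2")))
#' project_proportions(U, 1) # 0.5, 0.5
#' project_proportions(U, 2) # 0.2, 0.8
#' @export
project_proportions <- function(U, feature, target_clones = NULL) {
  stopifnot(feature %in% c(1, 2))
  coords <- .split_pairs(colnames(U))[, feature]
  if (is.null(target_clones)) target_clones <- unique(coords)
  out <- matrix(0, nrow(U), length(target_clones),
                dimnames = list(rownames(U), target_clones))
  for (k in seq_along(coords)) {
    cl <- coords[k]
    if (!cl %in% target_clones) {
      stop(sprintf("clone '%s' of feature %d is not in `target_clones`",
                   cl, feature))
    }
    out[, cl] <- out[, cl] + U[, k]
  }
  out
}

#' Total absolute deviation of a solution's projections from the inputs
#'
#' Computes the correction objective
#' \deqn{J(U, U_1, U_2) = \sum_{p,i} |u^{(1)}_{p,i} - \sum_{\ell:\pi_1(\ell)=i} u_{p,\ell}|
#'   + \sum_{p,j} |u^{(2)}_{p,j} - \sum_{\ell:\pi_2(\ell)=j} u_{p,\ell}|,}
#' the sum over samples and clones of the entrywise absolute deviations of
#' both marginals of `U` from `U1` and `U2`. It is zero exactly when `U` is
#' consistent with the inputs.
#'
#' @param U Proportion matrix over paired clones (`"i|j"` columns).
#' @param U1,U2 Input proportion matrices for the two feature classes; their
#'   column sets define the projection targets. All three matrices must
#'   share the same sample set.
#' @return Nonnegative total deviation.
#' @examples
#' U <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("1|1", "2|2")))
#' U1 <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("1", "2")))
#' U2 <- matrix(c(0.6, 0.4), 1, dimnames = list("s1", c("1", "2")))
#' consistency_error(U, U1, U2) # 0.2
#' @export
consistency_error <- function(U, U1, U2) {
  .check_same_samples(U1, U2)
  .check_same_samples(U, U1)
  U1 <- U1[rownames(U), , drop = FALSE]
  U2 <- U2[rownames(U), , drop = FALSE]
  P1 <- project_proportions(U, 1, colnames(U1))
  P2 <- project_proportions(U, 2, colnames(U2))
  sum(abs(P1 - U1)) + sum(abs(P2 - U2))
}

.check_same_samples <- function(A, B) {
  if (!setequal(rownames(A), rownames(B))) {
    stop("proportion matrices have different sample sets")
  }
  invisible(TRUE)
}
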