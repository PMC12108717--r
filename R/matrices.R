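#' Validate a binary drug-disease association matrix
#'
#' An association matrix records known drug-disease links: rows are drugs,
#' columns are diseases, and entry `A[i, j]` is 1 when drug i is known to
#' treat disease j and 0 otherwise (0 means "unknown", not "known absent").
#' Every entry must be exactly 0 or 1 and the row/column identifiers must be
#' unique.  Identifiers are added (`drug1..n`, `disease1..m`) when missing.
#'
#' @param A Numeric matrix with entries in `{0, 1}`.  Row names are drug
#'   identifiers, column names disease identifiers.
#' @return The validated matrix, with dimnames guaranteed.
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("DB01235", "DB00997"), c("168600", "114480")))
#' validate_association(A)
#' @export
validate_association <- function(A) {
  check_finite_matrix(A, "A")
  bad <- which(A != 0 & A != 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    rid <- if (is.null(rownames(A))) as.character(i) else rownames(A)[i]
    cid <- if (is.null(colnames(A))) as.character(j) else colnames(A)[j]
    stop(sprintf(
      "association matrix must be binary; entry [%s, %s] is %s",
      rid, cid, format(A[i, j])), call. = FALSE)
  }
  if (is.null(rownames(A))) rownames(A) <- default_ids("drug", nrow(A))
  if (is.null(colnames(A))) colnames(A) <- default_ids("disease", ncol(A))
  if (anyDuplicated(rownames(A))) {
    stop("duplicated drug identifiers in association matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(A))) {
    stop("duplicated disease identifiers in association matrix", call. = FALSE)
  }
  A
}

#' Canonicalize a similarity matrix
#'
#' Brings a square similarity matrix into the canonical form required by the
#' model: symmetrized as `(S + t(S)) / 2`, negative entries clipped to 0
#' (non-negativity keeps the multiplicative-update numerators non-negative),
#' and the diagonal set to 1, the conventional self-similarity.  The
#' operation is idempotent.
#'
#' @param S Square numeric matrix of similarities.
#' @param report If `TRUE`, attach an attribute `"changes"` (character
#'   vector) describing what was altered.
#' @return The canonicalized matrix.
#' @examples
#' S <- matrix(c(1, 0.4, 0.5, 1), 2, 2)
#' canonicalize_similarity(S)   # symmetrized to 0.45 off-diagonal
#' @export
canonicalize_similarity <- function(S, report = FALSE) {
  check_finite_matrix(S, "S")
  if (nrow(S) != ncol(S)) {
    stop(sprintf("similarity matrix must be square; got %d x %d",
                 nrow(S), ncol(S)), call. = FALSE)
  }
  changes <- character(0)
  asym <- max(abs(S - t(S)))
  if (asym > 0) {
    changes <- c(changes, sprintf(
      "symmetrized (max asymmetry %.3g)", asym))
  }
  out <- (S + t(S)) / 2
  nneg <- sum(out < 0)
  if (nneg > 0L) {
    changes <- c(changes, sprintf("clipped %d negative entries to 0", nneg))
    out[out < 0] <- 0
  }
  dmax <- max(abs(diag(out) - 1))
  if (dmax > 0) {
    changes <- c(changes, sprintf(
      "set diagonal to 1 (max change %.3g)", dmax))
  }
  diag(out) <- 1
  if (!is.null(rownames(S))) dimnames(out) <- dimnames(S)
  if (report) attr(out, "changes") <- changes
  out
}

#' Validate a canonical similarity matrix
#'
#' Checks the invariants a similarity matrix must satisfy after
#' [canonicalize_similarity()]: square, symmetric within `tol`, all entries
#' non-negative, unit diagonal.
#'
#' @param S Square numeric matrix.
#' @param tol Absolute symmetry tolerance (default `1e-8`).
#' @return `S`, invisibly, if valid; otherwise an error.
#' @export
validate_similarity <- function(S, tol = 1e-8) {
  check_finite_matrix(S, "S")
  if (nrow(S) != ncol(S)) {
    stop(sprintf("similarity matrix must be square; got %d x %d",
                 nrow(S), ncol(S)), call. = FALSE)
  }
  if (max(abs(S - t(S))) > tol) {
    stop("similarity matrix is not symmetric within tolerance; ",
         "run canonicalize_similarity() first", call. = FALSE)
  }
  if (any(S < 0)) {
    stop("similarity matrix has negative entries; ",
         "run canonicalize_similarity() first", call. = FALSE)
  }
  if (max(abs(diag(S) - 1)) > tol) {
    stop("similarity matrix diagonal is not 1; ",
         "run canonicalize_similarity() first", call. = FALSE)
  }
  invisible(S)
}
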