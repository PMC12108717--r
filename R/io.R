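# Labeled-matrix and prediction-table I/O.  All matrices travel as
# delimited text: first row = column identifiers, first column = row
# identifiers, TSV by default with comma accepted.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a labeled matrix from delimited text
#'
#' Reads a TSV or CSV matrix whose first row holds column identifiers and
#' first column holds row identifiers.  Association matrices are validated
#' as strictly binary; similarity matrices must be square and are
#' canonicalized ([canonicalize_similarity()]) with a warning describing
#' any change made.
#'
#' @param path File path.
#' @param kind `"association"` or `"similarity"`.
#' @param orientation For association matrices: `"drugs-rows"` (default)
#'   or `"diseases-rows"`; the latter transposes on read, accommodating
#'   sources that store the matrix as diseases x drugs.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @return A named numeric matrix.
#' @export
read_labeled_matrix <- function(path, kind = c("association", "similarity"),
                                orientation = c("drugs-rows",
                                                "diseases-rows"),
                                sep = NULL) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  non_num <- !vapply(df, is.numeric, logical(1))
  if (any(non_num)) {
    j <- which(non_num)[1L]
    i <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1L]
    if (is.na(i)) i <- 1L
    stop(sprintf("non-numeric value at row '%s', column '%s' in %s",
                 rownames(df)[i], colnames(df)[j], path), call. = FALSE)
  }
  M <- as.matrix(df)
  if (kind == "association") {
    if (orientation == "diseases-rows") M <- t(M)
    validate_association(M)
  } else {
    if (nrow(M) != ncol(M)) {
      stop(sprintf("similarity matrix in %s must be square; got %d x %d",
                   path, nrow(M), ncol(M)), call. = FALSE)
    }
    out <- canonicalize_similarity(M, report = TRUE)
    changes <- attr(out, "changes")
    if (length(changes) > 0L) {
      warning(sprintf("similarity matrix %s canonicalized: %s",
                      path, paste(changes, collapse = "; ")),
              call. = FALSE)
    }
    attr(out, "changes") <- NULL
    out
  }
}

#' Write a labeled matrix as delimited text
#'
#' Counterpart of [read_labeled_matrix()]; numbers are written with full
#' double precision so a write/read round trip is lossless to within
#' formatting tolerance.
#'
#' @param x Named numeric matrix.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(x, path, sep = "\t") {
  check_finite_matrix(x, "x")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("matrix must have row and column identifiers", call. = FALSE)
  }
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, col.names = NA)
  invisible(path)
}

#' Align similarity matrices to an association matrix
#'
#' Reorders (and if necessary subsets) the drug and disease similarity
#' matrices so their identifiers match the association matrix's row and
#' column order exactly, the alignment the model requires.
#'
#' @param A Binary association matrix with identifiers.
#' @param Sd Drug similarity matrix whose ids are a superset of `A`'s
#'   drugs.
#' @param Se Disease similarity matrix whose ids are a superset of `A`'s
#'   diseases.
#' @param provenance Optional free-text note recording where the data came
#'   from.
#' @return An object of class `"bc_bundle"`: a list with aligned `A`,
#'   `Sd`, `Se` and the `provenance` note.
#' @export
align_bundle <- function(A, Sd, Se, provenance = "") {
  A <- validate_association(A)
  align_one <- function(S, ids, what) {
    if (is.null(rownames(S)) || is.null(colnames(S))) {
      stop(sprintf("%s similarity matrix has no identifiers", what),
           call. = FALSE)
    }
    missing <- setdiff(ids, rownames(S))
    if (length(missing) > 0L) {
      stop(sprintf("%s similarity matrix is missing: %s", what,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    S[ids, ids, drop = FALSE]
  }
  structure(list(A = A,
                 Sd = align_one(Sd, rownames(A), "drug"),
                 Se = align_one(Se, colnames(A), "disease"),
                 provenance = provenance),
            class = "bc_bundle")
}

#' Write a ranked-prediction table
#'
#' Writes per-drug candidate rankings (see [rank_all_candidates()]) as TSV
#' with columns `drug_id`, `disease_id`, `score`, `rank`; scores are
#' formatted with 6 significant digits.  An empty ranking produces a
#' header-only file.  [read_predictions()] round-trips the output.
#'
#' @param ranked data.frame with columns `drug_id`, `disease_id`, `score`,
#'   `rank`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ranked, path) {
  need <- c("drug_id", "disease_id", "score", "rank")
  if (!is.data.frame(ranked) || !all(need %in% names(ranked))) {
    stop("ranked must be a data.frame with columns drug_id, disease_id, ",
         "score, rank", call. = FALSE)
  }
  out <- ranked[, need, drop = FALSE]
  out$score <- sprintf("%.6g", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ranked-prediction table
#'
#' @param path TSV written by [write_predictions()].
#' @return data.frame with columns `drug_id`, `disease_id`, `score`,
#'   `rank`.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric",
                                   "integer"),
                    stringsAsFactors = FALSE)
}

#' Write run metadata beside an output
#'
#' Records the seed, hyperparameters and MD5 hashes of the input files as
#' JSON so any run can be reproduced and its inputs verified.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used for the run.
#' @param hyperparameters Named list of hyperparameter values.
#' @param inputs Character vector of input file paths to hash (optional).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, seed, hyperparameters = list(),
                               inputs = character(0)) {
  meta <- list(seed = seed,
               hyperparameters = hyperparameters,
               input_md5 = as.list(tools::md5sum(inputs)),
               timestamp = format(Sys.time(), tz = "UTC",
                                  "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
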