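#' Rank candidate diseases for one drug
#'
#' The candidate pool for a drug is the set of diseases with no known
#' association (`A[drug, ] == 0`); known links are excluded.  Candidates
#' are ranked by descending predicted score, with ties broken
#' deterministically by lexicographic disease identifier.
#'
#' @param scores n x m score matrix (see [predict.bcnmf()]), with dimnames.
#' @param A The binary association matrix the model was fitted to, with the
#'   same dimnames.
#' @param drug_id Drug identifier (a row name of `A`).
#' @param top_k Maximum number of candidates to return (default 5, the
#'   usual shortlist length for case studies).
#' @return A data.frame with columns `disease_id`, `score`, `rank`, at most
#'   `top_k` rows.  A drug whose associations are all known yields zero
#'   rows.
#' @examples
#' sim <- simulate_bundle(n = 20, m = 15, k_true = 3, density = 0.2,
#'                        sim_noise = 0, seed = 2)
#' fit <- bcnmf(sim$bundle$A, sim$bundle$Sd, sim$bundle$Se, k = 3,
#'              max_iter = 100, seed = 1)
#' rank_candidates(predict(fit), sim$bundle$A, rownames(sim$bundle$A)[1])
#' @export
rank_candidates <- function(scores, A, drug_id, top_k = 5) {
  A <- validate_association(A)
  check_finite_matrix(scores, "scores")
  if (!identical(dim(scores), dim(A))) {
    stop("scores and A must have identical dimensions", call. = FALSE)
  }
  top_k <- check_count(top_k, "top_k")
  if (length(drug_id) != 1L || !drug_id %in% rownames(A)) {
    stop(sprintf("drug '%s' not found in the association matrix",
                 as.character(drug_id)[1L]), call. = FALSE)
  }
  unknown <- which(A[drug_id, ] == 0)
  ids <- colnames(A)[unknown]
  sc <- scores[drug_id, unknown]
  ord <- order(-sc, ids, method = "radix")
  keep <- head(ord, top_k)
  data.frame(disease_id = ids[keep],
             score = as.numeric(sc[keep]),
             rank = seq_along(keep),
             stringsAsFactors = FALSE)
}

#' Rank candidates for every drug
#'
#' Applies [rank_candidates()] to each row of the score matrix and stacks
#' the results, the layout used for prediction tables (drug, disease,
#' score, rank).
#'
#' @inheritParams rank_candidates
#' @return A data.frame with columns `drug_id`, `disease_id`, `score`,
#'   `rank`.
#' @export
rank_all_candidates <- function(scores, A, top_k = 5) {
  A <- validate_association(A)
  out <- lapply(rownames(A), function(d) {
    r <- rank_candidates(scores, A, d, top_k)
    if (nrow(r) == 0L) return(NULL)
    cbind(data.frame(drug_id = d, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(drug_id = character(0), disease_id = character(0),
                      score = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
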