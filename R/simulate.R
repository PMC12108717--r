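#' Generate a planted-structure synthetic benchmark
#'
#' Builds a drug-disease benchmark with known ground truth, emulating the
#' structure of the gold-standard repositioning datasets: a sparse binary
#' association matrix with planted low-rank structure, and similarity
#' matrices consistent (up to noise) with the planted latent factors.
#'
#' Ground-truth factors `X*` (k_true x n) and `Y*` (k_true x m) are drawn
#' i.i.d. as the 6th power of uniform(0, 1) deviates — a right-skewed
#' distribution making each drug or disease load mostly on a few latent
#' components, as real entities belong to a few functional categories —
#' and column-normalized to unit Euclidean norm, so the Gram matrices are
#' cosine similarities with unit diagonal and off-diagonal entries in
#' [0, 1].  (Dense uniform loadings would make `t(X*) %*% Y*` effectively
#' rank one, and its top-density binarization would carry almost no
#' recoverable planted structure.)  The association matrix sets
#' `A = 1` on exactly the top `density * n * m` cells of `t(X*) %*% Y*`
#' (ties broken by cell index), making the positive count exact.
#' Similarities are `Sd = canonicalize(t(X*) %*% X* + E)` and analogously
#' for `Se`, where `E` is a symmetric Gaussian perturbation with standard
#' deviation `sim_noise` (upper triangle drawn, then mirrored; the
#' diagonal is untouched and reset to 1 by canonicalization).
#'
#' Randomness is drawn in the fixed order X*, Y*, Sd-noise, Se-noise, so
#' the association matrix is identical across `sim_noise` settings at a
#' given seed — noise sweeps are matched experiments.
#'
#' @param n Number of drugs.
#' @param m Number of diseases.
#' @param k_true Planted latent rank; must be `< min(n, m)`.
#' @param density Fraction of cells set to 1, in (0, 1).
#' @param sim_noise Standard deviation of the similarity perturbation
#'   (>= 0; 0 gives similarities exactly consistent with the factors).
#' @param seed Integer seed; the generator is deterministic given the
#'   seed and leaves the caller's RNG state untouched.
#' @return An object of class `"bc_synthetic"`: a list with `bundle`
#'   (a `"bc_bundle"` holding `A`, `Sd`, `Se`), `factors` (the planted
#'   `X`, `Y`), `positives` (data.frame of planted-positive cells with
#'   ids and indices), and `spec` (the generating parameters).
#' @examples
#' sim <- simulate_bundle(n = 50, m = 40, k_true = 4, density = 0.1,
#'                        sim_noise = 0, seed = 7)
#' sum(sim$bundle$A)  # exactly 200 planted links
#' @export
simulate_bundle <- function(n = 100, m = 80, k_true = 8, density = 0.1,
                            sim_noise = 0, seed = 1) {
  n <- check_count(n, "n", lower = 2L)
  m <- check_count(m, "m", lower = 2L)
  k_true <- check_count(k_true, "k_true")
  if (k_true >= min(n, m)) {
    stop(sprintf("k_true = %d must be < min(n, m) = %d",
                 k_true, min(n, m)), call. = FALSE)
  }
  density <- check_scalar_number(density, "density", lower = 0,
                                 strict = TRUE)
  if (density >= 1) stop("`density` must be < 1", call. = FALSE)
  sim_noise <- check_scalar_number(sim_noise, "sim_noise", lower = 0)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  npos <- round(density * n * m)
  if (npos < 1L) {
    stop("density too small: no positive cells would be planted",
         call. = FALSE)
  }

  unit_cols <- function(M) sweep(M, 2L, sqrt(colSums(M^2)), "/")
  sym_noise <- function(q, sd) {
    E <- matrix(0, q, q)
    ut <- upper.tri(E)
    E[ut] <- stats::rnorm(sum(ut), 0, sd)
    E + t(E)
  }

  out <- with_seed(seed, {
    X <- unit_cols(matrix(stats::runif(k_true * n)^6, k_true, n))
    Y <- unit_cols(matrix(stats::runif(k_true * m)^6, k_true, m))
    Sd <- crossprod(X)
    Se <- crossprod(Y)
    if (sim_noise > 0) {
      Sd <- Sd + sym_noise(n, sim_noise)
      Se <- Se + sym_noise(m, sim_noise)
    }
    list(X = X, Y = Y, Sd = Sd, Se = Se)
  })

  drug_ids <- sprintf("DR%04d", seq_len(n))
  disease_ids <- sprintf("DI%04d", seq_len(m))
  scores <- crossprod(out$X, out$Y)
  v <- as.vector(scores)
  top <- order(-v, seq_along(v))[seq_len(npos)]   # ties broken by cell index
  A <- matrix(0, n, m, dimnames = list(drug_ids, disease_ids))
  A[top] <- 1
  Sd <- canonicalize_similarity(out$Sd)
  Se <- canonicalize_similarity(out$Se)
  dimnames(Sd) <- list(drug_ids, drug_ids)
  dimnames(Se) <- list(disease_ids, disease_ids)
  colnames(out$X) <- drug_ids
  colnames(out$Y) <- disease_ids

  idx <- arrayInd(top, dim(A))
  positives <- data.frame(drug_id = drug_ids[idx[, 1L]],
                          disease_id = disease_ids[idx[, 2L]],
                          row = idx[, 1L], col = idx[, 2L],
                          stringsAsFactors = FALSE)

  structure(list(
    bundle = structure(list(A = A, Sd = Sd, Se = Se,
                            provenance = sprintf(
                              "synthetic planted-structure benchmark (seed %d)",
                              seed)),
                       class = "bc_bundle"),
    factors = list(X = out$X, Y = out$Y),
    positives = positives,
    spec = list(n = n, m = m, k_true = k_true, density = density,
                sim_noise = sim_noise, seed = seed)
  ), class = "bc_synthetic")
}
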