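#' Partition known associations into cross-validation folds
#'
#' Randomly partitions the positive cells of the association matrix
#' (`A == 1`) into `n_folds` folds of as equal size as possible (sizes
#' differ by at most one).  The partition is deterministic given `seed`.
#'
#' @param A Binary association matrix.
#' @param n_folds Number of folds (>= 2); must not exceed the number of
#'   positives.
#' @param seed Integer seed for the random assignment.
#' @return An object of class `"bc_cv_plan"`: a list with `n_folds`,
#'   `cells` (a p x 2 matrix of positive-cell row/column indices), `fold`
#'   (fold index per positive cell), and `seed`.
#' @export
make_folds <- function(A, n_folds = 10, seed = 1) {
  A <- validate_association(A)
  n_folds <- check_count(n_folds, "n_folds", lower = 2L)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  cells <- which(A == 1, arr.ind = TRUE)
  p <- nrow(cells)
  if (p < n_folds) {
    stop(sprintf("only %d known associations but %d folds requested",
                 p, n_folds), call. = FALSE)
  }
  fold <- integer(p)
  perm <- with_seed(seed, sample.int(p))
  fold[perm] <- rep(seq_len(n_folds), length.out = p)
  structure(list(n_folds = n_folds, cells = unname(cells), fold = fold,
                 seed = seed),
            class = "bc_cv_plan")
}

#' Hide one fold's positives for training
#'
#' Returns a copy of `A` with the positives assigned to `fold_index` set to
#' 0, so the model trains without them; all other cells are unchanged.
#'
#' @param A Binary association matrix the plan was built from.
#' @param plan A `"bc_cv_plan"` from [make_folds()].
#' @param fold_index Fold to mask, in `1..n_folds`.
#' @return The masked association matrix.
#' @export
mask_fold <- function(A, plan, fold_index) {
  stopifnot(inherits(plan, "bc_cv_plan"))
  fold_index <- check_count(fold_index, "fold_index")
  if (fold_index > plan$n_folds) {
    stop(sprintf("fold_index %d exceeds n_folds = %d",
                 fold_index, plan$n_folds), call. = FALSE)
  }
  out <- A
  out[plan$cells[plan$fold == fold_index, , drop = FALSE]] <- 0
  out
}

#' Cross-validated evaluation of association prediction
#'
#' For each fold: the fold's positives are hidden ([mask_fold()]), the
#' model is fitted to the masked matrix, every cell is scored, and the
#' held-out positives are evaluated against all unknown cells (`A == 0`)
#' as negatives — training positives never enter the test pool.  Reported
#' per fold: AUC, AUPR, and accuracy / sensitivity / specificity /
#' precision / F1 at the fold's F1-maximizing threshold (recorded in the
#' report so a fixed cutoff can be substituted).
#'
#' Treating every unknown cell as a negative mirrors the candidate-pool
#' framing of drug repositioning: unknown pairs are exactly the pool the
#' ranking is asked to order.
#'
#' @inheritParams bcnmf
#' @param n_folds Number of folds (default 10).
#' @param seed Seed governing both the fold assignment and the per-fold
#'   fit initializations (fold f is fitted with seed `seed + f`).
#' @param verbose Print per-fold progress.
#' @return An object of class `"bc_cv_report"`: a list with `per_fold`
#'   (data.frame of fold, auc, aupr, acc, sen, spe, pre, f1, threshold),
#'   `aggregate` (data.frame of metric, mean, sd), and the settings.
#' @examples
#' sim <- simulate_bundle(n = 40, m = 30, k_true = 3, density = 0.15,
#'                        sim_noise = 0, seed = 3)
#' rep <- cross_validate(sim$bundle$A, sim$bundle$Sd, sim$bundle$Se,
#'                       k = 3, max_iter = 150, n_folds = 3, seed = 1)
#' rep$aggregate
#' @export
cross_validate <- function(A, Sd = NULL, Se = NULL, k = 50, mu = 0.1,
                           lambda = 0.1, max_iter = 1000, tol = 1e-6,
                           eps = 1e-12, n_folds = 10, seed = 1,
                           verbose = FALSE) {
  A <- validate_association(A)
  plan <- make_folds(A, n_folds, seed)
  neg <- which(A == 0)
  rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    Atrain <- mask_fold(A, plan, f)
    fit <- bcnmf(Atrain, Sd, Se, k = k, mu = mu, lambda = lambda,
                 max_iter = max_iter, tol = tol, eps = eps,
                 seed = seed + f)
    S <- predict(fit)
    held <- plan$cells[plan$fold == f, , drop = FALSE]
    scores <- c(S[held], S[neg])
    labels <- c(rep(1, nrow(held)), rep(0, length(neg)))
    th <- best_f1_threshold(scores, labels)
    tm <- threshold_metrics(scores, labels, th$threshold)
    rows[[f]] <- data.frame(
      fold = f,
      auc = roc_auc(scores, labels),
      aupr = pr_auc(scores, labels),
      acc = tm$acc, sen = tm$sen, spe = tm$spe, pre = tm$pre, f1 = tm$f1,
      threshold = th$threshold)
    if (verbose) {
      message(sprintf("fold %d/%d: AUC %.4f, AUPR %.4f",
                      f, n_folds, rows[[f]]$auc, rows[[f]]$aupr))
    }
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("auc", "aupr", "acc", "sen", "spe", "pre", "f1")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(mn) mean(per_fold[[mn]]), numeric(1)),
    sd = vapply(metrics, function(mn) stats::sd(per_fold[[mn]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 n_folds = n_folds, seed = seed,
                 hyperparameters = list(k = k, mu = mu, lambda = lambda,
                                        max_iter = max_iter, tol = tol,
                                        eps = eps)),
            class = "bc_cv_report")
}

#' @export
print.bc_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$n_folds, x$seed))
  agg <- x$aggregate
  cat(sprintf("  %-5s mean %.4f  sd %.4f\n",
              agg$metric, agg$mean, agg$sd), sep = "")
  invisible(x)
}

#' Grid search over hyperparameters by cross-validated AUC
#'
#' Evaluates every combination of the supplied `k`, `mu` and `lambda`
#' values with [cross_validate()] and ranks them by mean held-out AUC.
#'
#' @inheritParams cross_validate
#' @param k_grid,mu_grid,lambda_grid Numeric vectors of candidate values.
#' @return A data.frame with columns `k`, `mu`, `lambda`, `mean_auc`,
#'   `sd_auc`, sorted by decreasing `mean_auc`.
#' @export
grid_search <- function(A, Sd = NULL, Se = NULL, k_grid, mu_grid,
                        lambda_grid, max_iter = 1000, tol = 1e-6,
                        n_folds = 10, seed = 1, verbose = FALSE) {
  grid <- expand.grid(k = k_grid, mu = mu_grid, lambda = lambda_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- cross_validate(A, Sd, Se, k = grid$k[i], mu = grid$mu[i],
                          lambda = grid$lambda[i], max_iter = max_iter,
                          tol = tol, n_folds = n_folds, seed = seed)
    auc <- rep$aggregate[rep$aggregate$metric == "auc", ]
    if (verbose) {
      message(sprintf("k=%g mu=%g lambda=%g: AUC %.4f",
                      grid$k[i], grid$mu[i], grid$lambda[i], auc$mean))
    }
    data.frame(k = grid$k[i], mu = grid$mu[i], lambda = grid$lambda[i],
               mean_auc = auc$mean, sd_auc = auc$sd)
  })
  out <- do.call(rbind, res)
  out[order(-out$mean_auc), , drop = FALSE]
}
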