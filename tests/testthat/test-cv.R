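test_that("folds partition the positives into balanced groups", {
  set.seed(10)
  A <- matrix(rbinom(30, 1, 0.4), 6, 5)
  A[1:2] <- 1
  npos <- sum(A)
  plan <- make_folds(A, n_folds = 2, seed = 1)
  sizes <- tabulate(plan$fold, 2)
  expect_equal(sum(sizes), npos)
  expect_lte(diff(range(sizes)), 1)
  # union of folds = all positive cells, pairwise disjoint
  expect_equal(nrow(plan$cells), npos)
  expect_true(all(A[plan$cells] == 1))
  expect_false(anyDuplicated(plan$cells) > 0)
})

test_that("10 positives over 5 folds give exactly 2 per fold", {
  A <- matrix(0, 5, 4); A[1:10] <- 1
  plan <- make_folds(A, n_folds = 5, seed = 3)
  expect_equal(unname(tabulate(plan$fold, 5)), rep(2L, 5))
})

test_that("fold assignment is deterministic given the seed", {
  set.seed(11)
  A <- matrix(rbinom(80, 1, 0.3), 10, 8)
  A[1] <- 1
  expect_identical(make_folds(A, 4, seed = 7), make_folds(A, 4, seed = 7))
})

test_that("make_folds rejects more folds than positives", {
  A <- matrix(0, 4, 4); A[1:3] <- 1
  expect_error(make_folds(A, n_folds = 5, seed = 1), "3 known associations")
})

test_that("masking hides exactly one fold and restoring it is an involution", {
  set.seed(12)
  A <- matrix(rbinom(60, 1, 0.4), 10, 6)
  A[1:2] <- 1
  plan <- make_folds(A, 3, seed = 2)
  for (f in 1:3) {
    Am <- mask_fold(A, plan, f)
    held <- plan$cells[plan$fold == f, , drop = FALSE]
    expect_equal(sum(Am), sum(A) - nrow(held))
    expect_true(all(Am[held] == 0))
    # all other cells unchanged
    other <- A; other[held] <- 0
    expect_identical(Am, other)
    # restore
    Ar <- Am; Ar[held] <- 1
    expect_identical(Ar, A)
  }
})

test_that("cross-validation is correct on cheating and constant scores", {
  # bypass the fitted model: evaluate the metric path directly on a fold
  sim <- simulate_bundle(20, 15, 3, 0.2, 0, seed = 4)
  A <- sim$bundle$A
  plan <- make_folds(A, 4, seed = 1)
  held <- plan$cells[plan$fold == 1, , drop = FALSE]
  neg <- which(A == 0)
  labels <- c(rep(1, nrow(held)), rep(0, length(neg)))
  # scores read off the unmasked truth: perfect separation
  cheat <- c(A[held], A[neg])
  expect_equal(roc_auc(cheat, labels), 1.0)
  # constant scores: chance level
  expect_equal(roc_auc(rep(0.7, length(labels)), labels), 0.5)
})

test_that("cross_validate reports well-formed per-fold and aggregate metrics", {
  sim <- simulate_bundle(30, 24, 3, 0.15, 0, seed = 5)
  rep <- cross_validate(sim$bundle$A, sim$bundle$Sd, sim$bundle$Se,
                        k = 3, max_iter = 120, tol = 1e-5, n_folds = 3,
                        seed = 2)
  expect_s3_class(rep, "bc_cv_report")
  expect_equal(nrow(rep$per_fold), 3L)
  mets <- c("auc", "aupr", "acc", "sen", "spe", "pre", "f1")
  vals <- unlist(rep$per_fold[mets])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(rep$aggregate$mean,
               unname(colMeans(rep$per_fold[mets])))
  # determinism of the whole report
  rep2 <- cross_validate(sim$bundle$A, sim$bundle$Sd, sim$bundle$Se,
                         k = 3, max_iter = 120, tol = 1e-5, n_folds = 3,
                         seed = 2)
  expect_identical(rep, rep2)
})

test_that("held-out positives never reach the training objective", {
  sim <- simulate_bundle(20, 16, 3, 0.2, 0, seed = 6)
  A <- sim$bundle$A
  plan <- make_folds(A, 4, seed = 3)
  Am <- mask_fold(A, plan, 2)
  fit <- bcnmf(Am, sim$bundle$Sd, sim$bundle$Se, k = 3, max_iter = 30,
               seed = 1)
  # the fit's recorded objective is computed from the masked matrix only
  obj_masked <- objective_value(Am, fit$X, fit$Y, sim$bundle$Sd,
                                sim$bundle$Se, fit$mu, fit$lambda)
  obj_full <- objective_value(A, fit$X, fit$Y, sim$bundle$Sd,
                              sim$bundle$Se, fit$mu, fit$lambda)
  expect_equal(fit$objective[length(fit$objective)], obj_masked,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(obj_masked, obj_full)))
})

test_that("grid search ranks hyperparameter combinations by mean AUC", {
  sim <- simulate_bundle(24, 18, 3, 0.2, 0, seed = 7)
  res <- grid_search(sim$bundle$A, sim$bundle$Sd, sim$bundle$Se,
                     k_grid = c(2, 3), mu_grid = 0.1, lambda_grid = 0.1,
                     max_iter = 80, tol = 1e-4, n_folds = 2, seed = 1)
  expect_equal(nrow(res), 2L)
  expect_true(!is.unsorted(rev(res$mean_auc)))
  expect_true(all(res$mean_auc >= 0 & res$mean_auc <= 1))
})
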