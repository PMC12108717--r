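test_that("objective handles the zero-factor and exact-factorization cases", {
  inst <- rand_instance(4, 3, 2, seed = 11)
  k <- 2
  Z_X <- matrix(0, k, 4); Z_Y <- matrix(0, k, 3)
  # all cross terms vanish when both factors are zero
  expect_equal(
    objective_value(inst$A, Z_X, Z_Y, inst$Sd, inst$Se, mu = 0.3,
                    lambda = 0.5),
    sum(inst$A^2) + 0.5 * (sum(inst$Sd^2) + sum(inst$Se^2)))
  # every residual vanishes on an exactly consistent instance
  X <- inst$X; Y <- inst$Y
  expect_equal(
    objective_value(crossprod(X, Y), X, Y, crossprod(X), crossprod(Y),
                    mu = 0, lambda = 0.7),
    0)
})

test_that("objective matches the term-by-term scalar-loop expansion", {
  for (seed in c(11, 12, 13)) {
    inst <- rand_instance(4, 3, 2, seed = seed)
    got <- objective_value(inst$A, inst$X, inst$Y, inst$Sd, inst$Se,
                           mu = 0.1, lambda = 0.5)
    want <- naive_objective(inst$A, inst$X, inst$Y, inst$Sd, inst$Se,
                            mu = 0.1, lambda = 0.5)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("objective rejects mismatched shapes naming the operand", {
  inst <- rand_instance(4, 3, 2, seed = 14)
  expect_error(
    objective_value(inst$A, inst$X[, 1:3], inst$Y, inst$Sd, inst$Se),
    "X must be")
  expect_error(
    objective_value(inst$A, inst$X, inst$Y, inst$Se, inst$Se,
                    lambda = 0.1),
    "Sd must be")
})

test_that("multiplicative updates preserve zeros and fixed points", {
  inst <- rand_instance(5, 4, 2, seed = 21)
  Z <- matrix(0, 2, 5)
  expect_equal(update_X(inst$A, Z, inst$Y, inst$Sd, 0.1, 0.2), Z)
  Zy <- matrix(0, 2, 4)
  expect_equal(update_Y(inst$A, inst$X, Zy, inst$Se, 0.1, 0.2), Zy)
  # numerator == denominator elementwise => exact fixed point: on a fully
  # consistent instance (A = X^T Y, Sd = X^T X, Se = Y^T Y, mu = 0) the
  # ratio is 1 everywhere
  X <- inst$X; Y <- inst$Y
  A <- crossprod(X, Y)
  expect_equal(update_X(A, X, Y, crossprod(X), mu = 0, lambda = 0.3,
                        eps = 0),
               X, tolerance = 1e-12)
  expect_equal(update_Y(A, X, Y, crossprod(Y), mu = 0, lambda = 0.3,
                        eps = 0),
               Y, tolerance = 1e-12)
})

test_that("vectorized updates equal the scalar-loop rules", {
  inst <- rand_instance(5, 4, 2, seed = 31)
  gotX <- update_X(inst$A, inst$X, inst$Y, inst$Sd, mu = 0.1, lambda = 0.2)
  wantX <- naive_update_X(inst$A, inst$X, inst$Y, inst$Sd, 0.1, 0.2)
  expect_equal(gotX, wantX, tolerance = 1e-10)
  gotY <- update_Y(inst$A, inst$X, inst$Y, inst$Se, mu = 0.1, lambda = 0.2)
  wantY <- naive_update_Y(inst$A, inst$X, inst$Y, inst$Se, 0.1, 0.2)
  expect_equal(gotY, wantY, tolerance = 1e-10)
})

test_that("updates reject non-finite inputs", {
  inst <- rand_instance(4, 3, 2, seed = 41)
  Xbad <- inst$X; Xbad[1, 1] <- NaN
  expect_error(update_X(inst$A, Xbad, inst$Y, inst$Sd), "non-finite")
})

test_that("fit with max_iter = 0 returns the initialization unchanged", {
  inst <- rand_instance(6, 5, 2, seed = 51)
  fit <- bcnmf(inst$A, inst$Sd, inst$Se, k = 2, max_iter = 0, seed = 3)
  expect_length(fit$objective, 1L)
  expect_identical(fit$iterations, 0L)
  expect_false(fit$converged)
  # same seed reproduces the same initialization
  fit2 <- bcnmf(inst$A, inst$Sd, inst$Se, k = 2, max_iter = 0, seed = 3)
  expect_identical(fit$X, fit2$X)
})

test_that("fit is deterministic given the seed", {
  inst <- rand_instance(10, 8, 3, seed = 61)
  f1 <- bcnmf(inst$A, inst$Sd, inst$Se, k = 3, max_iter = 50, seed = 9)
  f2 <- bcnmf(inst$A, inst$Sd, inst$Se, k = 3, max_iter = 50, seed = 9)
  expect_identical(f1$X, f2$X)
  expect_identical(f1$Y, f2$Y)
  expect_identical(f1$objective, f2$objective)
})

test_that("fit leaves the caller's RNG stream untouched", {
  inst <- rand_instance(6, 5, 2, seed = 1)
  set.seed(123)
  before <- .Random.seed
  invisible(bcnmf(inst$A, k = 2, lambda = 0, max_iter = 5, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("fit records the objective trace and descends", {
  inst <- rand_instance(12, 9, 3, seed = 71)
  fit <- bcnmf(inst$A, inst$Sd, inst$Se, k = 3, max_iter = 200, tol = 0,
               seed = 1)
  expect_length(fit$objective, fit$iterations + 1L)
  expect_true(all(fit$X >= 0))
  expect_true(all(fit$Y >= 0))
  drops <- diff(fit$objective)
  expect_true(all(drops <= 1e-8 * abs(fit$objective[-length(fit$objective)])))
})

test_that("fit objective trace matches a re-run on the scalar-loop updates", {
  inst <- rand_instance(7, 5, 2, seed = 81)
  fit <- bcnmf(inst$A, inst$Sd, inst$Se, k = 2, mu = 0.1, lambda = 0.1,
               max_iter = 40, tol = 0, seed = 2)
  # replay the same initialization through the naive oracles
  init <- bcnmf(inst$A, inst$Sd, inst$Se, k = 2, mu = 0.1, lambda = 0.1,
                max_iter = 0, seed = 2)
  X <- init$X; Y <- init$Y
  Sd <- canonicalize_similarity(inst$Sd)
  Se <- canonicalize_similarity(inst$Se)
  for (i in 1:40) {
    X <- naive_update_X(inst$A, X, Y, Sd, 0.1, 0.1)
    Y <- naive_update_Y(inst$A, X, Y, Se, 0.1, 0.1)
  }
  want <- naive_objective(inst$A, X, Y, Sd, Se, 0.1, 0.1)
  got <- fit$objective[length(fit$objective)]
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("fit validates configuration and degenerate inputs", {
  inst <- rand_instance(5, 4, 2, seed = 91)
  expect_error(bcnmf(inst$A, inst$Sd, inst$Se, k = 4), "k = 4 must be <")
  expect_error(bcnmf(inst$A, k = 2, lambda = 0.1), "Sd and Se are required")
  A0 <- matrix(0, 5, 4)
  expect_warning(bcnmf(A0, inst$Sd, inst$Se, k = 2, max_iter = 5),
                 "no known links")
})

test_that("predicted scores equal the transpose product of the factors", {
  inst <- rand_instance(6, 5, 3, seed = 101)
  fit <- bcnmf(inst$A, inst$Sd, inst$Se, k = 3, max_iter = 30, seed = 1)
  S <- predict(fit)
  expect_equal(unname(S), naive_scores(fit$X, fit$Y), tolerance = 1e-12)
  expect_true(all(S >= 0))
  expect_identical(dimnames(S), list(fit$drug_ids, fit$disease_ids))
  # an exact factorization reproduces A: X = I (k = n), Y = A's rows
  A <- inst$A
  Xe <- diag(nrow(A)); Ye <- A
  expect_equal(crossprod(Xe, Ye), A)
  # zero factors give zero scores
  fit0 <- fit; fit0$X <- fit$X * 0
  expect_true(all(predict(fit0) == 0))
})

test_that("reduction: mu = lambda = 0 is plain NMF, lambda = 0 is Tikhonov", {
  inst <- rand_instance(5, 4, 2, seed = 111)
  A <- inst$A; X <- inst$X; Y <- inst$Y
  expect_equal(objective_value(A, X, Y, mu = 0, lambda = 0),
               sum((A - crossprod(X, Y))^2), tolerance = 1e-12)
  expect_equal(objective_value(A, X, Y, mu = 0.4, lambda = 0),
               sum((A - crossprod(X, Y))^2) + 0.4 * (sum(X^2) + sum(Y^2)),
               tolerance = 1e-12)
  # the classical Lee-Seung rule: X <- X * (Y A^T) / (Y Y^T X)
  got <- update_X(A, X, Y, mu = 0, lambda = 0, eps = 0)
  classical <- X * tcrossprod(Y, A) / (tcrossprod(Y) %*% X)
  expect_equal(got, classical, tolerance = 1e-12)
})
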