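# Independent brute-force oracles: scalar loops and exhaustive
# enumeration only, no shared code with the package implementation.

# term-by-term objective: reconstruction + Tikhonov + similarity penalties
naive_objective <- function(A, X, Y, Sd, Se, mu, lambda) {
  n <- nrow(A); m <- ncol(A); k <- nrow(X)
  rec <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- 0
    for (t in seq_len(k)) s <- s + X[t, i] * Y[t, j]
    rec <- rec + (A[i, j] - s)^2
  }
  tik <- 0
  for (t in seq_len(k)) {
    for (i in seq_len(n)) tik <- tik + X[t, i]^2
    for (j in seq_len(m)) tik <- tik + Y[t, j]^2
  }
  simp <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    g <- 0
    for (t in seq_len(k)) g <- g + X[t, i] * X[t, j]
    simp <- simp + (g - Sd[i, j])^2
  }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    g <- 0
    for (t in seq_len(k)) g <- g + Y[t, i] * Y[t, j]
    simp <- simp + (g - Se[i, j])^2
  }
  rec + mu * tik + lambda * simp
}

# elementwise multiplicative rule for X, evaluated entry by entry
naive_update_X <- function(A, X, Y, Sd, mu, lambda, eps = 1e-12) {
  n <- ncol(X); m <- ncol(Y); k <- nrow(X)
  out <- X
  for (t in seq_len(k)) for (i in seq_len(n)) {
    yat <- 0
    for (j in seq_len(m)) yat <- yat + Y[t, j] * A[i, j]
    xsd <- 0
    for (p in seq_len(n)) xsd <- xsd + X[t, p] * Sd[p, i]
    yytx <- 0
    for (s in seq_len(k)) {
      yyt <- 0
      for (j in seq_len(m)) yyt <- yyt + Y[t, j] * Y[s, j]
      yytx <- yytx + yyt * X[s, i]
    }
    xxtx <- 0
    for (s in seq_len(k)) {
      xxt <- 0
      for (p in seq_len(n)) xxt <- xxt + X[t, p] * X[s, p]
      xxtx <- xxtx + xxt * X[s, i]
    }
    num <- yat + 2 * lambda * xsd
    den <- yytx + mu * X[t, i] + 2 * lambda * xxtx + eps
    out[t, i] <- X[t, i] * num / den
  }
  out
}

naive_update_Y <- function(A, X, Y, Se, mu, lambda, eps = 1e-12) {
  n <- ncol(X); m <- ncol(Y); k <- nrow(X)
  out <- Y
  for (t in seq_len(k)) for (j in seq_len(m)) {
    xa <- 0
    for (i in seq_len(n)) xa <- xa + X[t, i] * A[i, j]
    yse <- 0
    for (q in seq_len(m)) yse <- yse + Y[t, q] * Se[q, j]
    xxty <- 0
    for (s in seq_len(k)) {
      xxt <- 0
      for (i in seq_len(n)) xxt <- xxt + X[t, i] * X[s, i]
      xxty <- xxty + xxt * Y[s, j]
    }
    yyty <- 0
    for (s in seq_len(k)) {
      yyt <- 0
      for (q in seq_len(m)) yyt <- yyt + Y[t, q] * Y[s, q]
      yyty <- yyty + yyt * Y[s, j]
    }
    num <- xa + 2 * lambda * yse
    den <- xxty + mu * Y[t, j] + 2 * lambda * yyty + eps
    out[t, j] <- Y[t, j] * num / den
  }
  out
}

# scalar triple-loop matrix product t(X) %*% Y
naive_scores <- function(X, Y) {
  n <- ncol(X); m <- ncol(Y); k <- nrow(X)
  S <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- 0
    for (t in seq_len(k)) s <- s + X[t, i] * Y[t, j]
    S[i, j] <- s
  }
  S
}

# all-pairs Mann-Whitney AUC with half credit for ties
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exhaustive threshold enumeration of the step-wise PR curve
naive_aupr <- function(scores, labels) {
  npos <- sum(labels == 1)
  ths <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_rec <- 0
  for (th in ths) {
    tp <- sum(scores >= th & labels == 1)
    fp <- sum(scores >= th & labels == 0)
    rec <- tp / npos
    prec <- tp / (tp + fp)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# direct confusion tally at a threshold
naive_confusion <- function(scores, labels, threshold) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1
    else if (pred && labels[i] == 0) fp <- fp + 1
    else if (!pred && labels[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# brute-force candidate ranking: filter unknown cells, sort, truncate
naive_rank <- function(scores, A, drug_id, top_k) {
  cand <- data.frame(disease_id = colnames(A), score = scores[drug_id, ],
                     known = A[drug_id, ] == 1, stringsAsFactors = FALSE)
  cand <- cand[!cand$known, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$disease_id, method = "radix"), ]
  head(cand[, c("disease_id", "score")], top_k)
}

# random small problem instance (not drawn from the package generator)
rand_instance <- function(n, m, k, seed) {
  set.seed(seed)
  sym01 <- function(q) {
    R <- matrix(runif(q * q), q, q)
    S <- (R + t(R)) / 2
    diag(S) <- 1
    S
  }
  list(A = matrix(rbinom(n * m, 1, 0.3), n, m),
       X = matrix(runif(k * n), k, n),
       Y = matrix(runif(k * m), k, m),
       Sd = sym01(n), Se = sym01(m))
}

rand_scores_labels <- function(n, seed, tie_prob = 0.3) {
  set.seed(seed)
  scores <- round(runif(n), if (runif(1) < tie_prob) 1 else 6)
  labels <- rbinom(n, 1, 0.3)
  if (sum(labels) == 0) labels[1] <- 1
  if (sum(labels) == n) labels[1] <- 0
  list(scores = scores, labels = labels)
}
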