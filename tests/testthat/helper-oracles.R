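# Independent brute-force / closed-form oracles used to check the
# implementations. These deliberately use naive loops and textbook formulas.

# exhaustive Otsu: best integer threshold t (class 0 = {v <= t}) by
# between-class variance computed from the raw values; ties -> lowest t
otsu_brute_split <- function(v) {
  best_t <- NA_integer_
  best_obj <- -Inf
  for (t in sort(unique(v))) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    obj <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (obj > best_obj + 1e-12) {
      best_obj <- obj
      best_t <- t
    }
  }
  best_t
}

# AUC by explicit positive-negative pair counting with half credit for ties
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exhaustive Youden scan over observed score values, positive iff s > c
youden_brute <- function(scores, labels) {
  best_c <- NA_real_
  best_j <- -Inf
  for (c in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] > c)
    spec <- mean(scores[labels == 0] <= c)
    if (sens + spec > best_j + 1e-12) {
      best_j <- sens + spec
      best_c <- c
    }
  }
  best_c
}

# closed-form leave-one-out OLS predictions via the leverage formula
loocv_hat_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  H <- X1 %*% solve(crossprod(X1)) %*% t(X1)
  yhat <- drop(H %*% y)
  (yhat - diag(H) * y) / (1 - diag(H))
}

# OLS coefficients via the normal equations
ols_normal_equations <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(crossprod(X1)) %*% crossprod(X1, y))
}

# single-linkage grouping by pairwise distance, brute force transitive
# closure
single_linkage_brute <- function(coords, link) {
  n <- nrow(coords)
  adj <- as.matrix(stats::dist(coords)) <= link
  groups <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && groups[j] != groups[i]) {
        g <- min(groups[i], groups[j])
        groups[groups == groups[i] | groups == groups[j]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(groups, unique(groups))
}
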