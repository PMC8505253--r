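# Independent brute-force oracles used to cross-check the implementation.

# O(n^3) complete-linkage agglomeration: repeatedly merge the pair of
# clusters with the smallest maximum pairwise distance.
naive_complete_linkage <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best_d <- Inf
    best <- c(NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- max(D[clusters[[a]], clusters[[b]]])
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# Brute-force robustness index via explicit set scans
brute_robustness <- function(sets) {
  universe <- unique(unlist(sets))
  if (length(universe) == 0) return(0)
  in_all <- vapply(universe, function(u) {
    all(vapply(sets, function(s) u %in% s, logical(1)))
  }, logical(1))
  sum(in_all) / length(universe)
}

# Hand Benjamini-Hochberg step-up: reject H_(1..i*) where i* is the largest
# i with p_(i) <= i q / m.
bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(ok) > 0) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# Closed-form OLS t-statistic for one coefficient
ols_t_oracle <- function(X, y, col) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  drop(b[col] / sqrt(s2 * XtXi[col, col]))
}

# Independent maximum-likelihood logistic fit: explicit log-likelihood
# maximised with a general-purpose optimiser (no IRLS).
logistic_oracle <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-12))
  ll1 <- -fit$value
  nll0 <- function(b0) -sum(y * b0 - log1p(exp(rep(b0, length(y)))))
  b0 <- stats::optimize(nll0, c(-20, 20))$minimum
  ll0 <- -nll0(b0)
  n <- length(y)
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  list(coef = fit$par, loglik = ll1, loglik_null = ll0,
    r2_nagelkerke = cs / (1 - exp(2 * ll0 / n)))
}
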