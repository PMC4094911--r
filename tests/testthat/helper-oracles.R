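# Independent oracles, implemented without touching the package internals.

# NIPALS PLS1: plain multi-component partial least squares for a single
# response, used as the reference against which OPLS training predictions
# are checked (OPLS with k orthogonal components must equal PLS1 with k+1
# components on the training data).
pls1_nipals_fitted <- function(X, y, ncomp) {
  X <- as.matrix(X)
  ybar <- mean(y)
  Xd <- X
  yd <- y - ybar
  yhat <- rep(ybar, length(y))
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    q <- sum(yd * t) / sum(t^2)
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - q * t
    yhat <- yhat + q * t
  }
  yhat
}

# Brute-force pair-counting AUC: P(pos > neg) + 0.5 P(pos == neg).
auc_bruteforce <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by enumerating every label assignment.
mw_exact_p_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combos <- utils::combn(n, length(a))
  u_null <- apply(combos, 2L, function(ix) {
    aa <- pooled[ix]; bb <- pooled[-ix]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  mu <- length(a) * length(b) / 2
  mean(abs(u_null - mu) >= abs(u_obs - mu) - 1e-12)
}
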