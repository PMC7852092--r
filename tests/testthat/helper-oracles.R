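# Straight-line oracle implementations used across test files. Written
# with explicit loops, independent of the package's batched code paths.

oracle_lstm_step <- function(h, C, x, p) {
  a <- c(h, x)
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(p$W_f %*% a + p$b_f)
  i <- sig(p$W_i %*% a + p$b_i)
  cand <- tanh(p$W_C %*% a + p$b_C)
  o <- sig(p$W_o %*% a + p$b_o)
  Cn <- f * C + i * cand
  list(h = as.vector(o * tanh(Cn)), C = as.vector(Cn))
}

oracle_single_attention <- function(h, M, bias) {
  l <- nrow(h); R <- ncol(h)
  e <- matrix(0, l, R)
  for (i in 1:l) for (r in 1:R) {
    e[i, r] <- sum(M[i, ] * h[, r]) + bias[i, r]
  }
  alpha <- matrix(0, l, R)
  for (r in 1:R) alpha[, r] <- exp(e[, r]) / sum(exp(e[, r]))
  abar <- numeric(l)
  for (i in 1:l) abar[i] <- sum(alpha[i, ]) / R
  z <- matrix(0, l, R)
  for (i in 1:l) for (r in 1:R) z[i, r] <- h[i, r] * abar[i]
  list(z = z, alpha_bar = abar)
}

oracle_pairwise <- function(h, W_Q, W_K, W_V, d_k) {
  Q <- h %*% W_Q; K <- h %*% W_K; V <- h %*% W_V
  S <- (Q %*% t(K)) / sqrt(d_k)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  list(Z = A %*% V, A = A)
}

# exhaustive threshold-enumeration oracle for the challenge metrics
oracle_metrics <- function(scores, labels, fdr = NULL) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  pts <- t(vapply(th, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    c(tpr = tp / n_pos, fpr = fp / n_neg,
      prec = if (tp + fp == 0) 1 else tp / (tp + fp))
  }, numeric(3)))
  fpr <- c(0, pts[, "fpr"], 1)
  tpr <- c(0, pts[, "tpr"], 1)
  roc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  rec <- c(0, pts[, "tpr"])
  prc <- sum(diff(rec) * pts[, "prec"])
  out <- list(auroc = roc, auprc = prc)
  if (!is.null(fdr)) {
    ok <- pts[, "prec"] >= 1 - fdr
    out$recall <- if (any(ok)) max(pts[ok, "tpr"]) else 0
  }
  out
}
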