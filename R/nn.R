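# Neural-network primitives: 1-D convolution (im2col), max-pooling, LSTM /
# Bi-LSTM, the single (position-wise) and pairwise (scaled dot-product)
# attention modules, sinusoidal positional encodings, dense heads, and
# their exact analytic backward passes. Everything is batched as plain
# matrix algebra so the BLAS does the heavy lifting; batches are stored as
# L x C x B arrays (sample-major rows after im2col).

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Numerically stable softmax
#'
#' @param x Numeric matrix.
#' @param axis 1 to normalize down each column (over rows/positions),
#'   2 to normalize along each row.
#' @return Matrix of the same shape whose slices along `axis` sum to 1.
#' @export
softmax <- function(x, axis = 1) {
  if (axis == 1) {
    shifted <- sweep(x, 2, apply(x, 2, max), "-")
    e <- exp(shifted)
    sweep(e, 2, colSums(e), "/")
  } else {
    shifted <- x - apply(x, 1, max)
    e <- exp(shifted)
    e / rowSums(e)
  }
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

## ---- convolution -----------------------------------------------------

conv_idx <- function(L, C, K) {
  l1 <- L - K + 1L
  idx <- matrix(0L, l1, K * C)
  for (ch in seq_len(C)) {
    for (t in seq_len(K)) {
      idx[, (ch - 1L) * K + t] <- (ch - 1L) * L + seq_len(l1) + t - 1L
    }
  }
  idx
}

conv1d_forward <- function(X, W, b, idx, want_cache = TRUE) {
  d <- dim(X)
  L <- d[1]; C <- d[2]; B <- d[3]
  l1 <- nrow(idx)
  Xc <- matrix(0, B * l1, ncol(idx))
  for (bb in seq_len(B)) {
    xv <- X[, , bb]
    Xc[((bb - 1L) * l1 + 1L):(bb * l1), ] <- xv[idx]
  }
  Z <- Xc %*% W
  Z <- sweep(Z, 2, b, "+")
  A <- pmax(Z, 0)
  cache <- if (want_cache) list(Xc = Xc, mask = Z > 0, B = B, l1 = l1,
                                LC = L * C, idx = idx) else NULL
  list(out = A, cache = cache)
}

conv1d_backward <- function(dA, cache, W, want_dx = FALSE) {
  dZ <- dA * cache$mask
  dW <- crossprod(cache$Xc, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (want_dx) {
    dXc <- dZ %*% t(W)
    B <- cache$B; l1 <- cache$l1
    dXv <- matrix(0, cache$LC, B)
    idxvec <- as.vector(cache$idx)
    for (bb in seq_len(B)) {
      vals <- as.vector(dXc[((bb - 1L) * l1 + 1L):(bb * l1), ])
      acc <- rowsum(vals, idxvec)
      v <- numeric(cache$LC)
      v[as.integer(rownames(acc))] <- acc[, 1]
      dXv[, bb] <- v
    }
    dX <- dXv
  }
  list(dW = dW, db = db, dX = dX)
}

## ---- max pooling -----------------------------------------------------

maxpool_forward <- function(A, l1, pool, B, want_cache = TRUE) {
  l <- l1 %/% pool
  FF <- ncol(A)
  out <- matrix(-Inf, B * l, FF)
  amax <- matrix(0L, B * l, FF)
  base <- as.vector(outer((seq_len(l) - 1L) * pool, (seq_len(B) - 1L) * l1,
                          "+"))
  for (t in seq_len(pool)) {
    cand <- A[base + t, , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    amax[upd] <- t
  }
  cache <- if (want_cache) list(amax = amax, base = base, l1 = l1,
                                pool = pool, B = B, l = l, FF = FF) else NULL
  list(out = out, cache = cache, l = l)
}

maxpool_backward <- function(dout, cache) {
  dA <- matrix(0, cache$B * cache$l1, cache$FF)
  for (t in seq_len(cache$pool)) {
    sel <- cache$amax == t
    tmp <- matrix(0, nrow(dout), ncol(dout))
    tmp[sel] <- dout[sel]
    dA[cache$base + t, ] <- dA[cache$base + t, ] + tmp
  }
  dA
}

## ---- LSTM ------------------------------------------------------------

#' Initialise LSTM gate parameters
#'
#' Gate weight matrices act on the concatenation `[h, x]`, so each has
#' shape `hidden_size x (hidden_size + input_size)`. The forget-gate bias
#' starts at 1 (standard practice; keeps early gradients flowing).
#'
#' @param input_size Input feature width.
#' @param hidden_size Hidden state width.
#' @return List with `W_f`, `W_i`, `W_C`, `W_o`, `b_f`, `b_i`, `b_C`,
#'   `b_o`, `hidden_size`.
#' @export
lstm_params <- function(input_size, hidden_size) {
  mk <- function() glorot(hidden_size, hidden_size + input_size)
  list(W_f = mk(), W_i = mk(), W_C = mk(), W_o = mk(),
       b_f = rep(1, hidden_size), b_i = rep(0, hidden_size),
       b_C = rep(0, hidden_size), b_o = rep(0, hidden_size),
       hidden_size = hidden_size)
}

#' One LSTM cell update
#'
#' Computes the forget/input/output gates as sigmoids of affine maps of
#' `[h_{t-1}, x_t]`, the candidate cell state through tanh, then
#' `C_t = f * C_{t-1} + i * C~_t` and `h_t = o * tanh(C_t)`.
#'
#' @param state List with `h` and `C` vectors (length `hidden_size`).
#' @param x_t Input vector at this position.
#' @param params Parameters from [lstm_params()].
#' @return Updated state list with `h` and `C`.
#' @export
lstm_step <- function(state, x_t, params) {
  a <- c(state$h, x_t)
  if (length(a) != ncol(params$W_f)) {
    stop("lstm_step: state/input dimensions do not match parameters")
  }
  f <- sigmoid(as.vector(params$W_f %*% a) + params$b_f)
  i <- sigmoid(as.vector(params$W_i %*% a) + params$b_i)
  cand <- tanh(as.vector(params$W_C %*% a) + params$b_C)
  o <- sigmoid(as.vector(params$W_o %*% a) + params$b_o)
  C <- f * state$C + i * cand
  list(h = o * tanh(C), C = C)
}

# Batched LSTM over a sequence. xs: list over time of (B x input) matrices.
# Gate biases are folded into the matmul via a constant-1 column.
lstm_seq_forward <- function(xs, params, want_cache = TRUE) {
  l <- length(xs)
  B <- nrow(xs[[1]])
  r <- params$hidden_size
  tWb <- list(f = rbind(t(params$W_f), params$b_f),
              i = rbind(t(params$W_i), params$b_i),
              C = rbind(t(params$W_C), params$b_C),
              o = rbind(t(params$W_o), params$b_o))
  ones <- rep(1, B)
  h <- matrix(0, B, r); C <- matrix(0, B, r)
  hs <- vector("list", l)
  cache <- if (want_cache) vector("list", l) else NULL
  for (t in seq_len(l)) {
    A <- cbind(h, xs[[t]], ones)
    f <- sigmoid(A %*% tWb$f)
    i <- sigmoid(A %*% tWb$i)
    cand <- tanh(A %*% tWb$C)
    o <- sigmoid(A %*% tWb$o)
    C_prev <- C
    C <- f * C_prev + i * cand
    tC <- tanh(C)
    h <- o * tC
    hs[[t]] <- h
    if (want_cache) {
      cache[[t]] <- list(A = A, f = f, i = i, cand = cand, o = o,
                         C_prev = C_prev, tC = tC)
    }
  }
  list(hs = hs, cache = cache)
}

lstm_seq_backward <- function(dhs, cache, params, input_size,
                              want_dx = FALSE) {
  l <- length(dhs)
  B <- nrow(dhs[[1]])
  r <- params$hidden_size
  g <- list(W_f = params$W_f * 0, W_i = params$W_i * 0,
            W_C = params$W_C * 0, W_o = params$W_o * 0,
            b_f = params$b_f * 0, b_i = params$b_i * 0,
            b_C = params$b_C * 0, b_o = params$b_o * 0)
  dh_next <- matrix(0, B, r)
  dC_next <- matrix(0, B, r)
  dxs <- if (want_dx) vector("list", l) else NULL
  for (t in rev(seq_len(l))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    do <- dh * cc$tC
    dC <- dC_next + dh * cc$o * (1 - cc$tC^2)
    df <- dC * cc$C_prev
    di <- dC * cc$cand
    dcand <- dC * cc$i
    dC_next <- dC * cc$f
    dzf <- df * cc$f * (1 - cc$f)
    dzi <- di * cc$i * (1 - cc$i)
    dzc <- dcand * (1 - cc$cand^2)
    dzo <- do * cc$o * (1 - cc$o)
    dA <- dzf %*% params$W_f + dzi %*% params$W_i +
      dzc %*% params$W_C + dzo %*% params$W_o
    nwc <- ncol(cc$A) - 1L  # last column of A is the folded bias constant
    Gf <- crossprod(dzf, cc$A); Gi <- crossprod(dzi, cc$A)
    Gc <- crossprod(dzc, cc$A); Go <- crossprod(dzo, cc$A)
    g$W_f <- g$W_f + Gf[, seq_len(nwc), drop = FALSE]
    g$W_i <- g$W_i + Gi[, seq_len(nwc), drop = FALSE]
    g$W_C <- g$W_C + Gc[, seq_len(nwc), drop = FALSE]
    g$W_o <- g$W_o + Go[, seq_len(nwc), drop = FALSE]
    g$b_f <- g$b_f + Gf[, nwc + 1L]
    g$b_i <- g$b_i + Gi[, nwc + 1L]
    g$b_C <- g$b_C + Gc[, nwc + 1L]
    g$b_o <- g$b_o + Go[, nwc + 1L]
    dh_next <- dA[, seq_len(r), drop = FALSE]
    if (want_dx) dxs[[t]] <- dA[, r + seq_len(input_size), drop = FALSE]
  }
  list(grads = g, dxs = dxs)
}

#' Bidirectional LSTM over a feature sequence
#'
#' Runs a forward-direction and a backward-direction LSTM over the input
#' and concatenates their hidden states on the feature axis, so the output
#' feature width is twice the per-direction hidden size.
#'
#' @param x An l x c input matrix (positions x features).
#' @param params_fwd,params_bwd Parameter lists from [lstm_params()].
#' @return An l x (2 * hidden_size) matrix.
#' @export
bilstm <- function(x, params_fwd, params_bwd) {
  l <- nrow(x)
  if (l == 0) return(matrix(0, 0, 2 * params_fwd$hidden_size))
  xs <- lapply(seq_len(l), function(t) matrix(x[t, ], 1))
  fw <- lstm_seq_forward(xs, params_fwd, want_cache = FALSE)$hs
  bw <- lstm_seq_forward(rev(xs), params_bwd, want_cache = FALSE)$hs
  bw <- rev(bw)
  out <- matrix(0, l, 2 * params_fwd$hidden_size)
  for (t in seq_len(l)) out[t, ] <- c(fw[[t]], bw[[t]])
  out
}

## ---- single attention ------------------------------------------------

#' Initialise single-attention parameters
#'
#' @param l Number of positions of the incoming hidden block.
#' @param r Feature width of the incoming hidden block.
#' @return List with `M` (l x l) and `bias` (l x r).
#' @export
single_attention_params <- function(l, r) {
  list(M = glorot(l, l), bias = matrix(0, l, r))
}

#' Position-wise (single) attention
#'
#' Computes unnormalized scores `e = M h + bias`, softmax-normalizes each
#' feature column over positions, averages the per-column weights into one
#' weight per position, and reweights the input elementwise:
#' `z[i, r] = h[i, r] * alpha_bar[i]`.
#'
#' @param h l x r hidden block.
#' @param params Parameters from [single_attention_params()].
#' @return List with `z` (l x r), `alpha_bar` (length-l weights summing
#'   to 1) and `alpha` (the l x r per-column weights).
#' @export
single_attention <- function(h, params) {
  if (any(!is.finite(h))) stop("single_attention: non-finite input")
  e <- params$M %*% h + params$bias
  alpha <- softmax(e, axis = 1)
  alpha_bar <- rowMeans(alpha)
  z <- h * alpha_bar
  list(z = z, alpha_bar = alpha_bar, alpha = alpha)
}

## ---- positional encoding ---------------------------------------------

#' Sinusoidal positional-encoding table
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d))` and entry `(pos, 2i+1)`
#' is `cos(pos / 10000^(2i/d))` (0-based indices). For any fixed offset k,
#' `PE(pos + k)` is a position-independent linear combination of the
#' `PE(pos)` entries, which is what lets dot-product attention read
#' relative positions.
#'
#' @param L Number of positions (rows; positions are 0-based).
#' @param d Encoding width (columns).
#' @return L x d matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(L, d) {
  pos <- 0:(L - 1)
  tab <- matrix(0, L, d)
  for (j in 0:(d - 1)) {
    i <- j %/% 2
    angle <- pos / 10000^(2 * i / d)
    tab[, j + 1] <- if (j %% 2 == 0) sin(angle) else cos(angle)
  }
  tab
}

## ---- pairwise attention ----------------------------------------------

#' Initialise pairwise-attention parameters
#'
#' @param c Input feature width (the projections act on the feature axis).
#' @param d_k Query/key width (default 64).
#' @param d_v Value width (default 64).
#' @return List with `W_Q`, `W_K` (c x d_k), `W_V` (c x d_v), `d_k`, `d_v`.
#' @export
pairwise_attention_params <- function(c, d_k = 64L, d_v = 64L) {
  if (d_k < 1 || d_v < 1) stop("d_k and d_v must be >= 1")
  list(W_Q = glorot(c, d_k), W_K = glorot(c, d_k), W_V = glorot(c, d_v),
       d_k = d_k, d_v = d_v)
}

#' Scaled dot-product (pairwise) attention
#'
#' Projects the (positionally encoded) input into queries, keys and values,
#' forms the l x l attention matrix `softmax(Q K^T / sqrt(d_k))` row-wise,
#' and returns `Z = attention %*% V`.
#'
#' @param h_pe l x c input block, positional encodings already added.
#' @param params Parameters from [pairwise_attention_params()].
#' @return List with `Z` (l x d_v) and `attention` (l x l, rows sum to 1).
#' @export
pairwise_attention <- function(h_pe, params) {
  Q <- h_pe %*% params$W_Q
  K <- h_pe %*% params$W_K
  V <- h_pe %*% params$W_V
  S <- tcrossprod(Q, K) / sqrt(params$d_k)
  A <- softmax(S, axis = 2)
  list(Z = A %*% V, attention = A, Q = Q, K = K, V = V)
}

pairwise_attention_backward <- function(dZ, fw, h_pe, params,
                                        dA_extra = NULL) {
  dA <- dZ %*% t(fw$V)
  if (!is.null(dA_extra)) dA <- dA + dA_extra
  dV <- crossprod(fw$attention, dZ)
  rs <- rowSums(dA * fw$attention)
  dS <- fw$attention * (dA - rs)
  sc <- 1 / sqrt(params$d_k)
  dQ <- (dS %*% fw$K) * sc
  dK <- (crossprod(dS, fw$Q)) * sc
  dW_Q <- crossprod(h_pe, dQ)
  dW_K <- crossprod(h_pe, dK)
  dW_V <- crossprod(h_pe, dV)
  dh <- tcrossprod(dQ, params$W_Q) + tcrossprod(dK, params$W_K) +
    tcrossprod(dV, params$W_V)
  list(dW_Q = dW_Q, dW_K = dW_K, dW_V = dW_V, dh = dh)
}

## ---- Adam ------------------------------------------------------------

adam_init <- function(params) {
  zeros <- function(x) if (is.list(x)) lapply(x, zeros) else x * 0
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]]) || !is.numeric(p[[nm]])) {
          if (is.list(p[[nm]])) {
            r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
            out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
          }
          next
        }
        mm <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        vv <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- mm / (1 - beta1^tt)
        vhat <- vv / (1 - beta2^tt)
        out_p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        out_m[[nm]] <- mm; out_v[[nm]] <- vv
      }
      list(p = out_p, m = out_m, v = out_v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = tt))
}
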