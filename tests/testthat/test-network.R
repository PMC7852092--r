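# Straight-line oracle implementations of the LSTM and attention
# equations, written with plain loops and independent of the package's
# batched code paths.

test_that("lstm_step follows the gate equations exactly", {
  # zero weights and biases: sigmoid(0) = 0.5, tanh(0) = 0 => h stays 0
  p0 <- lstm_params(2, 3)
  for (nm in c("W_f", "W_i", "W_C", "W_o")) p0[[nm]][] <- 0
  for (nm in c("b_f", "b_i", "b_C", "b_o")) p0[[nm]][] <- 0
  st <- lstm_step(list(h = rep(0, 3), C = rep(0, 3)), c(5, -3), p0)
  expect_equal(st$h, rep(0, 3))
  # scalar closed form: h = 0.5 * tanh(0.5 * tanh(b_C)) from zero state
  p1 <- lstm_params(1, 1)
  for (nm in c("W_f", "W_i", "W_C", "W_o")) p1[[nm]][] <- 0
  for (nm in c("b_f", "b_i", "b_o")) p1[[nm]][] <- 0
  p1$b_C <- 7
  st1 <- lstm_step(list(h = 0, C = 0), 0.3, p1)
  expect_equal(st1$h, 0.5 * tanh(0.5 * tanh(7)), tolerance = 1e-12)
  # random instances against the straight-line oracle; outputs bounded
  set.seed(21)
  for (rep in 1:20) {
    p <- lstm_params(3, 4)
    h <- rnorm(4); C <- rnorm(4); x <- rnorm(3) * 5
    got <- lstm_step(list(h = h, C = C), x, p)
    want <- oracle_lstm_step(h, C, x, p)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$C, want$C, tolerance = 1e-10)
    expect_true(all(abs(got$h) <= 1))
  }
  expect_error(lstm_step(list(h = rep(0, 2), C = rep(0, 2)), c(1, 2, 3),
                         lstm_params(3, 4)), "dimensions")
})

test_that("batched LSTM matches the single-step cell over a sequence", {
  set.seed(3)
  p <- lstm_params(2, 3)
  xs <- lapply(1:6, function(t) matrix(rnorm(2), 1))
  hs <- attnbind:::lstm_seq_forward(xs, p, want_cache = FALSE)$hs
  st <- list(h = rep(0, 3), C = rep(0, 3))
  for (t in 1:6) {
    st <- lstm_step(st, as.vector(xs[[t]]), p)
    expect_equal(as.vector(hs[[t]]), st$h, tolerance = 1e-12)
  }
})

test_that("bilstm doubles the feature width and is direction symmetric", {
  set.seed(8)
  pf <- lstm_params(5, 32)
  pb <- lstm_params(5, 32)
  x <- matrix(rnorm(7 * 5), 7, 5)
  out <- bilstm(x, pf, pb)
  expect_equal(dim(out), c(7, 64))
  # reversing the input swaps the roles of the two directions
  out_rev <- bilstm(x[7:1, ], pb, pf)
  expect_equal(out_rev[7:1, c(33:64, 1:32)], out, tolerance = 1e-12)
  # empty input
  expect_equal(dim(bilstm(x[0, , drop = FALSE], pf, pb)), c(0, 64))
})

test_that("single_attention matches Softmax-over-positions oracle", {
  # hand-computed 2x1 case: e = h = (1, 0)
  h <- matrix(c(1, 0), 2, 1)
  par <- list(M = diag(2), bias = matrix(0, 2, 1))
  out <- single_attention(h, par)
  expect_equal(out$alpha_bar, c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  expect_equal(as.vector(out$z), c(exp(1) / (exp(1) + 1), 0),
               tolerance = 1e-12)
  # normalization: each alpha column sums to 1, alpha_bar sums to 1
  set.seed(31)
  for (rep in 1:25) {
    l <- sample(2:6, 1); R <- sample(1:4, 1)
    h <- matrix(rnorm(l * R), l, R)
    par <- list(M = matrix(rnorm(l * l), l, l),
                bias = matrix(rnorm(l * R), l, R))
    out <- single_attention(h, par)
    expect_equal(colSums(out$alpha), rep(1, R), tolerance = 1e-6)
    expect_equal(sum(out$alpha_bar), 1, tolerance = 1e-6)
    want <- oracle_single_attention(h, par$M, par$bias)
    expect_equal(out$z, want$z, tolerance = 1e-6)
    expect_equal(out$alpha_bar, want$alpha_bar, tolerance = 1e-6)
  }
  # column-constant scores give uniform weights
  hc <- matrix(1, 3, 2)
  pc <- list(M = matrix(1 / 3, 3, 3), bias = matrix(0, 3, 2))
  expect_equal(single_attention(hc, pc)$alpha_bar, rep(1 / 3, 3))
  expect_error(single_attention(matrix(c(1, NA), 1), par), "non-finite")
})

test_that("pairwise_attention matches the scaled dot-product oracle", {
  set.seed(41)
  for (rep in 1:25) {
    l <- sample(2:5, 1); cdim <- sample(2:4, 1)
    h <- matrix(rnorm(l * cdim), l, cdim)
    par <- pairwise_attention_params(cdim, d_k = 3, d_v = 2)
    out <- pairwise_attention(h, par)
    expect_equal(rowSums(out$attention), rep(1, l), tolerance = 1e-6)
    want <- oracle_pairwise(h, par$W_Q, par$W_K, par$W_V, 3)
    expect_equal(out$Z, want$Z, tolerance = 1e-6)
    expect_equal(out$attention, want$A, tolerance = 1e-6)
  }
  # zero Q/K projections: uniform attention, Z replicates column means of V
  par0 <- pairwise_attention_params(3, d_k = 2, d_v = 2)
  par0$W_Q[] <- 0; par0$W_K[] <- 0
  h <- matrix(rnorm(12), 4, 3)
  out0 <- pairwise_attention(h, par0)
  expect_equal(out0$attention, matrix(1 / 4, 4, 4))
  V <- h %*% par0$W_V
  expect_equal(out0$Z, matrix(colMeans(V), 4, 2, byrow = TRUE))
  # default widths
  expect_equal(pairwise_attention_params(8)$d_k, 64)
  expect_equal(pairwise_attention_params(8)$d_v, 64)
  expect_error(pairwise_attention_params(3, d_k = 0), "d_k")
})

test_that("positional encoding follows the sinusoid table", {
  pe <- positional_encoding(10, 8)
  # row for position 0 alternates sin(0)=0 and cos(0)=1
  expect_equal(pe[1, ], rep(c(0, 1), 4))
  # pos=1, first column: denominator 10000^0 = 1
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_true(all(pe >= -1 & pe <= 1))
  # spot-check a general entry
  expect_equal(pe[4, 5], sin(3 / 10000^(4 / 8)), tolerance = 1e-12)
  expect_equal(pe[4, 6], cos(3 / 10000^(4 / 8)), tolerance = 1e-12)
})

test_that("PE(pos+k) is a fixed linear combination of PE(pos)", {
  d <- 8; L <- 64
  pe <- positional_encoding(L, d)
  for (k in c(1, 5, 17)) {
    # per-frequency rotation matrix, independent of position
    Tk <- matrix(0, d, d)
    for (i in 0:(d / 2 - 1)) {
      ang <- k / 10000^(2 * i / d)
      j <- 2 * i + 1
      Tk[j, j] <- cos(ang);     Tk[j + 1, j] <- sin(ang)
      Tk[j, j + 1] <- -sin(ang); Tk[j + 1, j + 1] <- cos(ang)
    }
    recon <- pe[1:(L - k), ] %*% Tk
    expect_equal(recon, pe[(1 + k):L, ], tolerance = 1e-9)
  }
})

test_that("softmax normalizes along the stated axis with max-shift", {
  x <- matrix(c(1000, 1001, -1000, 3), 2, 2)
  s1 <- softmax(x, axis = 1)
  expect_equal(colSums(s1), c(1, 1), tolerance = 1e-12)
  s2 <- softmax(x, axis = 2)
  expect_equal(rowSums(s2), c(1, 1), tolerance = 1e-12)
  expect_true(all(is.finite(s1)) && all(is.finite(s2)))
})

# generic nested get/add for the gradient check
leaf_paths <- function(x, prefix = character(0)) {
  if (is.numeric(x)) return(list(prefix))
  out <- list()
  for (nm in names(x)) {
    if (nm %in% c("hidden_size", "d_k", "d_v")) next
    out <- c(out, leaf_paths(x[[nm]], c(prefix, nm)))
  }
  out
}
get_leaf <- function(x, path) {
  for (nm in path) x <- x[[nm]]
  x
}
add_at <- function(x, path, i, delta) {
  if (length(path) == 1) {
    x[[path[1]]][i] <- x[[path[1]]][i] + delta
    return(x)
  }
  x[[path[1]]] <- add_at(x[[path[1]]], path[-1], i, delta)
  x
}

test_that("backpropagated gradients match finite differences", {
  set.seed(77)
  cfg <- model_config(bin_size = 20, flank = 15, conv_filters = 3,
                      conv_kernel = 6, pool_size = 3, lstm_units = 2,
                      d_k = 3, d_v = 3, dense_units = 4, dropout = 0,
                      seed = 5)
  m <- build_model(cfg)
  L <- cfg$input_length
  nb <- 2
  X <- array(rnorm(L * 6 * 2 * nb), dim = c(L, 6, 2 * nb))
  ns <- matrix(rnorm(2 * nb * 14), 2 * nb, 14)
  y <- c(1, 0)
  loss_of <- function(params) {
    m2 <- m; m2$params <- params
    fw <- attnbind:::network_forward(m2, X, ns)
    f <- ((fw$s_single[1:nb] + fw$s_single[nb + 1:nb]) / 2 +
            (fw$s_pair[1:nb] + fw$s_pair[nb + 1:nb]) / 2) / 2
    bce_loss(f, y)
  }
  fw <- attnbind:::network_forward(m, X, ns, want_cache = TRUE)
  f <- ((fw$s_single[1:nb] + fw$s_single[nb + 1:nb]) / 2 +
          (fw$s_pair[1:nb] + fw$s_pair[nb + 1:nb]) / 2) / 2
  eps <- 1e-7
  fc <- pmin(pmax(f, eps), 1 - eps)
  df <- (fc - y) / (fc * (1 - fc)) / nb
  bw <- attnbind:::network_backward(m, fw$cache,
                                    ds_single = rep(df / 4, 2),
                                    ds_pair = rep(df / 4, 2))
  paths <- leaf_paths(m$params)
  h <- 1e-5
  for (path in paths[seq(1, length(paths), by = 3)]) {
    g <- get_leaf(bw$grads, path)
    i <- sample(length(g), 1)
    fd <- (loss_of(add_at(m$params, path, i, h)) -
             loss_of(add_at(m$params, path, i, -h))) / (2 * h)
    denom <- max(1e-6, abs(fd) + abs(g[i]))
    expect_lt(abs(g[i] - fd) / denom, 1e-4,
              label = paste("gradient at", paste(path, collapse = "/")))
  }
})

test_that("forward pass is deterministic and strand-merge symmetric", {
  set.seed(12)
  cfg <- model_config(bin_size = 30, flank = 15, conv_filters = 4,
                      conv_kernel = 6, pool_size = 3, lstm_units = 3,
                      d_k = 4, d_v = 4, dense_units = 6, dropout = 0.3,
                      seed = 2)
  m <- build_model(cfg)
  L <- cfg$input_length
  mkblock <- function() {
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    blk <- cbind(one_hot(s), uniqueness = runif(L),
                 accessibility = runif(L) * 3)
    attr(blk, "strand") <- "forward"
    blk
  }
  bf <- mkblock()
  br <- reverse_complement_block(bf)
  ns <- rnorm(14)
  o1 <- model_forward(m, bf, br, ns)
  o2 <- model_forward(m, bf, br, ns)  # dropout must be inference-disabled
  expect_identical(o1$score, o2$score)
  expect_true(o1$score > 0 && o1$score < 1)
  # Siamese weight sharing + mean merge: swapping the strand inputs is a
  # no-op on the final score
  o3 <- model_forward(m, br, bf, ns)
  expect_equal(o3$score, o1$score, tolerance = 1e-12)
  # branch merge arithmetic
  expect_equal(o1$score, (o1$score_single + o1$score_pair) / 2)
})

test_that("model config round-trips through its yaml file", {
  cfg <- model_config(conv_filters = 8L, d_k = 16L, extras = "cgi",
                      merge_strands = "max", seed = 42L)
  path <- tempfile(fileext = ".yaml")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_equal(back, cfg)
})
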