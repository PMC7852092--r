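# The dual-branch attention network. A shared convolution + Bi-LSTM trunk
# feeds two heads -- the single (position-wise) attention branch and the
# pairwise (scaled dot-product) attention branch -- each ending in a dense
# layer that also receives the 14-long non-sequential vector and a sigmoid
# unit. Both DNA strands pass through the same weights (Siamese sharing);
# strand scores and branch scores are merged (mean by default).

#' Model configuration
#'
#' Collects every tunable hyperparameter of the network and training
#' scheme. Defaults follow the method's stated setup: 200-bp bins with
#' 400-bp flanks (1000-bp input), d_k = d_v = 64 pairwise-attention widths,
#' Adam at 1e-3 with binary cross-entropy, at most 60 epochs with
#' early stopping after 5 epochs without validation-auPRC improvement, and
#' balanced negative resampling each epoch.
#'
#' @param bin_size,flank Bin width and symmetric flank in bp; the input
#'   length is `bin_size + 2 * flank`.
#' @param conv_filters,conv_kernel 1-D convolution width and filter count.
#' @param pool_size Max-pooling width/stride after the convolution.
#' @param lstm_units Hidden size per Bi-LSTM direction.
#' @param d_k,d_v Pairwise-attention query/key and value widths.
#' @param dense_units Hidden units in each branch's dense head.
#' @param dropout Dropout rate on the dense hidden layer during training.
#' @param learning_rate Adam learning rate.
#' @param epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   auPRC improvement).
#' @param patience_tol Minimum increase counted as an improvement.
#' @param negative_ratio Negatives sampled per positive each epoch.
#' @param batch_size Samples (bin pairs) per gradient step.
#' @param merge_strands,merge_modules `"mean"` or `"max"` merging of the
#'   two strand scores and of the two branch scores.
#' @param extras Optional sequential channels among
#'   `c("conservation", "cgi")`.
#' @param shared_trunk Share one conv + Bi-LSTM trunk between the two
#'   attention branches (default) or train separate trunks.
#' @param positive_mode `"all_positives"` or `"peak_resample"` (one random
#'   200-bp window per ChIP peak each epoch).
#' @param seed Integer seed governing initialisation and sampling.
#' @param ... Override any field by name.
#' @return A list of class `"attnbind_config"`.
#' @export
model_config <- function(bin_size = 200L, flank = 400L,
                         conv_filters = 64L, conv_kernel = 34L,
                         pool_size = 10L, lstm_units = 32L,
                         d_k = 64L, d_v = 64L, dense_units = 64L,
                         dropout = 0.1, learning_rate = 1e-3,
                         epochs = 60L, patience = 5L, patience_tol = 1e-5,
                         negative_ratio = 1.0, batch_size = 32L,
                         merge_strands = c("mean", "max"),
                         merge_modules = c("mean", "max"),
                         extras = character(0), shared_trunk = TRUE,
                         positive_mode = c("all_positives", "peak_resample"),
                         seed = 1L, ...) {
  cfg <- list(bin_size = as.integer(bin_size), flank = as.integer(flank),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              pool_size = as.integer(pool_size),
              lstm_units = as.integer(lstm_units),
              d_k = as.integer(d_k), d_v = as.integer(d_v),
              dense_units = as.integer(dense_units),
              dropout = dropout, learning_rate = learning_rate,
              epochs = as.integer(epochs), patience = as.integer(patience),
              patience_tol = patience_tol,
              negative_ratio = negative_ratio,
              batch_size = as.integer(batch_size),
              merge_strands = match.arg(merge_strands),
              merge_modules = match.arg(merge_modules),
              extras = extras, shared_trunk = isTRUE(shared_trunk),
              positive_mode = match.arg(positive_mode),
              seed = as.integer(seed))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  cfg$input_length <- cfg$bin_size + 2L * cfg$flank
  class(cfg) <- "attnbind_config"
  cfg
}

#' Write / read a model configuration file
#'
#' Flat human-readable key-value YAML; round-trips every field.
#'
#' @param config Configuration from [model_config()].
#' @param path File path.
#' @return `read_model_config` returns the configuration.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$input_length <- NULL
  if (is.null(vals$extras)) vals$extras <- character(0)
  do.call(model_config, vals)
}

#' Attention-axis length implied by a configuration
#'
#' The input length shrinks to `L - conv_kernel + 1` after the (valid)
#' convolution and then by the pooling stride, giving the number of
#' positions the attention modules see.
#'
#' @param config Configuration from [model_config()].
#' @return Integer attention length.
#' @export
attention_length <- function(config) {
  (config$input_length - config$conv_kernel + 1L) %/% config$pool_size
}

init_trunk <- function(config, input_channels) {
  list(conv = list(W = glorot(config$conv_kernel * input_channels,
                              config$conv_filters),
                   b = rep(0, config$conv_filters)),
       lstm_f = lstm_params(config$conv_filters, config$lstm_units),
       lstm_b = lstm_params(config$conv_filters, config$lstm_units))
}

init_head <- function(n_in, n_hidden) {
  list(W1 = glorot(n_in, n_hidden), b1 = rep(0, n_hidden),
       W2 = glorot(n_hidden, 1L), b2 = 0)
}

#' Build an untrained dual-attention model
#'
#' Initialises all weights (Glorot-uniform, seeded from `config$seed`) for
#' the configured input shape.
#'
#' @param config Configuration from [model_config()].
#' @param input_channels Sequential channels (6 by default: A, C, G, T,
#'   uniqueness, accessibility; `extras` add more).
#' @param nonseq_size Length of the non-sequential vector (default
#'   6 annotation flags + 8 expression PCs = 14).
#' @return An object of class `"attnbind_model"`.
#' @export
build_model <- function(config, input_channels = 6L + length(config$extras),
                        nonseq_size = 14L) {
  l <- attention_length(config)
  if (l < 1) stop("configuration yields an empty attention axis")
  r2 <- 2L * config$lstm_units
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- list(
    trunk = init_trunk(config, input_channels),
    att = single_attention_params(l, r2),
    pw = pairwise_attention_params(r2, config$d_k, config$d_v),
    head_s = init_head(l * r2 + nonseq_size, config$dense_units),
    head_p = init_head(l * config$d_v + nonseq_size, config$dense_units)
  )
  if (!config$shared_trunk) {
    params$trunk_p <- init_trunk(config, input_channels)
  }
  structure(list(config = config, params = params,
                 input_channels = as.integer(input_channels),
                 nonseq_size = as.integer(nonseq_size),
                 l = l, pe = positional_encoding(l, r2),
                 conv_idx = conv_idx(config$input_length,
                                     as.integer(input_channels),
                                     config$conv_kernel)),
            class = "attnbind_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## ---- trunk -----------------------------------------------------------

trunk_forward <- function(trunk, X, model, want_cache = TRUE) {
  cfg <- model$config
  B <- dim(X)[3]
  cv <- conv1d_forward(X, trunk$conv$W, trunk$conv$b, model$conv_idx,
                       want_cache = want_cache)
  l1 <- nrow(model$conv_idx)
  pl <- maxpool_forward(cv$out, l1, cfg$pool_size, B,
                        want_cache = want_cache)
  l <- pl$l
  xs <- lapply(seq_len(l), function(t) {
    pl$out[t + (seq_len(B) - 1L) * l, , drop = FALSE]
  })
  lf <- lstm_seq_forward(xs, trunk$lstm_f, want_cache = want_cache)
  lb <- lstm_seq_forward(rev(xs), trunk$lstm_b, want_cache = want_cache)
  hs_b <- rev(lb$hs)
  r <- cfg$lstm_units
  arr <- array(unlist(lapply(seq_len(l), function(t) {
    cbind(lf$hs[[t]], hs_b[[t]])
  }), use.names = FALSE), dim = c(B, 2L * r, l))
  H <- aperm(arr, c(3, 2, 1))
  list(H = H, cv = cv, pl = pl, lf = lf, lb = lb, B = B, l = l)
}

trunk_backward <- function(dH, fw, trunk, model, want_dx = FALSE) {
  cfg <- model$config
  B <- fw$B; l <- fw$l; r <- cfg$lstm_units
  dHp <- aperm(dH, c(3, 2, 1))  # (B, 2r, l)
  dhs_f <- vector("list", l)
  dhs_b_rev <- vector("list", l)
  for (t in seq_len(l)) {
    dmat <- matrix(dHp[, , t], B, 2L * r)
    dhs_f[[t]] <- dmat[, seq_len(r), drop = FALSE]
    dhs_b_rev[[l - t + 1L]] <- dmat[, r + seq_len(r), drop = FALSE]
  }
  bf <- lstm_seq_backward(dhs_f, fw$lf$cache, trunk$lstm_f,
                          input_size = cfg$conv_filters, want_dx = TRUE)
  bb <- lstm_seq_backward(dhs_b_rev, fw$lb$cache, trunk$lstm_b,
                          input_size = cfg$conv_filters, want_dx = TRUE)
  dpool <- matrix(0, B * l, cfg$conv_filters)
  for (t in seq_len(l)) {
    rows <- t + (seq_len(B) - 1L) * l
    dpool[rows, ] <- bf$dxs[[t]] + bb$dxs[[l - t + 1L]]
  }
  dA <- maxpool_backward(dpool, fw$pl$cache)
  cb <- conv1d_backward(dA, fw$cv$cache, trunk$conv$W, want_dx = want_dx)
  list(grads = list(conv = list(W = cb$dW, b = cb$db),
                    lstm_f = bf$grads, lstm_b = bb$grads),
       dX = cb$dX)
}

## ---- dense heads -----------------------------------------------------

head_forward <- function(head, u, train = FALSE, dropout = 0) {
  z1 <- sweep(u %*% head$W1, 2, head$b1, "+")
  h1 <- pmax(z1, 0)
  mask <- NULL
  if (train && dropout > 0) {
    mask <- matrix(stats::rbinom(length(h1), 1, 1 - dropout),
                   nrow(h1)) / (1 - dropout)
    h1 <- h1 * mask
  }
  logit <- as.vector(h1 %*% head$W2) + head$b2
  list(s = sigmoid(logit), u = u, z1 = z1, h1 = h1, mask = mask,
       logit = logit)
}

head_backward <- function(ds, fw, head, is_logit_grad = FALSE) {
  dlogit <- if (is_logit_grad) ds else ds * fw$s * (1 - fw$s)
  dW2 <- crossprod(fw$h1, dlogit)
  db2 <- sum(dlogit)
  dh1 <- tcrossprod(matrix(dlogit, ncol = 1), head$W2)
  if (!is.null(fw$mask)) dh1 <- dh1 * fw$mask
  dh1 <- dh1 * (fw$z1 > 0)
  dW1 <- crossprod(fw$u, dh1)
  db1 <- colSums(dh1)
  du <- tcrossprod(dh1, head$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), du = du)
}

## ---- full forward / backward -----------------------------------------

merge_pair <- function(a, b, how) {
  if (how == "mean") (a + b) / 2 else pmax(a, b)
}

# X: L x C x B array; nonseq: B x nonseq_size. Rows of any strand pairing
# are handled by the caller. Returns branch scores per input block.
network_forward <- function(model, X, nonseq, want_cache = FALSE,
                            train = FALSE) {
  p <- model$params
  tr_s <- trunk_forward(p$trunk, X, model, want_cache = want_cache)
  tr_p <- if (model$config$shared_trunk) tr_s else
    trunk_forward(p$trunk_p, X, model, want_cache = want_cache)
  B <- tr_s$B; l <- tr_s$l
  r2 <- 2L * model$config$lstm_units

  # single-attention branch, batched over samples: the (l, r2, B) hidden
  # array viewed as l x (r2*B) puts each sample in its own column block
  H_all <- matrix(tr_s$H, l, r2 * B)
  e_all <- p$att$M %*% H_all + matrix(rep(p$att$bias, B), l)
  alpha_all <- softmax(e_all, axis = 1)
  Smean <- kronecker(diag(B), matrix(1 / r2, r2, 1))
  abar <- alpha_all %*% Smean                    # l x B
  abar_exp <- abar[, rep(seq_len(B), each = r2), drop = FALSE]
  z_all <- H_all * abar_exp
  U_s <- t(matrix(z_all, l * r2, B))

  U_p <- matrix(0, B, l * model$config$d_v)
  pa <- vector("list", B)
  for (bb in seq_len(B)) {
    hp_b <- matrix(tr_p$H[, , bb], l, r2) + model$pe
    pa[[bb]] <- pairwise_attention(hp_b, p$pw)
    U_p[bb, ] <- as.vector(pa[[bb]]$Z)
  }
  hs <- head_forward(p$head_s, cbind(U_s, nonseq), train,
                     model$config$dropout)
  hp <- head_forward(p$head_p, cbind(U_p, nonseq), train,
                     model$config$dropout)
  out <- list(s_single = hs$s, s_pair = hp$s)
  if (want_cache) {
    out$cache <- list(tr_s = tr_s, tr_p = tr_p, pa = pa,
                      H_all = H_all, alpha_all = alpha_all, abar = abar,
                      hs = hs, hp = hp, B = B, l = l, r2 = r2)
  }
  out
}

network_backward <- function(model, cache, ds_single, ds_pair,
                             want_dx = FALSE, is_logit_grad = FALSE) {
  p <- model$params
  cfg <- model$config
  B <- cache$B; l <- cache$l; r2 <- cache$r2
  bs <- head_backward(ds_single, cache$hs, p$head_s, is_logit_grad)
  bp <- head_backward(ds_pair, cache$hp, p$head_p, is_logit_grad)
  dU_s <- bs$du[, seq_len(l * r2), drop = FALSE]
  dU_p <- bp$du[, seq_len(l * cfg$d_v), drop = FALSE]

  # batched single-attention backward (mirrors the batched forward)
  H_all <- cache$H_all
  alpha_all <- cache$alpha_all
  abar_exp <- cache$abar[, rep(seq_len(B), each = r2), drop = FALSE]
  dz_all <- matrix(t(dU_s), l, r2 * B)
  Ssum <- kronecker(diag(B), matrix(1, r2, 1))
  dabar <- (dz_all * H_all) %*% Ssum             # l x B
  dh_all <- dz_all * abar_exp
  dalpha_all <- dabar[, rep(seq_len(B), each = r2), drop = FALSE] / r2
  colsum <- colSums(alpha_all * dalpha_all)
  de_all <- alpha_all * (dalpha_all - rep(colsum, each = l))
  g_att <- list(M = tcrossprod(de_all, H_all),
                bias = rowSums(array(de_all, c(l, r2, B)), dims = 2))
  dh_all <- dh_all + crossprod(p$att$M, de_all)
  dH_s <- array(dh_all, dim = c(l, r2, B))

  g_pw <- list(W_Q = p$pw$W_Q * 0, W_K = p$pw$W_K * 0, W_V = p$pw$W_V * 0)
  dH_p <- array(0, dim = dim(cache$tr_p$H))
  for (bb in seq_len(B)) {
    hp_b <- matrix(cache$tr_p$H[, , bb], l, r2) + model$pe
    dZ <- matrix(dU_p[bb, ], l, cfg$d_v)
    pab <- pairwise_attention_backward(dZ, cache$pa[[bb]], hp_b, p$pw)
    g_pw$W_Q <- g_pw$W_Q + pab$dW_Q
    g_pw$W_K <- g_pw$W_K + pab$dW_K
    g_pw$W_V <- g_pw$W_V + pab$dW_V
    dH_p[, , bb] <- pab$dh
  }
  grads <- list(att = g_att, pw = g_pw,
                head_s = bs$grads, head_p = bp$grads)
  if (cfg$shared_trunk) {
    tb <- trunk_backward(dH_s + dH_p, cache$tr_s, p$trunk, model,
                         want_dx = want_dx)
    grads$trunk <- tb$grads
    dX <- tb$dX
  } else {
    tb_s <- trunk_backward(dH_s, cache$tr_s, p$trunk, model,
                           want_dx = want_dx)
    tb_p <- trunk_backward(dH_p, cache$tr_p, p$trunk_p, model,
                           want_dx = want_dx)
    grads$trunk <- tb_s$grads
    grads$trunk_p <- tb_p$grads
    dX <- if (want_dx) tb_s$dX + tb_p$dX else NULL
  }
  list(grads = grads, dX = dX)
}

## ---- scoring ---------------------------------------------------------

#' Score one input region (both strands) through the full model
#'
#' Runs the Siamese forward pass on the forward-strand and
#' reverse-complement blocks, merges strand scores and branch scores
#' according to the configuration, and optionally returns the attention
#' traces of both branches on both strands.
#'
#' @param model Model from [build_model()] (or [fit_model()]).
#' @param block_fwd,block_rc L x C feature blocks from [assemble_block()].
#' @param nonseq Non-sequential vector (length `model$nonseq_size`).
#' @param want_traces Also return attention traces.
#' @return List with `score` (in (0,1)), per-branch scores `score_single`
#'   and `score_pair`, and (optionally) `traces`.
#' @export
model_forward <- function(model, block_fwd, block_rc,
                          nonseq = numeric(model$nonseq_size),
                          want_traces = FALSE) {
  X <- array(0, dim = c(nrow(block_fwd), ncol(block_fwd), 2L))
  X[, , 1] <- block_fwd
  X[, , 2] <- block_rc
  ns <- rbind(nonseq, nonseq)
  fw <- network_forward(model, X, ns, want_cache = want_traces)
  cfg <- model$config
  s_single <- merge_pair(fw$s_single[1], fw$s_single[2], cfg$merge_strands)
  s_pair <- merge_pair(fw$s_pair[1], fw$s_pair[2], cfg$merge_strands)
  out <- list(score = merge_pair(s_single, s_pair, cfg$merge_modules),
              score_single = s_single, score_pair = s_pair)
  if (want_traces) {
    out$traces <- list(
      single = list(forward = as.vector(fw$cache$abar[, 1]),
                    reverse_complement = as.vector(fw$cache$abar[, 2])),
      pairwise = list(forward = fw$cache$pa[[1]]$attention,
                      reverse_complement = fw$cache$pa[[2]]$attention))
  }
  out
}

#' Predict scores for a batch of paired-strand inputs
#'
#' @param model Model object.
#' @param X_fwd,X_rc L x C x B arrays of forward and reverse-complement
#'   blocks (sample b pairs `X_fwd[,,b]` with `X_rc[,,b]`).
#' @param nonseq B x nonseq_size matrix.
#' @param batch_size Samples per internal forward pass.
#' @return List with `score`, `score_single`, `score_pair` (length-B
#'   vectors, strand-merged).
#' @export
predict_scores <- function(model, X_fwd, X_rc, nonseq,
                           batch_size = 64L) {
  B <- dim(X_fwd)[3]
  cfg <- model$config
  score_s <- numeric(B); score_p <- numeric(B)
  for (lo in seq(1L, B, by = batch_size)) {
    hi <- min(B, lo + batch_size - 1L)
    nb <- hi - lo + 1L
    X <- array(0, dim = c(dim(X_fwd)[1], dim(X_fwd)[2], 2L * nb))
    X[, , seq_len(nb)] <- X_fwd[, , lo:hi]
    X[, , nb + seq_len(nb)] <- X_rc[, , lo:hi]
    ns <- rbind(nonseq[lo:hi, , drop = FALSE],
                nonseq[lo:hi, , drop = FALSE])
    fw <- network_forward(model, X, ns)
    score_s[lo:hi] <- merge_pair(fw$s_single[seq_len(nb)],
                                 fw$s_single[nb + seq_len(nb)],
                                 cfg$merge_strands)
    score_p[lo:hi] <- merge_pair(fw$s_pair[seq_len(nb)],
                                 fw$s_pair[nb + seq_len(nb)],
                                 cfg$merge_strands)
  }
  list(score = merge_pair(score_s, score_p, cfg$merge_modules),
       score_single = score_s, score_pair = score_p)
}

#' Save / load a model checkpoint
#'
#' One file holding the weights with the configuration embedded.
#'
#' @param model Model object.
#' @param path Checkpoint path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "attnbind_model"))
  m
}
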