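# Training: iterative per-epoch negative resampling, Adam + binary
# cross-entropy, validation-auPRC early stopping, and best-epoch model
# selection.

#' Binary cross-entropy loss
#'
#' @param scores Predicted probabilities in (0,1).
#' @param y 0/1 labels.
#' @param eps Clamp applied to scores for numerical safety.
#' @return Mean binary cross-entropy.
#' @export
bce_loss <- function(scores, y, eps = 1e-7) {
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

with_seed <- function(seed, expr) {
  force(seed)  # before the state snapshot, in case its promise draws
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

# fold (seed, salt) into the 32-bit range R's RNG accepts
mix_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 100003 + as.numeric(salt)) %% 2147483647)
}

#' Draw one epoch's training sample
#'
#' Positives are either every bound (B) bin (`mode = "all_positives"`) or
#' one uniformly placed `bin_size`-bp window inside each ChIP peak
#' (`mode = "peak_resample"`, the strategy used for factors with very many
#' bound sites). Negatives are freshly drawn each epoch, without
#' replacement, from the unbound (U) bins, `ratio` per positive (at least
#' one when any positive exists). Ambiguous (A) bins never enter the
#' sample. Deterministic given `seed` and `epoch_index`.
#'
#' @param labels Bin data.frame with a `label` column (B/U/A).
#' @param mode `"all_positives"` or `"peak_resample"`.
#' @param peaks narrowPeak data.frame, required for `"peak_resample"`.
#' @param ratio Negatives per positive (default 1).
#' @param seed Base seed.
#' @param epoch_index Epoch number (>= 1).
#' @param bin_size Window width for `"peak_resample"`.
#' @return List with `positives` and `negatives` bin data.frames,
#'   `epoch_index` and `seed`.
#' @export
sample_epoch <- function(labels, mode = c("all_positives", "peak_resample"),
                         peaks = NULL, ratio = 1.0, seed = 1L,
                         epoch_index = 1L, bin_size = 200L) {
  mode <- match.arg(mode)
  with_seed(mix_seed(seed, epoch_index), {
    if (mode == "all_positives") {
      pos <- labels[labels$label == "B", , drop = FALSE]
    } else {
      if (is.null(peaks)) stop("peak_resample requires a peak set")
      start <- integer(nrow(peaks))
      for (i in seq_len(nrow(peaks))) {
        lo <- peaks$start[i]
        hi <- peaks$end[i] - bin_size
        start[i] <- if (hi <= lo) {
          as.integer(round((peaks$start[i] + peaks$end[i]) / 2 -
                             bin_size / 2))
        } else {
          as.integer(lo + floor(runif(1) * (hi - lo + 1L)))
        }
      }
      pos <- data.frame(chrom = peaks$chrom, start = start,
                        end = start + as.integer(bin_size), label = "B",
                        stringsAsFactors = FALSE)
    }
    if (nrow(pos) == 0) stop("no positive bins: target is untrainable")
    neg_pool <- labels[labels$label == "U", , drop = FALSE]
    n_neg <- min(nrow(neg_pool), max(1L, floor(ratio * nrow(pos))))
    neg <- neg_pool[sample.int(nrow(neg_pool), n_neg), , drop = FALSE]
    list(positives = pos, negatives = neg,
         epoch_index = as.integer(epoch_index), seed = as.integer(seed))
  })
}

#' Early-stopping decision rule
#'
#' Patience-from-best: training stops after the first epoch at which the
#' validation metric has not improved (by more than `tol`) over the best
#' value for `patience` consecutive epochs.
#'
#' @param val_history Per-epoch validation metric values.
#' @param patience Consecutive non-improving epochs tolerated (default 5).
#' @param tol Minimum increase counted as improvement (default 1e-5).
#' @return List with `stop_epoch` (last epoch run; `length(val_history)`
#'   if patience is never exhausted) and `best_epoch`.
#' @export
early_stop_epoch <- function(val_history, patience = 5L, tol = 1e-5) {
  best <- -Inf
  best_epoch <- 0L
  since <- 0L
  for (e in seq_along(val_history)) {
    if (val_history[e] > best + tol) {
      best <- val_history[e]
      best_epoch <- e
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) {
        return(list(stop_epoch = e, best_epoch = best_epoch))
      }
    }
  }
  list(stop_epoch = length(val_history), best_epoch = best_epoch)
}

#' Pick the best candidate model by validation auPRC
#'
#' @param candidates List of lists, each with `weights` and `val_auprc`.
#' @return The `weights` of the highest-auPRC candidate; ties go to the
#'   earliest candidate.
#' @export
select_model <- function(candidates) {
  if (length(candidates) == 0) stop("no candidate models")
  scores <- vapply(candidates, function(c) c$val_auprc, numeric(1))
  candidates[[which.max(scores)]]$weights
}

merge_backward <- function(a, b, how, dm) {
  if (how == "mean") {
    list(da = dm / 2, db = dm / 2)
  } else {
    list(da = dm * (a >= b), db = dm * (a < b))
  }
}

# One gradient step on a batch of paired-strand samples. Every
# strand/branch output carries its own binary cross-entropy against the
# bin label (the gradient at each output logit is then the saturation-proof
# (s - y) form); the configured merges apply at prediction time. Jensen's
# inequality makes this per-output loss an upper bound on the loss of the
# merged score, so driving it down drives the ensemble down too.
train_step <- function(model, adam_state, Xb, nonseq2, y) {
  cfg <- model$config
  nb <- length(y)
  fw <- network_forward(model, Xb, nonseq2, want_cache = TRUE,
                        train = TRUE)
  y2 <- c(y, y)
  eps <- 1e-7
  cl <- function(s) pmin(pmax(s, eps), 1 - eps)
  loss <- (bce_loss(cl(fw$s_single), y2) + bce_loss(cl(fw$s_pair), y2)) / 2
  dlog_s <- (fw$s_single - y2) / (4 * nb)
  dlog_p <- (fw$s_pair - y2) / (4 * nb)
  bw <- network_backward(model, fw$cache, ds_single = dlog_s,
                         ds_pair = dlog_p, is_logit_grad = TRUE)
  upd <- adam_update(model$params, bw$grads, adam_state,
                     lr = cfg$learning_rate)
  model$params <- upd$params
  list(model = model, adam_state = upd$state, loss = loss)
}

#' Train on pre-encoded arrays for a fixed number of epochs
#'
#' The low-level loop behind [fit_model()]: shuffled minibatches, Adam,
#' binary cross-entropy on the merged score. No resampling and no early
#' stopping; use [fit_model()] for the full scheme.
#'
#' @param model Model from [build_model()].
#' @param X_fwd,X_rc L x C x B arrays of paired-strand blocks.
#' @param nonseq B x nonseq_size matrix.
#' @param y Length-B 0/1 labels.
#' @param epochs Number of passes over the data.
#' @param seed Seed for shuffling (and dropout).
#' @param adam_state Optional optimizer state to continue from.
#' @return List with `model`, `adam_state` and per-epoch `losses`.
#' @export
train_on_arrays <- function(model, X_fwd, X_rc, nonseq, y, epochs = 1L,
                            seed = model$config$seed, adam_state = NULL) {
  if (is.null(adam_state)) adam_state <- adam_init(model$params)
  B <- length(y)
  bs <- model$config$batch_size
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(B)
      batch_losses <- c()
      for (lo in seq(1L, B, by = bs)) {
        sel <- ord[lo:min(B, lo + bs - 1L)]
        nb <- length(sel)
        Xb <- array(0, dim = c(dim(X_fwd)[1], dim(X_fwd)[2], 2L * nb))
        Xb[, , seq_len(nb)] <- X_fwd[, , sel, drop = FALSE]
        Xb[, , nb + seq_len(nb)] <- X_rc[, , sel, drop = FALSE]
        ns2 <- rbind(nonseq[sel, , drop = FALSE],
                     nonseq[sel, , drop = FALSE])
        st <- train_step(model, adam_state, Xb, ns2, y[sel])
        model <- st$model
        adam_state <- st$adam_state
        batch_losses <- c(batch_losses, st$loss)
      }
      losses[ep] <- mean(batch_losses)
    }
  })
  list(model = model, adam_state = adam_state, losses = losses)
}

#' Encode a set of bins into paired-strand input arrays
#'
#' Expands each bin by the configured flank, assembles the sequential
#' feature block on both strands, and stacks them into arrays.
#'
#' @param bins Bin data.frame.
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param tracks Track list as for [assemble_block()].
#' @param config Model configuration.
#' @return List with `X_fwd`, `X_rc` (L x C x n arrays).
#' @export
encode_bins <- function(bins, genome, tracks, config) {
  chrom_lengths <- if (methods::is(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else {
    vapply(genome, nchar, integer(1))
  }
  n <- nrow(bins)
  L <- config$input_length
  C <- 6L + length(config$extras)
  X_fwd <- array(0, dim = c(L, C, n))
  X_rc <- array(0, dim = c(L, C, n))
  for (i in seq_len(n)) {
    region <- expand_bin(bins[i, ], flank = config$flank,
                         chrom_length = chrom_lengths[[bins$chrom[i]]])
    blocks <- assemble_block(region, genome, tracks, config$extras)
    X_fwd[, , i] <- blocks$forward
    X_rc[, , i] <- blocks$reverse_complement
  }
  list(X_fwd = X_fwd, X_rc = X_rc)
}

#' Fit the dual-attention model with iterative negative resampling
#'
#' Implements the full training scheme: each epoch pairs all positives (or
#' per-peak resampled windows) with freshly drawn negatives, takes
#' shuffled Adam steps on binary cross-entropy, and evaluates auROC/auPRC
#' on a fixed validation set. Training stops at the epoch cap or when the
#' validation auPRC has not improved for `config$patience` consecutive
#' epochs, and the weights of the best-validation epoch are returned.
#'
#' @param model Model from [build_model()].
#' @param labels Labeled bin data.frame (B/U/A) for the training cell type;
#'   blacklist-overlapping bins should already be dropped.
#' @param genome,tracks Inputs for [encode_bins()].
#' @param nonseq Either a length-`nonseq_size` vector used for every bin,
#'   or a function `f(bins)` returning an n x nonseq_size matrix (see
#'   [make_nonseq_builder()]).
#' @param train_chroms,val_chrom Chromosome split; they must be disjoint.
#' @param peaks Optional narrowPeak data.frame for
#'   `config$positive_mode == "peak_resample"`.
#' @param val_negative_ratio Validation negatives kept per validation
#'   positive (one fixed seeded draw; all negatives if fewer).
#' @param verbose Print per-epoch progress.
#' @return The trained model (best-epoch weights) with a `history`
#'   data.frame (`epoch`, `train_loss`, `val_auroc`, `val_auprc`) and
#'   `best_epoch` attached.
#' @export
fit_model <- function(model, labels, genome, tracks, nonseq,
                      train_chroms, val_chrom, peaks = NULL,
                      val_negative_ratio = 10, verbose = FALSE) {
  cfg <- model$config
  if (val_chrom %in% train_chroms) {
    stop("validation chromosome must be disjoint from training chromosomes")
  }
  train_labels <- labels[labels$chrom %in% train_chroms, , drop = FALSE]
  val_labels <- labels[labels$chrom %in% val_chrom &
                         labels$label != "A", , drop = FALSE]
  if (sum(val_labels$label == "B") == 0) {
    stop("validation set has no positive bins")
  }
  val_pos <- val_labels[val_labels$label == "B", , drop = FALSE]
  val_neg_pool <- val_labels[val_labels$label == "U", , drop = FALSE]
  n_vneg <- min(nrow(val_neg_pool),
                max(1L, floor(val_negative_ratio * nrow(val_pos))))
  val_neg <- with_seed(cfg$seed,
    val_neg_pool[sample.int(nrow(val_neg_pool), n_vneg), , drop = FALSE])
  ns_build <- if (is.function(nonseq)) {
    nonseq
  } else {
    function(b) matrix(rep(nonseq, nrow(b)), ncol = length(nonseq),
                       byrow = TRUE)
  }
  val_bins <- rbind(val_pos, val_neg)
  val_y <- as.integer(val_bins$label == "B")
  val_enc <- encode_bins(val_bins, genome, tracks, cfg)
  val_ns <- ns_build(val_bins)

  pos_enc <- NULL
  if (cfg$positive_mode == "all_positives") {
    pos_bins <- train_labels[train_labels$label == "B", , drop = FALSE]
    if (nrow(pos_bins) == 0) stop("no positive bins: target is untrainable")
    pos_enc <- encode_bins(pos_bins, genome, tracks, cfg)
  }

  adam_state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auroc = numeric(0), val_auprc = numeric(0))
  best_auprc <- -Inf
  best_params <- model$params
  best_epoch <- 0L
  since <- 0L
  for (ep in seq_len(cfg$epochs)) {
    es <- sample_epoch(train_labels, mode = cfg$positive_mode,
                       peaks = peaks, ratio = cfg$negative_ratio,
                       seed = cfg$seed, epoch_index = ep,
                       bin_size = cfg$bin_size)
    if (cfg$positive_mode == "all_positives") {
      ep_pos <- pos_enc
    } else {
      ep_pos <- encode_bins(es$positives, genome, tracks, cfg)
    }
    neg_enc <- encode_bins(es$negatives, genome, tracks, cfg)
    n_pos <- dim(ep_pos$X_fwd)[3]
    n_neg <- dim(neg_enc$X_fwd)[3]
    L <- cfg$input_length; C <- dim(ep_pos$X_fwd)[2]
    X_fwd <- array(0, dim = c(L, C, n_pos + n_neg))
    X_rc <- array(0, dim = c(L, C, n_pos + n_neg))
    X_fwd[, , seq_len(n_pos)] <- ep_pos$X_fwd
    X_fwd[, , n_pos + seq_len(n_neg)] <- neg_enc$X_fwd
    X_rc[, , seq_len(n_pos)] <- ep_pos$X_rc
    X_rc[, , n_pos + seq_len(n_neg)] <- neg_enc$X_rc
    y <- c(rep(1L, n_pos), rep(0L, n_neg))
    ns <- rbind(ns_build(es$positives), ns_build(es$negatives))
    tr <- train_on_arrays(model, X_fwd, X_rc, ns, y, epochs = 1L,
                          seed = mix_seed(cfg$seed, 7L * ep),
                          adam_state = adam_state)
    model <- tr$model
    adam_state <- tr$adam_state
    val_pred <- predict_scores(model, val_enc$X_fwd, val_enc$X_rc, val_ns)
    sl <- scored_labels(val_pred$score, val_y)
    v_auroc <- auroc(sl)
    v_auprc <- auprc(sl)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = tr$losses[1],
                                val_auroc = v_auroc, val_auprc = v_auprc))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f val_auROC %.3f val_auPRC %.3f",
                      ep, tr$losses[1], v_auroc, v_auprc))
    }
    if (v_auprc > best_auprc + cfg$patience_tol) {
      best_auprc <- v_auprc
      best_params <- model$params
      best_epoch <- ep
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= cfg$patience) break
    }
  }
  model$params <- best_params
  model$history <- history
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  model
}
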