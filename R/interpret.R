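# Interpretation: attention extraction mapped back to genome coordinates,
# gradient saliency, candidate-bin filtering, 20-bp motif-window
# extraction around attention peaks, internal PWM scanning, and
# attention-vs-ChIP-fold-change correlation.

#' Map an attention position to a genomic coordinate
#'
#' The attention axis is shorter than the input because of the convolution
#' and pooling; the map is affine: position p (1-based) sits at
#' `origin + (p - 1) * downsample_factor + downsample_factor / 2`, where
#' `origin` is the region start shifted by the convolution's
#' receptive-field center.
#'
#' @param trace An attention trace from [extract_attention()].
#' @param pos 1-based attention position(s).
#' @return Genomic bp coordinate(s).
#' @export
attention_to_genomic <- function(trace, pos) {
  trace$origin + (pos - 1) * trace$downsample_factor +
    trace$downsample_factor / 2
}

#' Extract attention traces for one input region
#'
#' Returns per-position attention weights from both branches on both
#' strands. Reverse-complement-strand traces are reversed along the
#' position axis so both strands share the forward genomic orientation.
#' Every trace carries the affine coordinate map (`downsample_factor`,
#' `origin`) back to genomic bp.
#'
#' @param model Trained model.
#' @param region Region list from [expand_bin()].
#' @param block_fwd,block_rc Feature blocks for the region.
#' @param nonseq Non-sequential vector.
#' @return List with `single` (per strand: normalized weight vectors
#'   summing to 1) and `pairwise` (per strand: `matrix` and `colsum`),
#'   plus `score`, `downsample_factor`, `origin`.
#' @export
extract_attention <- function(model, region, block_fwd, block_rc,
                              nonseq = numeric(model$nonseq_size)) {
  fw <- model_forward(model, block_fwd, block_rc, nonseq,
                      want_traces = TRUE)
  cfg <- model$config
  ds <- cfg$pool_size
  origin <- region$region_start - region$pad_left +
    (cfg$conv_kernel - 1) / 2
  l <- model$l
  rc_alpha <- rev(fw$traces$single$reverse_complement)
  rc_mat <- fw$traces$pairwise$reverse_complement[l:1, l:1, drop = FALSE]
  list(single = list(forward = fw$traces$single$forward,
                     reverse_complement = rc_alpha),
       pairwise = list(
         forward = list(matrix = fw$traces$pairwise$forward,
                        colsum = colSums(fw$traces$pairwise$forward)),
         reverse_complement = list(matrix = rc_mat,
                                   colsum = colSums(rc_mat))),
       score = fw$score, score_single = fw$score_single,
       score_pair = fw$score_pair,
       downsample_factor = ds, origin = origin)
}

#' Gradient saliency of the output score over the input region
#'
#' Backpropagates the merged output score to the sequential input and
#' reduces over channels per position (max of absolute gradients by
#' default, switchable to the L2 norm). The reverse-complement strand is
#' reversed so both vectors share the forward orientation.
#'
#' @param model Trained model.
#' @param block_fwd,block_rc Feature blocks.
#' @param nonseq Non-sequential vector.
#' @param reduce `"max_abs"` or `"l2"` channel reduction.
#' @return List with per-position vectors `forward` and
#'   `reverse_complement` (both length L).
#' @export
saliency <- function(model, block_fwd, block_rc,
                     nonseq = numeric(model$nonseq_size),
                     reduce = c("max_abs", "l2")) {
  reduce <- match.arg(reduce)
  cfg <- model$config
  L <- nrow(block_fwd); C <- ncol(block_fwd)
  X <- array(0, dim = c(L, C, 2L))
  X[, , 1] <- block_fwd
  X[, , 2] <- block_rc
  ns <- rbind(nonseq, nonseq)
  fw <- network_forward(model, X, ns, want_cache = TRUE)
  s1_s <- fw$s_single[1]; s2_s <- fw$s_single[2]
  s1_p <- fw$s_pair[1]; s2_p <- fw$s_pair[2]
  ms_s <- merge_pair(s1_s, s2_s, cfg$merge_strands)
  ms_p <- merge_pair(s1_p, s2_p, cfg$merge_strands)
  mb <- merge_backward(ms_s, ms_p, cfg$merge_modules, 1)
  sb_s <- merge_backward(s1_s, s2_s, cfg$merge_strands, mb$da)
  sb_p <- merge_backward(s1_p, s2_p, cfg$merge_strands, mb$db)
  bw <- network_backward(model, fw$cache,
                         ds_single = c(sb_s$da, sb_s$db),
                         ds_pair = c(sb_p$da, sb_p$db),
                         want_dx = TRUE)
  red <- function(g) {
    m <- matrix(g, L, C)
    if (reduce == "max_abs") apply(abs(m), 1, max) else sqrt(rowSums(m^2))
  }
  list(forward = red(bw$dX[, 1]),
       reverse_complement = rev(red(bw$dX[, 2])))
}

#' Filter predicted-positive bins lacking a dominant accessibility peak
#'
#' Motif analysis targets bins the model calls bound (score > 0.5) that
#' cannot be explained by an obvious DNase spike: bins whose input-region
#' coverage has max/mean ratio of 15 or more are removed, as are bins with
#' all-zero coverage.
#'
#' @param predictions Bin data.frame with a `score` column.
#' @param access_track Per-chromosome list of per-base accessibility.
#' @param config Model configuration (for the flank).
#' @param chrom_lengths Named chromosome lengths.
#' @param score_threshold Positive-call threshold (default 0.5).
#' @param peak_ratio_limit Maximum allowed max/mean coverage ratio
#'   (default 15).
#' @return The retained rows of `predictions`.
#' @export
filter_candidate_bins <- function(predictions, access_track, config,
                                  chrom_lengths, score_threshold = 0.5,
                                  peak_ratio_limit = 15) {
  keep <- logical(nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    if (predictions$score[i] <= score_threshold) next
    region <- expand_bin(predictions[i, ], flank = config$flank,
                         chrom_length = chrom_lengths[[predictions$chrom[i]]])
    v <- access_track[[predictions$chrom[i]]][
      (region$region_start + 1L):region$region_end]
    m <- mean(v)
    if (m > 0 && max(v) / m < peak_ratio_limit) keep[i] <- TRUE
  }
  predictions[keep, , drop = FALSE]
}

#' Extract 20-bp motif windows around attention peaks
#'
#' For each bin, finds the attention position with the maximum weight
#' (pairwise-branch column sums by default, averaged over the forward and
#' reversed reverse-complement strands; leftmost on ties), maps it to a
#' genomic coordinate, and cuts a window of `window` bp centered there,
#' shifted to stay inside the input region.
#'
#' @param bins Bin data.frame (rows aligned with `traces`).
#' @param traces List of per-bin outputs of [extract_attention()].
#' @param regions List of per-bin regions from [expand_bin()].
#' @param genome Genome for subsequence extraction.
#' @param window Window length in bp (default 20).
#' @param branch `"pairwise"` (column sums) or `"single"` (alpha-bar).
#' @return data.frame with `chrom`, `start`, `end`,
#'   `attention_peak_coord`, `source_start`, `source_end`, `sequence`.
#' @export
extract_motif_windows <- function(bins, traces, regions, genome,
                                  window = 20L,
                                  branch = c("pairwise", "single")) {
  branch <- match.arg(branch)
  seqs <- if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else genome
  out <- vector("list", nrow(bins))
  for (i in seq_len(nrow(bins))) {
    tr <- traces[[i]]
    w <- if (branch == "pairwise") {
      (tr$pairwise$forward$colsum + tr$pairwise$reverse_complement$colsum) / 2
    } else {
      (tr$single$forward + tr$single$reverse_complement) / 2
    }
    p <- which.max(w)  # which.max takes the leftmost maximum
    center <- round(attention_to_genomic(tr, p))
    start <- as.integer(center - window %/% 2)
    region <- regions[[i]]
    start <- max(start, region$region_start)
    start <- min(start, region$region_end - window)
    end <- start + as.integer(window)
    out[[i]] <- data.frame(
      chrom = bins$chrom[i], start = start, end = end,
      attention_peak_coord = center,
      source_start = bins$start[i], source_end = bins$end[i],
      sequence = substr(seqs[[bins$chrom[i]]], start + 1L, end),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Scan sequences with a PWM (log-odds, both strands)
#'
#' For each sequence, the best `sum(log2(p_b / background))` over all
#' offsets and both strands. Zero probabilities are floored. Ties prefer
#' the forward strand, then the leftmost offset.
#'
#' @param sequences Character vector of DNA sequences.
#' @param pwm 4 x W probability matrix with rows A, C, G, T.
#' @param background Background base probability (default 0.25).
#' @param prob_floor Floor applied to PWM entries (default 1e-3).
#' @return data.frame with `score`, `offset` (0-based), `strand` per
#'   sequence.
#' @export
pwm_scan <- function(sequences, pwm, background = 0.25,
                     prob_floor = 1e-3) {
  stopifnot(nrow(pwm) == 4)
  pwm <- pmax(pwm, prob_floor)
  logodds <- log2(pwm / background)
  W <- ncol(pwm)
  rc_logodds <- logodds[4:1, W:1, drop = FALSE]  # reverse complement scan
  scan_one <- function(s, lo) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    n <- length(idx)
    if (n < W) return(numeric(0))
    vapply(0:(n - W), function(off) {
      b <- idx[off + seq_len(W)]
      if (anyNA(b)) return(-Inf)
      sum(lo[cbind(b, seq_len(W))])
    }, numeric(1))
  }
  res <- lapply(sequences, function(s) {
    sf <- scan_one(s, logodds)
    sr <- scan_one(s, rc_logodds)
    if (length(sf) == 0) return(list(score = NA_real_, offset = NA_integer_,
                                     strand = NA_character_))
    best <- max(c(sf, sr))
    if (max(sf) >= best) {
      list(score = best, offset = which.max(sf) - 1L, strand = "+")
    } else {
      list(score = best, offset = which.max(sr) - 1L, strand = "-")
    }
  })
  data.frame(score = vapply(res, `[[`, numeric(1), "score"),
             offset = vapply(res, `[[`, integer(1), "offset"),
             strand = vapply(res, `[[`, character(1), "strand"),
             stringsAsFactors = FALSE)
}

#' Correlate attention weights with a ChIP fold-change track
#'
#' Averages the fold-change track within each attention position's
#' footprint, z-scores both the attention vector and the track vector per
#' bin, pools the pairs over bins, and reports Pearson and Spearman
#' coefficients.
#'
#' @param traces List of per-bin [extract_attention()] outputs.
#' @param fold_track Per-chromosome list of per-base fold-change values.
#' @param bins Bin data.frame aligned with `traces`.
#' @param branch `"single"` (alpha-bar, default) or `"pairwise"`
#'   (column sums), averaged over strands.
#' @return List with `pearson`, `spearman`, `n_pairs`, and the pooled
#'   `attention` / `fold_change` vectors.
#' @export
attention_signal_correlation <- function(traces, fold_track, bins,
                                         branch = c("single", "pairwise")) {
  branch <- match.arg(branch)
  att_all <- c(); fc_all <- c()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    w <- if (branch == "single") {
      (tr$single$forward + tr$single$reverse_complement) / 2
    } else {
      (tr$pairwise$forward$colsum + tr$pairwise$reverse_complement$colsum) / 2
    }
    l <- length(w)
    ds <- tr$downsample_factor
    v <- fold_track[[bins$chrom[i]]]
    fc <- vapply(seq_len(l), function(p) {
      lo <- floor(tr$origin + (p - 1) * ds) + 1L
      hi <- min(length(v), lo + ds - 1L)
      lo <- max(1L, lo)
      mean(v[lo:hi])
    }, numeric(1))
    zs <- function(x) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }
    att_all <- c(att_all, zs(w))
    fc_all <- c(fc_all, zs(fc))
  }
  if (stats::sd(att_all) == 0 || stats::sd(fc_all) == 0) {
    stop("correlation undefined: zero variance in pooled values")
  }
  list(pearson = cor(att_all, fc_all, method = "pearson"),
       spearman = cor(att_all, fc_all, method = "spearman"),
       n_pairs = length(att_all),
       attention = att_all, fold_change = fc_all)
}

#' One-sided permutation test for positive correlation
#'
#' @param x,y Paired numeric vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return p-value for the alternative `cor(x, y) > 0`.
#' @export
cor_permutation_pvalue <- function(x, y, n_perm = 1000L, seed = 1L) {
  obs <- cor(x, y)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) cor(x, sample(y)),
                   numeric(1))
    (1 + sum(perm >= obs)) / (n_perm + 1)
  })
}
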