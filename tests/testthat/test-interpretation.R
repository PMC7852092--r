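tiny_trained_free_model <- function() {
  cfg <- model_config(bin_size = 40, flank = 30, conv_kernel = 8,
                      conv_filters = 4, pool_size = 4, lstm_units = 3,
                      d_k = 4, d_v = 4, dense_units = 6, dropout = 0,
                      seed = 3)
  build_model(cfg)
}

test_that("pwm_scan equals exhaustive offset-and-strand enumeration", {
  oracle_scan <- function(s, pwm, floor = 1e-3) {
    pwm <- pmax(pwm, floor)
    lo <- log2(pwm / 0.25)
    W <- ncol(pwm)
    bases <- c("A", "C", "G", "T")
    rc <- function(x) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(x, "")[[1]]), collapse = ""))
    best <- -Inf
    for (strand in c("+", "-")) {
      seq_use <- if (strand == "+") s else rc(s)
      for (off in 0:(nchar(s) - W)) {
        sub <- substr(seq_use, off + 1, off + W)
        idx <- match(strsplit(sub, "")[[1]], bases)
        sc <- sum(lo[cbind(idx, 1:W)])
        if (sc > best) best <- sc
      }
    }
    best
  }
  set.seed(13)
  pwm <- make_pwm("ACGTAC", sharpness = 0.8)
  seqs <- replicate(30, paste(sample(c("A", "C", "G", "T"), 15, TRUE),
                              collapse = ""))
  res <- pwm_scan(seqs, pwm)
  for (i in seq_along(seqs)) {
    expect_equal(res$score[i], oracle_scan(seqs[i], pwm),
                 tolerance = 1e-12, info = seqs[i])
  }
})

test_that("pwm_scan consensus, uniform, and strand-symmetry properties", {
  pwm <- make_pwm("ACGTAC", sharpness = 0.996)
  # consensus sequence achieves the maximal score ~ W * log2(p_max/0.25)
  res <- pwm_scan(c("ACGTAC", "TTTTTT", "GTACGT"), pwm)
  expect_equal(res$score[1], sum(log2(pmax(pwm, 1e-3)[cbind(
    match(strsplit("ACGTAC", "")[[1]], c("A", "C", "G", "T")), 1:6)] /
      0.25)), tolerance = 1e-12)
  expect_true(res$score[1] >= max(res$score))
  # RC of the consensus scores identically (on the minus strand)
  rc <- "GTACGT"
  expect_equal(pwm_scan(rc, pwm)$score, res$score[1], tolerance = 1e-12)
  expect_equal(pwm_scan(rc, pwm)$strand, "-")
  # uniform PWM scores 0 everywhere
  u <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pwm_scan("ACGTACGT", u)$score, 0)
})

test_that("attention traces normalize, map coordinates, and align strands", {
  m <- tiny_trained_free_model()
  cfg <- m$config
  L <- cfg$input_length
  set.seed(2)
  g <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                         collapse = ""))
  tracks <- list(uniqueness = list(chr1 = rep(1, 2000)),
                 accessibility = list(chr1 = runif(2000)))
  bin <- data.frame(chrom = "chr1", start = 1000, end = 1040)
  region <- expand_bin(bin, flank = cfg$flank, chrom_length = 2000)
  blocks <- assemble_block(region, g, tracks)
  tr <- extract_attention(m, region, blocks$forward,
                          blocks$reverse_complement)
  expect_equal(sum(tr$single$forward), 1, tolerance = 1e-6)
  expect_equal(sum(tr$single$reverse_complement), 1, tolerance = 1e-6)
  expect_length(tr$single$forward, m$l)
  expect_length(tr$pairwise$forward$colsum, m$l)
  expect_equal(dim(tr$pairwise$forward$matrix), c(m$l, m$l))
  # coordinate map: attention positions land inside the region, and the
  # round trip is exact to within one downsample factor
  coords <- attention_to_genomic(tr, seq_len(m$l))
  expect_true(all(coords >= region$region_start &
                    coords <= region$region_end))
  p_back <- (coords - tr$origin - tr$downsample_factor / 2) /
    tr$downsample_factor + 1
  expect_equal(p_back, seq_len(m$l), tolerance = 1e-9)
})

test_that("saliency has input resolution and responds to the merge head", {
  m <- tiny_trained_free_model()
  cfg <- m$config
  L <- cfg$input_length
  set.seed(6)
  s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  bf <- cbind(one_hot(s), uniqueness = rep(1, L),
              accessibility = runif(L))
  attr(bf, "strand") <- "forward"
  br <- reverse_complement_block(bf)
  sal <- saliency(m, bf, br)
  expect_length(sal$forward, L)
  expect_length(sal$reverse_complement, L)
  expect_true(all(sal$forward >= 0))
  # zeroed output head kills every gradient
  m0 <- m
  m0$params$head_s$W1[] <- 0; m0$params$head_s$W2[] <- 0
  m0$params$head_p$W1[] <- 0; m0$params$head_p$W2[] <- 0
  sal0 <- saliency(m0, bf, br)
  expect_equal(sal0$forward, rep(0, L))
})

test_that("filter_candidate_bins applies score and coverage-ratio rules", {
  cfg <- model_config(bin_size = 40, flank = 30)
  chrom_lengths <- c(chr1 = 1000)
  preds <- data.frame(chrom = "chr1",
                      start = c(100, 300, 500, 700),
                      end = c(140, 340, 540, 740),
                      score = c(0.9, 0.9, 0.4, 0.9))
  flat <- rep(2, 1000)
  spike <- flat
  spike[320] <- 600  # a single dominant spike inside the second region
  zero <- rep(0, 1000)
  track <- list(chr1 = flat)
  kept <- filter_candidate_bins(preds, track, cfg, chrom_lengths)
  expect_equal(kept$start, c(100, 300, 700))  # score 0.4 dropped
  track2 <- list(chr1 = spike)
  kept2 <- filter_candidate_bins(preds, track2, cfg, chrom_lengths)
  expect_false(300 %in% kept2$start)  # dominant spike dropped
  expect_true(700 %in% kept2$start)
  kept3 <- filter_candidate_bins(preds, list(chr1 = zero), cfg,
                                 chrom_lengths)
  expect_equal(nrow(kept3), 0)  # zero-mean bins dropped
})

test_that("motif windows are 20 bp, inside the region, centered on the
           attention peak", {
  m <- tiny_trained_free_model()
  cfg <- m$config
  set.seed(3)
  g <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                         collapse = ""))
  tracks <- list(uniqueness = list(chr1 = rep(1, 2000)),
                 accessibility = list(chr1 = runif(2000)))
  bins <- data.frame(chrom = "chr1", start = c(500, 1500),
                     end = c(540, 1540))
  regions <- lapply(seq_len(nrow(bins)), function(i) {
    expand_bin(bins[i, ], flank = cfg$flank, chrom_length = 2000)
  })
  traces <- lapply(regions, function(r) {
    blocks <- assemble_block(r, g, tracks)
    extract_attention(m, r, blocks$forward, blocks$reverse_complement)
  })
  win <- extract_motif_windows(bins, traces, regions, g)
  expect_equal(win$end - win$start, rep(20, 2))
  for (i in 1:2) {
    expect_gte(win$start[i], regions[[i]]$region_start)
    expect_lte(win$end[i], regions[[i]]$region_end)
    expect_equal(nchar(win$sequence[i]), 20)
    # the window's sequence matches the genome at its coordinates
    expect_equal(win$sequence[i],
                 substr(g$chr1, win$start[i] + 1, win$end[i]))
  }
})

test_that("attention-signal correlation detects aligned and anti-aligned
           fixtures", {
  # synthetic trace objects with a known coordinate map
  mk_trace <- function(w) {
    list(single = list(forward = w / sum(w),
                       reverse_complement = w / sum(w)),
         downsample_factor = 10, origin = 0)
  }
  l <- 50
  peak <- exp(-((1:l) - 25)^2 / 18)
  track_peak <- rep(peak, each = 10)  # same shape at base resolution
  tr <- list(mk_trace(peak))
  bins <- data.frame(chrom = "chr1", start = 0, end = 200)
  res <- attention_signal_correlation(tr, list(chr1 = track_peak), bins)
  expect_gt(res$pearson, 0.99)
  # reversed track anti-aligns a sharp asymmetric peak
  sharp <- c(rep(0.01, 10), 5, rep(0.01, l - 11))
  res2 <- attention_signal_correlation(list(mk_trace(sharp)),
                                       list(chr1 = rev(rep(sharp,
                                                           each = 10))),
                                       bins)
  expect_lt(res2$pearson, 0)
  # zero-variance input errors
  expect_error(attention_signal_correlation(
    list(mk_trace(rep(1, l))), list(chr1 = rep(1, 10 * l)), bins),
    "zero variance")
})

test_that("permutation p-value is small for a strong positive
           correlation and large for noise", {
  set.seed(8)
  x <- rnorm(100)
  y <- x + rnorm(100, sd = 0.3)
  expect_lt(cor_permutation_pvalue(x, y, n_perm = 200, seed = 2), 0.01)
  z <- rnorm(100)
  expect_gt(cor_permutation_pvalue(x, z, n_perm = 200, seed = 2), 0.05)
})
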