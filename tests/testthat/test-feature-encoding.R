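test_that("one_hot encodes A/C/G/T columns with N rows all zero", {
  m <- one_hot("ACGT")
  expect_equal(unname(m), rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_equal(unname(one_hot("NN")), matrix(0, 2, 4))
  expect_equal(dim(one_hot(strrep("ACGTN", 200))), c(1000, 4))
  expect_true(all(rowSums(one_hot("acgtn")) == c(1, 1, 1, 1, 0)))
  expect_error(one_hot("ACXT"), "position 3")
})

test_that("reverse_complement_block complements bases, reverses tracks", {
  blk <- cbind(one_hot("AACG"), uniqueness = c(0.1, 0.2, 0.3, 0.4),
               accessibility = c(5, 6, 7, 8))
  attr(blk, "strand") <- "forward"
  rc <- reverse_complement_block(blk)
  expect_equal(unname(rc[, 1:4]), unname(one_hot("CGTT")))
  expect_equal(unname(rc[, "uniqueness"]), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(unname(rc[, "accessibility"]), c(8, 7, 6, 5))
  expect_equal(attr(rc, "strand"), "reverse_complement")
  # involution
  back <- reverse_complement_block(rc)
  expect_equal(unname(back), unname(blk))
  expect_equal(attr(back, "strand"), "forward")
})

test_that("uniqueness_track implements the inverse-occurrence rule", {
  # genome built so chosen k-mers occur exactly 1, 2 and 5 times (both
  # strands counted); k small to keep the construction transparent
  k <- 5
  unique_mer <- "ACGTC"
  twice_mer <- "GGATG"
  five_mer <- "TTTAA"
  spacer <- "CCCCCCC"
  g <- list(chr1 = paste0(unique_mer, spacer, twice_mer, spacer, twice_mer,
                          spacer, paste(rep(five_mer, 5),
                                        collapse = spacer)))
  tr <- uniqueness_track(g, k = k)$chr1
  expect_equal(tr[1], 1)                 # unique k-mer
  expect_equal(tr[13], 0.5)              # occurs twice
  five_pos <- as.integer(regexpr("TTTAA", g$chr1))
  expect_equal(tr[five_pos], 0)          # occurs five times
  # trailing k-1 positions are 0
  n <- nchar(g$chr1)
  expect_equal(tr[(n - k + 2):n], rep(0, k - 1))
})

test_that("uniqueness scores agree with exhaustive k-mer counting", {
  set.seed(11)
  g <- list(c1 = paste(sample(c("A", "C", "G", "T"), 800, TRUE),
                       collapse = ""),
            c2 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                       collapse = ""))
  k <- 6
  tr <- uniqueness_track(g, k = k)
  # brute-force oracle: count each k-mer across both strands by regex-free
  # enumeration
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  all_mers <- c()
  for (s in g) {
    n <- nchar(s)
    all_mers <- c(all_mers, substring(s, 1:(n - k + 1), k:n),
                  substring(rc(s), 1:(n - k + 1), k:n))
  }
  for (chrom in names(g)) {
    s <- g[[chrom]]
    n <- nchar(s)
    for (p in sample(1:(n - k + 1), 25)) {
      mer <- substr(s, p, p + k - 1)
      occ <- sum(all_mers == mer)
      want <- if (occ > 4) 0 else 1 / occ
      expect_equal(tr[[chrom]][p], want)
    }
  }
  # values confined to {0, 1, 1/2, 1/3, 1/4}
  expect_true(all(unlist(tr) %in% c(0, 1, 1 / 2, 1 / 3, 1 / 4)))
})

test_that("normalize_coverage_1x scales to unit genome-wide mean", {
  expect_equal(normalize_coverage_1x(rep(4, 10), 10), rep(1, 10))
  expect_equal(normalize_coverage_1x(rep(0, 5), 5), rep(0, 5))
  expect_equal(normalize_coverage_1x(c(2, 2, 6, 6), 4),
               c(0.5, 0.5, 1.5, 1.5))
  expect_error(normalize_coverage_1x(1:3, 0), "must be > 0")
  # scale equivariance
  x <- runif(20) * 7
  expect_equal(normalize_coverage_1x(3.7 * x, 20),
               normalize_coverage_1x(x, 20))
  # list form shares one constant
  out <- normalize_coverage_1x(list(a = c(2, 2), b = c(6, 6)), 4)
  expect_equal(out, list(a = c(0.5, 0.5), b = c(1.5, 1.5)))
})

test_that("annotation_vector flags overlap per category", {
  bin <- data.frame(chrom = "chr1", start = 1000, end = 1200)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  sets <- list(coding = empty, intron = empty,
               promoter = data.frame(chrom = "chr1", start = 1100,
                                     end = 1500),
               utr5 = empty, utr3 = empty, cgi = empty)
  v <- annotation_vector(bin, sets)
  expect_equal(unname(v), c(0, 0, 1, 0, 0, 0))
  expect_length(v, 6)
  sets_none <- lapply(sets, function(x) empty)
  expect_equal(unname(annotation_vector(bin, sets_none)), rep(0L, 6))
  expect_error(annotation_vector(bin, sets[1:5]), "six")
})

test_that("expression_pcs has length 8, symmetry, and rank padding", {
  set.seed(2)
  tpm <- matrix(rexp(50 * 4, 1 / 100), 50, 4,
                dimnames = list(NULL, paste0("c", 1:4)))
  pcs <- expression_pcs(tpm)
  expect_equal(dim(pcs), c(4, 8))
  # identical columns give identical score vectors
  tpm2 <- cbind(a = tpm[, 1], b = tpm[, 1], c = tpm[, 2])
  p2 <- expression_pcs(tpm2)
  expect_equal(p2["a", ], p2["b", ])
  # 3 cell types -> rank <= 2 -> components 3..8 exactly 0
  expect_equal(unname(p2[, 3:8]), matrix(0, 3, 6))
  expect_error(expression_pcs(tpm[, 1, drop = FALSE]), "two cell types")
})

test_that("cgi_score follows the observed/expected CpG rule", {
  expect_equal(cgi_score(cgi_window_counts(strrep("A", 50))), 0L)
  # L=10, N_CpG=5, N_C=5, N_G=5: 5*10/25 = 2 > 0.6 and GC = 1 > 0.5
  expect_equal(cgi_score(cgi_window_counts("CGCGCGCGCG")), 1L)
  # GC fraction 0.6 but no CpG dinucleotide at all
  expect_equal(cgi_score(cgi_window_counts("CCCAATTGGG")), 0L)
})

test_that("cgi_track agrees with brute-force recounts on random windows", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
  win <- 100L
  tr <- cgi_track(s, window = win)
  half <- win %/% 2
  for (p in sample(seq_len(1500), 60)) {
    lo <- max(1, p - half)
    hi <- min(1500, p + half - 1)
    expect_equal(tr[p],
                 cgi_score(cgi_window_counts(substr(s, lo, hi))),
                 info = paste("pos", p))
  }
})

test_that("assemble_block stacks channels and zero-pads off-chromosome", {
  set.seed(7)
  g <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 800, TRUE),
                         collapse = ""))
  tracks <- list(uniqueness = list(chr1 = runif(800)),
                 accessibility = list(chr1 = runif(800) * 5),
                 conservation = list(chr1 = runif(800)),
                 cgi = list(chr1 = as.numeric(cgi_track(g$chr1))))
  bin <- data.frame(chrom = "chr1", start = 0, end = 200)
  region <- expand_bin(bin, flank = 400, chrom_length = 800)
  blocks <- assemble_block(region, g, tracks)
  expect_equal(dim(blocks$forward), c(1000, 6))
  # padded rows (left 400) all zero across every channel
  expect_equal(sum(abs(blocks$forward[1:400, ])), 0)
  expect_equal(attr(blocks$forward, "strand"), "forward")
  expect_equal(attr(blocks$reverse_complement, "strand"),
               "reverse_complement")
  # extras widen the block
  b8 <- assemble_block(region, g, tracks, extras = c("conservation", "cgi"))
  expect_equal(ncol(b8$forward), 8)
  # RC consistency: assembling the RC'd genome gives the RC block
  mid_bin <- data.frame(chrom = "chr1", start = 300, end = 500)
  mr <- expand_bin(mid_bin, flank = 100, chrom_length = 800)
  bl <- assemble_block(mr, g, tracks)
  expect_equal(unname(reverse_complement_block(bl$forward)),
               unname(bl$reverse_complement))
})
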