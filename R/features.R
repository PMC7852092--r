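# Per-strand sequential feature encoding: one-hot sequence, 35-bp
# uniqueness, accessibility coverage, and the optional conservation / CpG
# island channels, plus the 14-long non-sequential vector (6 annotation
# flags + 8 expression principal components).

#' One-hot encode a DNA sequence
#'
#' @param sequence DNA string over \{A,C,G,T,N\}, case-insensitive.
#' @return An L x 4 matrix with columns `A`, `C`, `G`, `T`; each A/C/G/T
#'   row has exactly one 1, N rows are all zero.
#' @export
one_hot <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  bad <- which(is.na(idx) & chars != "N")
  if (length(bad) > 0) {
    stop(sprintf("invalid base '%s' at position %d", chars[bad[1]], bad[1]))
  }
  m <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Reverse-complement a sequential feature block
#'
#' The four sequence channels are complemented (A<->T, C<->G) and all
#' channels are reversed along the position axis; scalar tracks
#' (uniqueness, accessibility, extras) are reversed only.
#'
#' @param block L x C matrix with the channel layout of [assemble_block()].
#' @return The reverse-complement block, same shape, with the `strand`
#'   attribute flipped.
#' @export
reverse_complement_block <- function(block) {
  out <- block[rev(seq_len(nrow(block))), , drop = FALSE]
  out[, c("A", "C", "G", "T")] <- out[, c("T", "G", "C", "A")]
  colnames(out) <- colnames(block)
  strand <- attr(block, "strand")
  attr(out, "strand") <- if (identical(strand, "reverse_complement")) {
    "forward"
  } else {
    "reverse_complement"
  }
  out
}

kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

#' Per-base sequence uniqueness (mappability) track
#'
#' Scores each position by the genome-wide occurrence count of the k-mer
#' starting there, counted on both strands: unique k-mers score 1, k-mers
#' occurring n = 2..4 times score 1/n, and k-mers occurring more than four
#' times score 0 (the Duke 35-bp convention). The trailing k-1 positions of
#' each chromosome, and k-mers containing N, score 0.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector
#'   of chromosome sequences.
#' @param k K-mer width in bp (default 35).
#' @return Named list of per-base numeric vectors, one per chromosome.
#' @export
uniqueness_track <- function(genome, k = 35L) {
  if (k < 1) stop("k must be >= 1")
  seqs <- if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else {
    genome
  }
  seqs <- vapply(seqs, toupper, character(1))
  rcs <- vapply(seqs, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  all_kmers <- unlist(lapply(c(seqs, rcs), kmers_of, k = k),
                      use.names = FALSE)
  counts <- table(all_kmers)
  lapply(seqs, function(s) {
    n <- nchar(s)
    v <- numeric(n)
    if (n >= k) {
      km <- kmers_of(s, k)
      occ <- as.integer(counts[km])
      score <- ifelse(occ <= 4, 1 / occ, 0)
      score[grepl("[^ACGT]", km)] <- 0
      v[seq_along(score)] <- score
    }
    v
  })
}

#' Normalize a coverage track to 1x genome-wide mean
#'
#' Scales the track by a single constant so that its mean over the
#' effective genome equals 1 (RPGC-style normalization). An all-zero track
#' is returned unchanged.
#'
#' @param track Numeric vector of per-base counts, or a named list of such
#'   vectors (one per chromosome; scaled by one shared constant).
#' @param effective_genome_size Effective genome size in bp.
#' @return Track of the same shape, scaled.
#' @export
normalize_coverage_1x <- function(track, effective_genome_size) {
  if (effective_genome_size <= 0) stop("effective_genome_size must be > 0")
  total <- if (is.list(track)) sum(vapply(track, sum, numeric(1)))
           else sum(track)
  if (total == 0) return(track)
  scale <- effective_genome_size / total
  if (is.list(track)) lapply(track, `*`, scale) else track * scale
}

#' Binary genomic-annotation vector for a bin
#'
#' @param bin One-row bin data.frame.
#' @param annotation_sets Named list of exactly six interval tables
#'   (canonically: coding, intron, promoter, utr5, utr3, cgi).
#' @return Named integer vector of six 0/1 flags; flag i is 1 iff the bin
#'   overlaps at least 1 bp of set i.
#' @export
annotation_vector <- function(bin, annotation_sets) {
  if (length(annotation_sets) != 6) {
    stop("exactly six annotation sets are required, got ",
         length(annotation_sets))
  }
  gr <- as_granges0(bin)
  flags <- vapply(annotation_sets, function(set) {
    s <- as_granges0(set)
    if (length(s) == 0) 0L else as.integer(IRanges::overlapsAny(gr, s))
  }, integer(1))
  flags
}

#' Per-cell-type expression scores from TPM principal components
#'
#' Runs PCA over the cell-type dimension of a TPM matrix (cell types as
#' observations, genes as variables, centered, unscaled) and returns the
#' first `n_components` scores per cell type. Components beyond the rank of
#' the data are exactly 0. Each component's sign is fixed by making its
#' largest-magnitude gene loading positive, so scores are reproducible
#' across platforms. With `standardize = TRUE` (the default) each retained
#' component's scores are scaled to unit variance across cell types, which
#' keeps the expression features on the same numeric scale as the other
#' network inputs.
#'
#' @param tpm_matrix Numeric matrix, genes x cell types, column names are
#'   cell-type identifiers.
#' @param n_components Number of scores per cell type (default 8).
#' @param log_transform Apply log2(TPM + 1) first (default FALSE).
#' @param standardize Scale each component's scores to unit variance.
#' @return Matrix of cell types x `n_components`.
#' @export
expression_pcs <- function(tpm_matrix, n_components = 8L,
                           log_transform = FALSE, standardize = TRUE) {
  if (ncol(tpm_matrix) < 2) {
    stop("at least two cell types are required for expression PCs")
  }
  x <- t(tpm_matrix)
  if (log_transform) x <- log2(x + 1)
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  tol <- max(p$sdev) * 1e-8
  rank <- sum(p$sdev > tol)
  k_avail <- min(rank, n_components)
  out <- matrix(0, nrow = nrow(x), ncol = n_components,
                dimnames = list(rownames(x), paste0("PC", 1:n_components)))
  if (k_avail > 0) {
    scores <- p$x[, seq_len(k_avail), drop = FALSE]
    for (j in seq_len(k_avail)) {
      load <- p$rotation[, j]
      if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
      if (standardize) scores[, j] <- scores[, j] / sd(scores[, j])
    }
    out[, seq_len(k_avail)] <- scores
  }
  out
}

#' Count CpG-island statistics in a window
#'
#' @param sequence DNA string.
#' @return List with `N_CpG` (CpG dinucleotides), `N_C`, `N_G`, `L`.
#' @export
cgi_window_counts <- function(sequence) {
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  list(N_CpG = if (n < 2) 0L else
         sum(chars[-n] == "C" & chars[-1] == "G"),
       N_C = sum(chars == "C"),
       N_G = sum(chars == "G"),
       L = n)
}

#' Binary CpG-island score
#'
#' Scores 1 iff the observed/expected CpG ratio `N_CpG * L / ((N_C+N_G)/2)^2`
#' exceeds 0.6 and the GC fraction `(N_C+N_G)/L` exceeds 0.5.
#'
#' @param counts List from [cgi_window_counts()].
#' @return 0 or 1.
#' @export
cgi_score <- function(counts) {
  gc <- counts$N_C + counts$N_G
  if (counts$L <= 0 || gc == 0) return(0L)
  obs_exp <- counts$N_CpG * counts$L / ((gc / 2)^2)
  as.integer(obs_exp > 0.6 && gc / counts$L > 0.5)
}

#' Per-base CpG-island track for one chromosome
#'
#' Applies the binary CpG-island rule in a sliding window centered on each
#' base (clipped at chromosome ends).
#'
#' @param sequence Chromosome DNA string.
#' @param window Window length in bp (default 200).
#' @return Integer vector of 0/1, one value per base.
#' @export
cgi_track <- function(sequence, window = 200L) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  isC <- cumsum(c(0L, chars == "C"))
  isG <- cumsum(c(0L, chars == "G"))
  cpg <- c(chars[-n] == "C" & chars[-1] == "G", FALSE)
  isCpG <- cumsum(c(0L, cpg))
  half <- window %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half - 1L)
  nC <- isC[hi + 1L] - isC[lo]
  nG <- isG[hi + 1L] - isG[lo]
  # CpG starting positions inside [lo, hi-1]
  nCpG <- isCpG[pmax(hi, 1L)] - isCpG[lo]
  L <- hi - lo + 1L
  gc <- nC + nG
  obs_exp <- ifelse(gc > 0, nCpG * L / ((gc / 2)^2), 0)
  as.integer(obs_exp > 0.6 & gc > 0.5 * L)
}

region_sequence <- function(region, genome) {
  seqs <- if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else {
    genome
  }
  s <- seqs[[region$chrom]]
  core <- substr(s, region$region_start + 1L, region$region_end)
  paste0(strrep("N", region$pad_left), core, strrep("N", region$pad_right))
}

pad_track_slice <- function(v, region) {
  core <- v[(region$region_start + 1L):region$region_end]
  c(numeric(region$pad_left), core, numeric(region$pad_right))
}

#' Assemble the per-strand sequential feature block for an input region
#'
#' Stacks the fixed channel layout A, C, G, T, uniqueness, accessibility
#' (plus optional conservation and CGI channels) over the expanded input
#' region, and returns the forward block together with its
#' reverse-complement twin. Off-chromosome padding yields all-zero rows in
#' every channel.
#'
#' @param region Region list from [expand_bin()].
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param tracks Named list of per-chromosome per-base track lists; must
#'   contain `uniqueness` and `accessibility`, optionally `conservation`
#'   and `cgi`.
#' @param extras Character vector among `c("conservation", "cgi")` naming
#'   the optional channels to include (default none).
#' @return List with elements `forward` and `reverse_complement`, each an
#'   L x C matrix (C = 6 + length(extras)) with a `strand` attribute.
#' @export
assemble_block <- function(region, genome, tracks, extras = character(0)) {
  L <- region$region_end - region$region_start +
    region$pad_left + region$pad_right
  seq_part <- one_hot(region_sequence(region, genome))
  chan <- list(seq_part)
  for (nm in c("uniqueness", "accessibility")) {
    if (is.null(tracks[[nm]])) stop("missing track: ", nm)
    chan[[length(chan) + 1]] <-
      pad_track_slice(tracks[[nm]][[region$chrom]], region)
  }
  for (nm in extras) {
    if (!nm %in% c("conservation", "cgi")) stop("unknown extra channel: ", nm)
    if (is.null(tracks[[nm]])) stop("missing track: ", nm)
    chan[[length(chan) + 1]] <-
      pad_track_slice(tracks[[nm]][[region$chrom]], region)
  }
  block <- do.call(cbind, chan)
  colnames(block) <- c("A", "C", "G", "T", "uniqueness", "accessibility",
                       extras)
  if (nrow(block) != L) stop("track/genome length mismatch for region")
  attr(block, "strand") <- "forward"
  list(forward = block, reverse_complement = reverse_complement_block(block))
}

#' Build the per-bin non-sequential vector function
#'
#' Combines the six binary annotation flags of each bin with a cell type's
#' expression principal-component scores into the length-14 vector fused
#' into the dense layers.
#'
#' @param annotation_sets Named list of six interval tables.
#' @param expression_scores Numeric vector of the cell type's expression
#'   PCs (length 8 at defaults).
#' @return A function `f(bins)` returning an n x (6 + length(scores))
#'   matrix.
#' @export
make_nonseq_builder <- function(annotation_sets, expression_scores) {
  if (length(annotation_sets) != 6) {
    stop("exactly six annotation sets are required")
  }
  set_grs <- lapply(annotation_sets, as_granges0)
  function(bins) {
    gr <- as_granges0(bins)
    flags <- vapply(set_grs, function(s) {
      if (length(s) == 0) integer(nrow(bins))
      else as.integer(IRanges::overlapsAny(gr, s))
    }, integer(nrow(bins)))
    if (nrow(bins) == 1) flags <- matrix(flags, nrow = 1)
    cbind(flags, matrix(rep(expression_scores, nrow(bins)),
                        ncol = length(expression_scores), byrow = TRUE))
  }
}
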