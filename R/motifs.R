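# Motif I/O: JASPAR PFM and MEME-minimal readers, and a PWM builder used
# by the synthetic-data generator. PWMs are 4 x W probability matrices
# with rows A, C, G, T.

#' Build a PWM from a consensus sequence
#'
#' Each column gives the consensus base probability
#' `sharpness + (1 - sharpness) / 4` and the remaining mass uniformly to
#' the other bases, so `sharpness = 1` is a deterministic consensus and
#' `sharpness -> 0` tends to uniform columns.
#'
#' @param consensus DNA string over A/C/G/T.
#' @param sharpness Column concentration in (0, 1].
#' @return 4 x nchar(consensus) probability matrix, rows A, C, G, T.
#' @export
make_pwm <- function(consensus, sharpness = 0.9) {
  if (nchar(consensus) == 0) stop("empty consensus")
  stopifnot(sharpness > 0, sharpness <= 1)
  idx <- match(strsplit(toupper(consensus), "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("consensus must be over A/C/G/T")
  W <- length(idx)
  pwm <- matrix((1 - sharpness) / 4, 4, W,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(idx, seq_len(W))] <- pwm[cbind(idx, seq_len(W))] + sharpness
  pwm
}

#' Sample sequences from a PWM
#'
#' @param pwm 4 x W probability matrix.
#' @param n Number of sequences.
#' @return Character vector of length `n`.
#' @export
sample_pwm <- function(pwm, n = 1L) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(ncol(pwm)), function(j) {
      sample(bases, 1, prob = pwm[, j])
    }, character(1)), collapse = "")
  }, character(1))
}

#' Read motifs in JASPAR PFM format
#'
#' Accepts the `>ID name` header followed by four lines of per-base
#' counts, with or without the `A [ ... ]` bracket decoration. Counts are
#' column-normalized to probabilities.
#'
#' @param path Path to a JASPAR-format file (may hold several motifs).
#' @return Named list of 4 x W probability matrices (rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR header ('>') found in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    name <- trimws(sub("^>", "", lines[i]))
    rows <- lines[(i + 1):(i + 4)]
    parsed <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", trimws(r))
      r <- gsub("[][]", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    mat <- do.call(rbind, parsed)
    rownames(mat) <- c("A", "C", "G", "T")
    out[[name]] <- sweep(mat, 2, colSums(mat), "/")
  }
  out
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#'
#' @param path Path to a MEME-format motif file.
#' @return Named list of 4 x W probability matrices (rows A, C, G, T).
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) stop("no MOTIF blocks found in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]][1]
    mhead <- grep("letter-probability matrix", lines)
    mhead <- mhead[mhead > s][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mhead]))
    rows <- lines[(mhead + 1):(mhead + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4)))
    pwm <- t(mat)
    rownames(pwm) <- c("A", "C", "G", "T")
    out[[name]] <- pwm
  }
  out
}

#' Write motif windows as BED and FASTA
#'
#' @param windows data.frame from [extract_motif_windows()].
#' @param bed_path,fasta_path Output paths (either may be NULL to skip).
#' @export
write_motif_windows <- function(windows, bed_path = NULL,
                                fasta_path = NULL) {
  if (!is.null(bed_path)) {
    gr <- GenomicRanges::GRanges(windows$chrom,
      IRanges::IRanges(windows$start + 1L, windows$end))
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(windows$sequence)
    names(ss) <- sprintf("%s:%d-%d", windows$chrom, windows$start,
                         windows$end)
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(windows)
}
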