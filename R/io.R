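# Format I/O. Peaks, blacklists and annotations are BED/narrowPeak;
# coverage tracks are bedGraph; genomes are FASTA; labels follow the
# challenge TSV layout (chr start stop <cell...> with B/U/A values).

NARROWPEAK_EXTRA <- c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer")

#' Read a BED or narrowPeak interval file
#'
#' @param path Path to a tab-separated BED3+ or ENCODE narrowPeak file.
#' @param format `"auto"` guesses narrowPeak from a 10-column layout.
#' @return A data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   plus `score` and `summit` (absolute bp of the point-source offset)
#'   when present.
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    format <- if (length(first) == 10) "narrowPeak" else "bed"
  }
  gr <- if (format == "narrowPeak") {
    rtracklayer::import(path, format = "BED", extraCols = NARROWPEAK_EXTRA)
  } else {
    rtracklayer::import(path, format = "BED")
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  if ("signalValue" %in% names(md)) out$score <- md$signalValue
  else if ("score" %in% names(md)) out$score <- md$score
  if ("peak" %in% names(md)) out$summit <- out$start + md$peak
  out
}

#' Write intervals as a narrowPeak file
#'
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally
#'   `score` and `summit` columns.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  score <- if ("score" %in% names(peaks)) peaks$score else rep(0, n)
  summit <- if ("summit" %in% names(peaks)) {
    as.integer(peaks$summit - peaks$start)
  } else {
    as.integer((peaks$end - peaks$start) %/% 2)
  }
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   paste0("peak_", seq_len(n)), 0L, ".",
                   score, -1, -1, summit)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

#' Write per-base tracks as a bedGraph file
#'
#' Consecutive equal values are run-length collapsed.
#'
#' @param tracks Named list of per-base numeric vectors, one per chromosome.
#' @param path Output path.
#' @export
write_bedgraph <- function(tracks, path) {
  parts <- lapply(names(tracks), function(chrom) {
    r <- rle(tracks[[chrom]])
    end <- cumsum(r$lengths)
    data.frame(chrom = chrom, start = end - r$lengths, end = end,
               value = r$values, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  df <- df[df$value != 0, , drop = FALSE]  # sparse convention
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               score = df$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Expand an interval track to a per-base vector for one chromosome
#'
#' @param track data.frame from [read_bedgraph()].
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @return Numeric vector of length `chrom_length`; bases not covered by
#'   any interval get 0.
#' @export
track_to_vector <- function(track, chrom, chrom_length) {
  v <- numeric(chrom_length)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    v[(tr$start[i] + 1L):tr$end[i]] <- tr$value[i]
  }
  v
}

#' Read a genome FASTA
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write the challenge-style label TSV
#'
#' One row per bin, one column per cell type, values B/U/A; header is
#' `chr start stop <cell1> <cell2> ...`.
#'
#' @param bins Bin data.frame giving the coordinate grid (`chrom`, `start`,
#'   `end`).
#' @param labels_by_cell Named list of per-bin label vectors, one entry per
#'   cell type, each aligned with `bins`.
#' @param path Output path.
#' @export
write_labels_tsv <- function(bins, labels_by_cell, path) {
  df <- data.frame(chr = bins$chrom, start = bins$start, stop = bins$end,
                   stringsAsFactors = FALSE)
  for (cell in names(labels_by_cell)) df[[cell]] <- labels_by_cell[[cell]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a challenge-style label TSV
#'
#' @param path Path written by [write_labels_tsv()].
#' @return data.frame with `chrom`, `start`, `end` and one B/U/A column per
#'   cell type.
#' @export
read_labels_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df
}

#' Read a TPM expression matrix (genes x cell types)
#'
#' @param path TSV with a header row of cell-type names and gene ids in the
#'   first column.
#' @return Numeric matrix, rows = genes, columns = cell types.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}
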