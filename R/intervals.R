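#' @importFrom stats prcomp cor rnorm runif rexp rbinom sd setNames
#' @importFrom utils head tail read.delim write.table
NULL

# All coordinates in this package are 0-based half-open (BED convention).
# GenomicRanges is 1-based closed; conversion happens only inside the
# overlap helpers below.

#' Convert a 0-based half-open interval table to a GRanges
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), or a `GRanges` (returned as is).
#' @return A `GRanges` object.
#' @keywords internal
as_granges0 <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  bad <- which(x$start >= x$end | x$start < 0)
  if (length(bad) > 0) {
    stop("malformed interval(s) with start >= end or start < 0 at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Tile a chromosome into sliding-window bins
#'
#' Divides a chromosome into fixed-width bins on a sliding grid: bin k
#' covers `[k*step, k*step + bin_size)` for every k such that the bin lies
#' fully on the chromosome. The defaults (200-bp bins, 50-bp step) are the
#' resolution at which binding status is labeled and predicted.
#'
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp (default 200).
#' @param step Sliding step in bp (default 50); must satisfy
#'   `0 < step <= bin_size`.
#' @param chrom Chromosome name attached to each bin.
#' @return A data.frame with columns `chrom`, `start`, `end`, `label`
#'   (initialised to `"unlabeled"`), sorted by `start`. Zero rows when the
#'   chromosome is shorter than one bin.
#' @examples
#' make_bins(1000)            # 17 bins: [0,200), [50,250), ..., [800,1000)
#' @export
make_bins <- function(chrom_length, bin_size = 200L, step = 50L,
                      chrom = "chr1") {
  if (bin_size <= 0 || step <= 0) {
    stop("bin_size and step must be positive")
  }
  if (step > bin_size) stop("step must not exceed bin_size")
  if (chrom_length < bin_size) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  k <- 0:((chrom_length - bin_size) %/% step)
  start <- as.integer(k * step)
  data.frame(chrom = chrom, start = start, end = start + as.integer(bin_size),
             label = "unlabeled", stringsAsFactors = FALSE)
}

#' Label bins as bound / unbound / ambiguous from two peak sets
#'
#' A bin overlapping (by at least `min_overlap` bp) any conservative,
#' IDR-passing peak is bound (`"B"`); a bin overlapping only a relaxed peak
#' is ambiguous (`"A"`); every other bin is unbound (`"U"`). Ambiguous bins
#' are excluded from training and validation downstream.
#'
#' @param bins Bin data.frame from [make_bins()].
#' @param conservative_peaks,relaxed_peaks Interval tables (data.frame with
#'   `chrom`, `start`, `end`, 0-based half-open) or `GRanges`.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return `bins` with the `label` column filled with `"B"`, `"A"` or `"U"`.
#' @export
label_bins <- function(bins, conservative_peaks, relaxed_peaks,
                       min_overlap = 1L) {
  gr <- as_granges0(bins)
  lab <- rep("U", nrow(bins))
  cons <- as_granges0(conservative_peaks)
  relx <- as_granges0(relaxed_peaks)
  if (length(relx) > 0) {
    hit_r <- IRanges::overlapsAny(gr, relx, minoverlap = min_overlap)
    lab[hit_r] <- "A"
  }
  if (length(cons) > 0) {
    hit_c <- IRanges::overlapsAny(gr, cons, minoverlap = min_overlap)
    lab[hit_c] <- "B"
  }
  bins$label <- lab
  bins
}

#' Expand a bin symmetrically into a fixed-length input region
#'
#' Each bin is extended by `flank` bp on both sides to form the model input
#' region (200 + 2*400 = 1000 bp at the defaults). Near chromosome ends the
#' region is clipped and the lost bp recorded as `pad_left` / `pad_right`,
#' so `region_end - region_start + pad_left + pad_right` always equals
#' `bin_size + 2*flank`. Padded positions are filled with N (sequence) and
#' 0 (tracks) at encoding time.
#'
#' @param bin One-row bin data.frame (or list with `chrom`, `start`, `end`).
#' @param flank Flank size in bp (default 400).
#' @param chrom_length Chromosome length in bp, for clipping.
#' @return A list with `chrom`, `bin_start`, `bin_end`, `region_start`,
#'   `region_end`, `pad_left`, `pad_right`.
#' @export
expand_bin <- function(bin, flank = 400L, chrom_length) {
  start <- bin$start[1]
  end <- bin$end[1]
  rs <- start - flank
  re <- end + flank
  pad_left <- max(0L, -rs)
  pad_right <- max(0L, re - as.integer(chrom_length))
  list(chrom = bin$chrom[1],
       bin_start = start, bin_end = end,
       region_start = max(0L, as.integer(rs)),
       region_end = min(as.integer(chrom_length), as.integer(re)),
       pad_left = as.integer(pad_left), pad_right = as.integer(pad_right))
}

#' Remove or zero out bins overlapping blacklisted regions
#'
#' Bins overlapping artifact-prone (blacklisted) regions are excluded from
#' training (`mode = "drop"`); at prediction time they are instead flagged
#' so the predictor emits a score of exactly 0 (`mode = "zero"`).
#'
#' @param bins Bin data.frame.
#' @param blacklist Interval table or `GRanges`; may be empty.
#' @param mode `"drop"` to remove overlapping bins, `"zero"` to flag them.
#' @return For `"drop"`, the filtered bin data.frame. For `"zero"`, `bins`
#'   with an added logical column `force_zero`.
#' @export
apply_blacklist <- function(bins, blacklist, mode = c("drop", "zero")) {
  mode <- match.arg(mode)
  bl <- as_granges0(blacklist)
  if (length(bl) == 0) {
    hit <- rep(FALSE, nrow(bins))
  } else {
    hit <- IRanges::overlapsAny(as_granges0(bins), bl, minoverlap = 1L)
  }
  if (mode == "drop") {
    bins[!hit, , drop = FALSE]
  } else {
    bins$force_zero <- hit
    bins
  }
}
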