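# Seeded synthetic-data generator. Emulates the statistical structure the
# predictor exploits: binding requires a sequence motif AND an accessible
# (open-chromatin) site, cell types differ in which motif sites are
# accessible, and decoy sites violate exactly one of the two conditions.
# Everything every other module consumes is emitted in its standard
# format: FASTA genome, narrowPeak conservative/relaxed peaks, bedGraph
# accessibility and ChIP fold-change per cell type, annotation BEDs, an
# expression TSV, and the challenge-style B/U/A label TSV.

#' Synthetic-experiment configuration
#'
#' Defaults describe the desk-scale study: a 200-kb genome in four equal
#' chromosomes, 20 candidate bound sites (planted motif + accessibility
#' peak), 60 accessible decoys without a motif (open chromatin is mostly
#' unbound by any given factor, so accessible decoys outnumber bound
#' sites), 20 motif decoys without accessibility, and two cell types that
#' each see a random 70% of the candidate sites as accessible (hence
#' bound) -- the cross-cell-type signal. Accessibility peaks are Gaussian bumps (height 8, sd 75 bp)
#' over a 0.25 baseline; ChIP fold-change bumps are height 10, sd 75 bp
#' over a baseline of 1.
#'
#' @param genome_length Total genome length in bp.
#' @param n_chroms Number of equal-length chromosomes.
#' @param gc_content Background GC fraction.
#' @param motif_consensus,motif_sharpness PWM consensus and concentration
#'   (see [make_pwm()]).
#' @param n_bound_sites Candidate bound sites (motif + accessibility).
#' @param n_decoy_accessible Accessible decoys without a motif.
#' @param n_decoy_motif Motif decoys without accessibility.
#' @param n_cell_types Number of cell types.
#' @param cell_bound_fraction Fraction of candidate sites accessible
#'   (= bound) in each cell type.
#' @param access_height,access_sd Accessibility peak shape.
#' @param access_baseline Accessibility baseline level.
#' @param fold_height,fold_sd,fold_baseline Fold-change peak shape.
#' @param peak_width Width of the called ChIP peaks around each bound
#'   motif, bp.
#' @param ambiguous_fraction Relaxed-only peaks (sources of A labels) as a
#'   fraction of `n_bound_sites`, placed on accessible decoys.
#' @param label_noise Probability of flipping a bin's B/U label.
#' @param min_separation Minimum distance between planted sites, bp.
#' @param n_genes Genes in the synthetic expression matrix.
#' @param seed Mandatory integer seed.
#' @return A list of class `"attnbind_simconfig"`.
#' @export
simulation_config <- function(genome_length = 200000L, n_chroms = 4L,
                              gc_content = 0.41,
                              motif_consensus = "TGACGTCATGCA",
                              motif_sharpness = 0.9,
                              n_bound_sites = 20L,
                              n_decoy_accessible = 60L,
                              n_decoy_motif = 20L,
                              n_cell_types = 2L,
                              cell_bound_fraction = 0.7,
                              access_height = 8, access_sd = 75,
                              access_baseline = 0.25,
                              fold_height = 10, fold_sd = 75,
                              fold_baseline = 1,
                              peak_width = 150L,
                              ambiguous_fraction = 0.15,
                              label_noise = 0,
                              min_separation = 1200L,
                              n_genes = 100L,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  cfg$chrom_length <- as.integer(genome_length %/% n_chroms)
  cfg$chrom_names <- paste0("chrS", seq_len(n_chroms))
  cfg$cell_names <- paste0("cell", LETTERS[seq_len(n_cell_types)])
  class(cfg) <- "attnbind_simconfig"
  cfg
}

random_genome <- function(cfg) {
  p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
         G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  setNames(lapply(cfg$chrom_names, function(ch) {
    paste(sample(names(p), cfg$chrom_length, replace = TRUE, prob = p),
          collapse = "")
  }), cfg$chrom_names)
}

# Uniform positions with a minimum pairwise separation on one chromosome
# (gap method: order statistics in the shrunken interval, gaps re-inflated).
place_positions <- function(n, cfg) {
  margin <- 1000L
  usable <- cfg$chrom_length - 2L * margin - (n - 1L) * cfg$min_separation
  if (usable <= 0) stop("site placement infeasible; genome too small")
  u <- sort(floor(runif(n) * usable))
  as.integer(margin + u + (seq_len(n) - 1L) * cfg$min_separation)
}

# Sites are dealt to chromosomes round-robin per kind, so every chromosome
# carries a comparable mix of bound sites and both decoy kinds -- a
# balanced design that keeps any chromosome usable as a held-out split.
place_sites <- function(cfg) {
  kind_seq <- rep(c("bound", "decoy_accessible", "decoy_motif"),
                  c(cfg$n_bound_sites, cfg$n_decoy_accessible,
                    cfg$n_decoy_motif))
  chrom_assign <- rep_len(cfg$chrom_names, length(kind_seq))
  parts <- lapply(cfg$chrom_names, function(ch) {
    k_ch <- sample(kind_seq[chrom_assign == ch])
    data.frame(chrom = ch, pos = place_positions(length(k_ch), cfg),
               kind = k_ch, stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

gaussian_bump <- function(track, center, height, sd) {
  lo <- max(1L, as.integer(center - 4 * sd))
  hi <- min(length(track), as.integer(center + 4 * sd))
  x <- lo:hi
  track[x] <- track[x] + height * exp(-(x - center)^2 / (2 * sd^2))
  track
}

#' Generate a complete synthetic binding experiment
#'
#' Plants motif instances in a random genome, lays accessibility and
#' ChIP fold-change bumps, derives conservative/relaxed peak calls and the
#' per-cell B/U/A label grid through [label_bins()], simulates a
#' cell-structured expression matrix, and writes every artifact to
#' standard-format files. Byte-identical output for identical seeds.
#'
#' @param cfg Configuration from [simulation_config()].
#' @param dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @return Invisibly, a `"synthetic_truth"` list: the genome, planted
#'   site tables (`bound_sites` with per-cell accessibility columns,
#'   `decoy_accessible`, `decoy_motif`), per-cell accessibility and
#'   fold-change tracks, per-cell peak tables, the labeled bin grid
#'   (`bins`, `labels_by_cell`), the expression matrix, annotation sets,
#'   and the file `manifest`.
#' @export
simulate_binding_data <- function(cfg, dir = NULL) {
  with_seed(cfg$seed, {
    pwm <- make_pwm(cfg$motif_consensus, cfg$motif_sharpness)
    W <- ncol(pwm)
    genome <- random_genome(cfg)

    n_amb <- round(cfg$ambiguous_fraction * cfg$n_bound_sites)
    sites <- place_sites(cfg)

    # plant motif instances at bound and motif-decoy sites
    for (i in which(sites$kind != "decoy_accessible")) {
      inst <- sample_pwm(pwm, 1)
      s <- genome[[sites$chrom[i]]]
      substr(s, sites$pos[i] + 1L, sites$pos[i] + W) <- inst
      genome[[sites$chrom[i]]] <- s
    }

    bound <- sites[sites$kind == "bound", , drop = FALSE]
    dec_acc <- sites[sites$kind == "decoy_accessible", , drop = FALSE]
    dec_mot <- sites[sites$kind == "decoy_motif", , drop = FALSE]

    # per-cell accessible subsets of the candidate bound sites; every
    # site is accessible in at least one cell type
    n_per_cell <- max(1L, round(cfg$cell_bound_fraction *
                                  nrow(bound)))
    repeat {
      member <- vapply(cfg$cell_names, function(cell) {
        seq_len(nrow(bound)) %in% sample.int(nrow(bound), n_per_cell)
      }, logical(nrow(bound)))
      if (all(rowSums(member) > 0)) break
    }
    colnames(member) <- cfg$cell_names
    for (cell in cfg$cell_names) bound[[cell]] <- member[, cell]

    half_peak <- cfg$peak_width %/% 2L
    center <- bound$pos + W %/% 2L
    access <- list(); fold <- list()
    cons_peaks <- list(); relax_peaks <- list()
    amb_idx <- if (n_amb > 0 && nrow(dec_acc) > 0) {
      sample.int(nrow(dec_acc), min(n_amb, nrow(dec_acc)))
    } else integer(0)
    for (cell in cfg$cell_names) {
      acc <- setNames(lapply(cfg$chrom_names, function(ch) {
        rep(cfg$access_baseline, cfg$chrom_length)
      }), cfg$chrom_names)
      fc <- setNames(lapply(cfg$chrom_names, function(ch) {
        rep(cfg$fold_baseline, cfg$chrom_length)
      }), cfg$chrom_names)
      for (i in which(bound[[cell]])) {
        acc[[bound$chrom[i]]] <- gaussian_bump(acc[[bound$chrom[i]]],
          center[i], cfg$access_height, cfg$access_sd)
        fc[[bound$chrom[i]]] <- gaussian_bump(fc[[bound$chrom[i]]],
          center[i], cfg$fold_height, cfg$fold_sd)
      }
      for (i in seq_len(nrow(dec_acc))) {
        acc[[dec_acc$chrom[i]]] <- gaussian_bump(acc[[dec_acc$chrom[i]]],
          dec_acc$pos[i] + W %/% 2L, cfg$access_height, cfg$access_sd)
      }
      access[[cell]] <- acc
      fold[[cell]] <- fc
      sel <- which(bound[[cell]])
      cons <- data.frame(chrom = bound$chrom[sel],
                         start = pmax(0L, center[sel] - half_peak),
                         end = pmin(cfg$chrom_length,
                                    center[sel] + half_peak),
                         score = cfg$fold_height,
                         summit = center[sel],
                         stringsAsFactors = FALSE)
      relax_extra <- if (length(amb_idx) > 0) {
        dc <- dec_acc$pos[amb_idx] + W %/% 2L
        data.frame(chrom = dec_acc$chrom[amb_idx],
                   start = pmax(0L, dc - half_peak),
                   end = pmin(cfg$chrom_length, dc + half_peak),
                   score = cfg$fold_height / 4,
                   summit = dc, stringsAsFactors = FALSE)
      } else cons[0, , drop = FALSE]
      cons_peaks[[cell]] <- cons
      relax_peaks[[cell]] <- rbind(cons, relax_extra)
    }

    # B/U/A labels on the sliding-bin grid
    bins <- do.call(rbind, lapply(cfg$chrom_names, function(ch) {
      make_bins(cfg$chrom_length, chrom = ch)
    }))
    labels_by_cell <- lapply(setNames(cfg$cell_names, cfg$cell_names),
      function(cell) {
        lab <- label_bins(bins, cons_peaks[[cell]],
                          relax_peaks[[cell]])$label
        if (cfg$label_noise > 0) {
          flip <- runif(length(lab)) < cfg$label_noise & lab != "A"
          lab[flip] <- ifelse(lab[flip] == "B", "U", "B")
        }
        lab
      })

    # expression matrix with cell-type structure
    base_expr <- rexp(cfg$n_genes, rate = 1 / 50)
    expr <- vapply(cfg$cell_names, function(cell) {
      pmax(0, base_expr * exp(rnorm(cfg$n_genes, sd = 0.5)))
    }, numeric(cfg$n_genes))
    rownames(expr) <- paste0("gene", seq_len(cfg$n_genes))
    expr <- sweep(expr, 2, colSums(expr), "/") * 1e6  # TPM scale

    # six uninformative annotation interval sets
    annotation_sets <- lapply(setNames(nm = c("coding", "intron",
        "promoter", "utr5", "utr3", "cgi")), function(nm) {
      n <- 25L
      chrom <- sample(cfg$chrom_names, n, replace = TRUE)
      start <- floor(runif(n) * (cfg$chrom_length - 2000L))
      data.frame(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + 500L + floor(runif(n) * 1500L)),
                 stringsAsFactors = FALSE)
    })

    manifest <- list(seed = cfg$seed, files = character(0),
                     config_hash = sum(utf8ToInt(paste(
                       deparse(unclass(cfg)), collapse = ""))))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fp <- function(...) file.path(dir, paste0(...))
      ss <- Biostrings::DNAStringSet(unlist(genome))
      Biostrings::writeXStringSet(ss, fp("genome.fa"))
      files <- c(genome = fp("genome.fa"))
      for (cell in cfg$cell_names) {
        write_bedgraph(access[[cell]], fp(cell, ".accessibility.bedGraph"))
        write_bedgraph(fold[[cell]], fp(cell, ".fold_change.bedGraph"))
        write_narrowpeak(cons_peaks[[cell]],
                         fp(cell, ".conservative.narrowPeak"))
        write_narrowpeak(relax_peaks[[cell]], fp(cell, ".relaxed.narrowPeak"))
        files <- c(files, fp(cell, ".accessibility.bedGraph"),
                   fp(cell, ".fold_change.bedGraph"),
                   fp(cell, ".conservative.narrowPeak"),
                   fp(cell, ".relaxed.narrowPeak"))
      }
      write_labels_tsv(bins, labels_by_cell, fp("labels.tsv"))
      write.table(data.frame(gene = rownames(expr), expr,
                             check.names = FALSE),
                  fp("expression.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      for (nm in names(annotation_sets)) {
        a <- annotation_sets[[nm]]
        gr <- GenomicRanges::GRanges(a$chrom,
          IRanges::IRanges(a$start + 1L, a$end))
        rtracklayer::export(gr, fp("annotation_", nm, ".bed"),
                            format = "BED")
        files <- c(files, fp("annotation_", nm, ".bed"))
      }
      files <- c(files, fp("labels.tsv"), fp("expression.tsv"))
      manifest$files <- basename(unname(files))
      jsonlite::write_json(manifest, fp("manifest.json"),
                           auto_unbox = TRUE)
    }

    truth <- list(config = cfg, genome = genome, pwm = pwm,
                  motif_width = W,
                  bound_sites = bound, decoy_accessible = dec_acc,
                  decoy_motif = dec_mot,
                  access = access, fold = fold,
                  cons_peaks = cons_peaks, relax_peaks = relax_peaks,
                  bins = bins, labels_by_cell = labels_by_cell,
                  expression = expr, annotation_sets = annotation_sets,
                  manifest = manifest)
    class(truth) <- "synthetic_truth"
    invisible(truth)
  })
}
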