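# The desk-scale study fixture: one seeded synthetic experiment shared by
# the training-recovery and interpretation tests, with trained models
# memoised so several test blocks can reuse them.

.study <- new.env(parent = emptyenv())

# the study conditions: 200-kb genome, 20 bound sites, fixed seed
study_truth <- function() {
  if (is.null(.study$truth)) {
    cfg <- simulation_config(seed = 1)
    .study$truth <- simulate_binding_data(cfg)
    .study$uniq <- uniqueness_track(.study$truth$genome)
    .study$pcs <- expression_pcs(.study$truth$expression)
  }
  list(truth = .study$truth, uniq = .study$uniq, pcs = .study$pcs)
}

# the small desk-scale network/training configuration (see the methods
# vignette for the rationale behind each value)
study_config <- function(seed) {
  model_config(conv_filters = 64L, conv_kernel = 12L, pool_size = 10L,
               lstm_units = 8L, d_k = 8L, d_v = 8L, dense_units = 8L,
               dropout = 0.3, learning_rate = 2e-3, epochs = 20L,
               patience = 5L, batch_size = 8L, negative_ratio = 10,
               seed = seed)
}

study_chroms <- list(train = c("chrS1", "chrS2"), val = "chrS3",
                     test = "chrS4")

# train on cellA (train chromosomes, chrS3 validation) with the given
# weight seed; memoised
study_model <- function(seed) {
  key <- paste0("model_", seed)
  if (is.null(.study[[key]])) {
    s <- study_truth()
    labels <- s$truth$bins
    labels$label <- s$truth$labels_by_cell$cellA
    tracks <- list(uniqueness = s$uniq,
                   accessibility = s$truth$access$cellA)
    nonseq <- make_nonseq_builder(s$truth$annotation_sets,
                                  s$pcs["cellA", ])
    m <- build_model(study_config(seed))
    .study[[key]] <- fit_model(m, labels, s$truth$genome, tracks, nonseq,
                               train_chroms = study_chroms$train,
                               val_chrom = study_chroms$val)
  }
  .study[[key]]
}

# held-out evaluation: cellB on the held-out chromosome; memoised
study_heldout <- function(seed) {
  key <- paste0("eval_", seed)
  if (is.null(.study[[key]])) {
    s <- study_truth()
    m <- study_model(seed)
    test <- s$truth$bins
    test$label <- s$truth$labels_by_cell$cellB
    test <- test[test$chrom == study_chroms$test & test$label != "A", ]
    tracks <- list(uniqueness = s$uniq,
                   accessibility = s$truth$access$cellB)
    enc <- encode_bins(test, s$truth$genome, tracks, m$config)
    ns <- make_nonseq_builder(s$truth$annotation_sets,
                              s$pcs["cellB", ])(test)
    pred <- predict_scores(m, enc$X_fwd, enc$X_rc, ns, batch_size = 128L)
    .study[[key]] <- list(bins = test, pred = pred,
                          y = as.integer(test$label == "B"))
  }
  .study[[key]]
}

# accessibility-only logistic baseline: bin mean and max coverage,
# trained on the cellA training bins, applied to the held-out set
study_dnase_baseline <- function() {
  if (is.null(.study$baseline)) {
    s <- study_truth()
    binfeat <- function(b, acc) {
      t(vapply(seq_len(nrow(b)), function(i) {
        v <- acc[[b$chrom[i]]][(b$start[i] + 1):b$end[i]]
        c(mean(v), max(v))
      }, numeric(2)))
    }
    labels <- s$truth$bins
    labels$label <- s$truth$labels_by_cell$cellA
    trb <- labels[labels$chrom %in% study_chroms$train &
                    labels$label != "A", ]
    Xtr <- binfeat(trb, s$truth$access$cellA)
    fit <- suppressWarnings(stats::glm.fit(
      cbind(1, Xtr), as.integer(trb$label == "B"),
      family = stats::binomial()))
    ev <- study_heldout(1)
    Xte <- binfeat(ev$bins, s$truth$access$cellB)
    .study$baseline <- as.vector(
      stats::plogis(cbind(1, Xte) %*% fit$coefficients))
  }
  .study$baseline
}
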