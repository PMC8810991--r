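# Shared desk-scale configurations.  Architectures and epoch counts are
# scaled down from the package defaults so the whole suite trains
# hundreds of small networks in minutes; the vignette discusses the
# choice of problem sizes.

tiny_base_spec <- function(...) {
  base_classifier_spec(hidden = c(16, 16), epochs = 25, learning_rate = 3e-3,
                       weight_decay = 2e-3, optimizer = "adam", ...)
}

std_base_spec <- function(...) {
  base_classifier_spec(hidden = c(32, 32), epochs = 10, learning_rate = 1e-3,
                       weight_decay = 2e-3, optimizer = "adam", ...)
}

tiny_defer_spec <- function(alpha = 1, seed = 1, ...) {
  defer_model_spec(hidden = c(32, 32), alpha = alpha, epochs = 15,
                   learning_rate = 1e-3, optimizer = "adam", seed = seed, ...)
}

std_defer_spec <- function(alpha = 1, seed = 1, ...) {
  defer_model_spec(alpha = alpha, epochs = 60, learning_rate = 1e-3,
                   optimizer = "adam", seed = seed, ...)
}

# mixed-difficulty cohort: 60% separable, 30% irreducibly ambiguous,
# 10% confidently mislabelled relative to their features
mixed_cohort <- function(n_per_class = 300, seed = 1) {
  simulate_cohort(n_per_class = n_per_class, class_separation = 10,
                  easy_fraction = 0.6, ambiguous_fraction = 0.3,
                  overconfident_wrong_fraction = 0.1, seed = seed)
}

# zero-diagnostic-entropy regime: no ambiguous region, so member votes
# are (near-)unanimous everywhere and entropy thresholding has nothing
# to act on
ocw_cohort <- function(n_per_class = 300, seed = 1) {
  simulate_cohort(n_per_class = n_per_class, class_separation = 10,
                  easy_fraction = 0.9, ambiguous_fraction = 0,
                  overconfident_wrong_fraction = 0.1, seed = seed)
}

# independent brute-force confusion-matrix oracle used by metric tests
oracle_metrics <- function(decisions, labels) {
  stopifnot(length(decisions) == length(labels))
  kept <- decisions != "defer"
  cm <- function(truth, pred) {
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
      if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
      if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
      if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
    }
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    list(tp = tp, tn = tn, fp = fp, fn = fn, f1 = f1,
         acc = if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else NA_real_,
         sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }
  on_kept <- cm(labels[kept], as.integer(decisions[kept]))
  pred_all <- ifelse(kept, suppressWarnings(as.integer(decisions)), labels)
  overall <- cm(labels, pred_all)
  list(defer_rate = mean(!kept), kept = on_kept, f1_overall = overall$f1)
}
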