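# The coverage-accuracy sweep protocol.
#
# One model per control value (no warm starting across the grid): the
# alpha grid for LDU and LD, the entropy-threshold grid for DT.  Every
# grid point is reported, including degenerate ones (defer rate 0 or 1),
# with flags, so sweep outputs are rectangular.

#' Sweep the control parameter of a deferral algorithm
#'
#' Runs the full two-stage pipeline per seed and evaluates every grid
#' point on the test split, producing one tidy record per
#' `(algorithm, control value, seed)`:
#'
#' * `"ldu"` -- trains a deep ensemble per seed, builds stage-two
#'   features for both splits, then trains one defer network per
#'   `alpha` in `grid` (the stage-two seed equals the sweep seed and is
#'   shared across the grid, so the sweep isolates the effect of
#'   `alpha`).
#' * `"ld"`  -- trains one widened end-to-end network per `alpha`.
#' * `"dt"`  -- trains the ensemble once per seed and thresholds its
#'   entropy at each value in `grid`.
#'
#' Each record also carries `diagnostic_f1`, the F1 of the no-defer
#' diagnostic predictor on the same test split (the ensemble majority
#' vote for `"ldu"`/`"dt"`; a single cross-entropy-trained network for
#' `"ld"`), the dashed reference line of the standard displays.
#'
#' @param train,test Feature tables from [split_cohort()].
#' @param algorithm `"ldu"`, `"ld"` or `"dt"`.
#' @param grid Numeric vector of `alpha` values (`"ldu"`/`"ld"`) or
#'   entropy thresholds in nats (`"dt"`).
#' @param seeds Integer vector; the whole pipeline is repeated per seed.
#' @param k Ensemble size for `"ldu"`/`"dt"`.
#' @param base_spec A [base_classifier_spec()] for stage one / LD.
#' @param defer_spec A [defer_model_spec()]; its `alpha` is overridden
#'   by the grid.
#' @param entropy Entropy kind for `"dt"`.
#' @param cross_fit For `"ldu"`: build the stage-two *training* features
#'   by cross-fitting ([stage2_features_crossfit()]) instead of scoring
#'   the training rows with the ensemble that was fitted on them.  The
#'   default `FALSE` is the single-split procedure; cross-fitting
#'   removes the optimistic-confidence shift between the defer network's
#'   training and prediction inputs, which matters at small sample
#'   sizes.
#' @param folds Cross-fitting folds (used when `cross_fit = TRUE`).
#' @return A `defer_sweep` tibble: `algorithm`, `param_name`,
#'   `param_value`, `seed`, the [compute_metrics()] columns and
#'   `diagnostic_f1`.
#' @examples
#' \donttest{
#' parts <- split_cohort(simulate_cohort(n_per_class = 150, seed = 1))
#' sw <- sweep_defer(parts$train, parts$test, "ldu", grid = c(0.5, 1, 2),
#'                   seeds = 1, k = 3,
#'                   base_spec = base_classifier_spec(hidden = c(16, 16), epochs = 10),
#'                   defer_spec = defer_model_spec(hidden = c(32, 32), epochs = 10))
#' sw
#' }
#' @export
sweep_defer <- function(train, test, algorithm = c("ldu", "ld", "dt"),
                        grid, seeds = 1L, k = 10L,
                        base_spec = base_classifier_spec(),
                        defer_spec = defer_model_spec(),
                        entropy = c("diagnostic", "ensemble"),
                        cross_fit = FALSE, folds = 5L) {
  algorithm <- match.arg(algorithm)
  entropy <- match.arg(entropy)
  if (length(grid) == 0L) stop("`grid` must be non-empty.", call. = FALSE)
  labels <- as.integer(test$label)

  out <- purrr::map_dfr(as.integer(seeds), function(s) {
    if (algorithm %in% c("ldu", "dt")) {
      ens <- train_ensemble(train, base_spec, k = k, master_seed = s)
      pr_test <- predict(ens, test)
      diag_f1 <- f1_positive(labels, majority_diagnosis(pr_test))
      if (algorithm == "ldu") {
        s2_train <- if (cross_fit) {
          stage2_features_crossfit(train, base_spec, k = k, master_seed = s,
                                   folds = folds)
        } else {
          build_stage2_features(predict(ens, train))
        }
        s2_test <- build_stage2_features(pr_test)
      }
    } else {
      diag_net <- train_diagnostic_network(train, base_spec, seed = s)
      diag_f1 <- f1_positive(labels, predict(diag_net, test)$pred)
    }
    purrr::map_dfr(grid, function(g) {
      tri <- switch(
        algorithm,
        ldu = {
          sp <- defer_spec; sp$alpha <- g; sp$seed <- s
          triage(train_defer_network(s2_train, sp), s2_test)
        },
        ld = triage(train_ld(train, base_spec, alpha = g, seed = s,
                             alpha_on = defer_spec$alpha_on), test),
        dt = triage_dt(pr_test, threshold = g, entropy = entropy)
      )
      dplyr::bind_cols(
        tibble::tibble(algorithm = algorithm,
                       param_name = if (algorithm == "dt") "threshold" else "alpha",
                       param_value = g, seed = s),
        compute_metrics(tri, labels),
        tibble::tibble(diagnostic_f1 = diag_f1)
      )
    })
  })
  class(out) <- c("defer_sweep", class(out))
  out
}
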