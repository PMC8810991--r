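# Entropy-based epistemic uncertainty from ensemble probabilities.
#
# Two measures, both in nats (natural log):
#   ensemble entropy   u_e = -sum_k p_k log p_k over the K member
#                      positive-class probabilities (a sum of
#                      per-member terms, NOT a normalised entropy: the
#                      p_k do not form a distribution over k);
#   diagnostic entropy u_d = entropy of the ensemble's class-vote
#                      fractions, zero exactly when the members vote
#                      unanimously.

xlogx <- function(p) {
  out <- p * log(p)
  out[p == 0] <- 0
  out
}

check_prob_input <- function(probs) {
  p <- if (is.vector(probs) && is.numeric(probs)) {
    matrix(probs, nrow = 1L)
  } else {
    m <- as.matrix(probs)
    storage.mode(m) <- "double"
    m
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("member probabilities must be finite and in [0, 1].", call. = FALSE)
  }
  p
}

#' Ensemble entropy of member probabilities
#'
#' `-sum_k p_k log(p_k)` over the K member positive-class probabilities
#' of each patient, with the convention `0 * log(0) = 0`.  Low values
#' mean every member is individually confident (probabilities near 0 or
#' 1); the measure says nothing about whether the members *agree* -- see
#' [diagnostic_entropy()] for that.  For a per-member average of the
#' full binary entropy use [mean_binary_entropy()].
#'
#' @param probs Numeric vector of one patient's K member probabilities,
#'   or a matrix / ensemble-output tibble with one row per patient.
#' @return Entropy in nats; one value per patient.
#' @examples
#' ensemble_entropy(c(1, 1, 1))       # 0
#' ensemble_entropy(c(0.5, 0.5, 0.5)) # 1.0397
#' @export
ensemble_entropy <- function(probs) {
  p <- check_prob_input(probs)
  unname(-rowSums(xlogx(p)))
}

#' @rdname ensemble_entropy
#' @details `mean_binary_entropy()` computes
#'   `(1/K) sum_k [-p_k log p_k - (1-p_k) log(1-p_k)]`, the mean proper
#'   binary entropy of the members; it is provided as a documented
#'   variant and is not used by default anywhere in the package.
#' @export
mean_binary_entropy <- function(probs) {
  p <- check_prob_input(probs)
  unname(-rowMeans(xlogx(p) + xlogx(1 - p)))
}

#' Diagnostic entropy of ensemble class votes
#'
#' Each member votes class 1 when its probability is at least 0.5 (the
#' same convention as [majority_diagnosis()]); with vote fractions
#' `P_0`, `P_1` the diagnostic entropy is `-sum_c P_c log(P_c)`.  It is
#' 0 exactly when the votes are unanimous and reaches its maximum
#' `log(2)` when the votes split evenly, i.e. it measures *disagreement*
#' between members regardless of how confident each one is.
#'
#' @inheritParams ensemble_entropy
#' @return Entropy in nats, in `[0, log(2)]`; one value per patient.
#' @examples
#' diagnostic_entropy(c(0.9, 0.8, 0.99)) # 0: unanimous
#' diagnostic_entropy(c(0.9, 0.1))       # log(2): split votes
#' @export
diagnostic_entropy <- function(probs) {
  p <- check_prob_input(probs)
  f1 <- rowMeans(p >= 0.5)
  unname(-(xlogx(f1) + xlogx(1 - f1)))
}

#' Per-patient uncertainty summary of an ensemble output
#'
#' @param predictions Ensemble output tibble with `p_*` columns.
#' @return The input with columns `u_e` (ensemble entropy), `u_d`
#'   (diagnostic entropy) and `p_vote_pos` (fraction of members voting
#'   positive) appended.
#' @export
add_uncertainty <- function(predictions) {
  p <- prob_matrix(predictions)
  dplyr::mutate(
    tibble::as_tibble(predictions),
    u_e = ensemble_entropy(p),
    u_d = diagnostic_entropy(p),
    p_vote_pos = rowMeans(p >= 0.5)
  )
}

#' Stage-two input features
#'
#' Assembles the defer network's input: the K member probabilities in
#' member order followed by the ensemble entropy `u_e` and the
#' diagnostic entropy `u_d`, for K + 2 predictors per patient.
#' `sample_id` and, when present, `label`/`subgroup` are carried along
#' for bookkeeping but are never part of the model input.
#'
#' @param predictions Ensemble output tibble with `p_*` columns.
#' @return A tibble with `sample_id`, `p_0 .. p_{K-1}`, `u_e`, `u_d`
#'   (+ optional `label`, `subgroup`).
#' @examples
#' pr <- tibble::tibble(sample_id = "a", p_0 = 0.5, p_1 = 0.5, p_2 = 0.5)
#' build_stage2_features(pr)
#' @export
build_stage2_features <- function(predictions) {
  p <- prob_matrix(predictions)
  k <- ncol(p)
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(predictions)) {
      as.character(predictions$sample_id)
    } else {
      sprintf("s%05d", seq_len(nrow(p)))
    },
    tibble::as_tibble(p),
    u_e = ensemble_entropy(p),
    u_d = diagnostic_entropy(p)
  )
  if ("label" %in% names(predictions)) out$label <- as.integer(predictions$label)
  if ("subgroup" %in% names(predictions)) out$subgroup <- predictions$subgroup
  out
}

#' Cross-fitted stage-two features for the training split
#'
#' In-sample ensemble probabilities are optimistically confident: the
#' members have seen the very rows being scored, so the defer network
#' would be trained on uncertainty profiles systematically sharper than
#' anything it meets at prediction time.  This helper removes that shift
#' by K-fold cross-fitting: the rows of each fold are scored by an
#' ensemble trained on the remaining folds only (same spec, same member
#' seeds), so every training row carries out-of-sample uncertainty.
#'
#' @param train Feature table with `f*` columns and a 0/1 `label`.
#' @param base_spec A [base_classifier_spec()] shared by all fold
#'   ensembles.
#' @param k Ensemble size.
#' @param master_seed Seed from which all fold-member seeds derive.
#' @param folds Number of cross-fitting folds.
#' @return A stage-two feature tibble (see [build_stage2_features()])
#'   with rows in the order of `train`.
#' @export
stage2_features_crossfit <- function(train, base_spec = base_classifier_spec(),
                                     k = 50L, master_seed = 1L, folds = 5L) {
  stopifnot(folds >= 2L, nrow(train) >= folds)
  fold <- rep_len(seq_len(folds), nrow(train))
  parts <- purrr::map(seq_len(folds), function(f) {
    ens_f <- train_ensemble(train[fold != f, , drop = FALSE], base_spec,
                            k = k, master_seed = master_seed)
    build_stage2_features(predict(ens_f, train[fold == f, , drop = FALSE]))
  })
  out <- dplyr::bind_rows(parts)
  out[order(unlist(split(seq_len(nrow(train)), fold), use.names = FALSE)), ,
      drop = FALSE]
}

# numeric matrix of stage-two predictors in documented column order
stage2_matrix <- function(features) {
  p <- prob_matrix(features)
  if (!all(c("u_e", "u_d") %in% names(features))) {
    stop("stage-two features need `u_e` and `u_d` columns; ",
         "see build_stage2_features().", call. = FALSE)
  }
  cbind(p, u_e = features$u_e, u_d = features$u_d)
}
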