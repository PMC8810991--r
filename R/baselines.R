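# Comparison algorithms.
#
# LD: learning to defer WITHOUT uncertainty information -- the ordinary
#     diagnostic network with its output widened by one (0, 1, defer),
#     trained end-to-end on raw features with the same defer loss as the
#     stage-two network (one shared implementation).
# DT: direct triage by uncertainty -- defer every patient whose
#     diagnostic (or ensemble) entropy exceeds a threshold; classify the
#     rest by ensemble majority vote.

#' Train the LD baseline (learning to defer without uncertainty)
#'
#' @param train Feature table with `f*` columns and a 0/1 `label`.
#' @param spec A [base_classifier_spec()]; LD reuses the diagnostic
#'   network's architecture and optimisation settings.
#' @param alpha Positive defer-loss weight, same semantics as in
#'   [defer_model_spec()].
#' @param seed Integer initialisation seed.
#' @param alpha_on Which loss term carries `alpha`; see [defer_loss()].
#' @return An `ld_model`; pass it to [triage()] with a raw feature
#'   table.
#' @export
train_ld <- function(train, spec = base_classifier_spec(), alpha = 1,
                     seed = 1L, alpha_on = c("target", "defer")) {
  stopifnot(inherits(spec, "base_classifier_spec"))
  alpha_on <- match.arg(alpha_on)
  x <- feature_matrix(train)
  check_two_classes(train$label)
  net <- train_base_net(x, train$label, spec, seed = seed, n_out = 3L,
                        loss = "defer", alpha = alpha, alpha_on = alpha_on)
  structure(list(net = net, spec = spec, alpha = alpha, alpha_on = alpha_on,
                 n_features = ncol(x)),
            class = "ld_model")
}

#' @rdname triage
#' @export
triage.ld_model <- function(model, data, ...) {
  x <- feature_matrix(data)
  p <- mlp_prob(model$net, x)
  triage_tibble(
    if ("sample_id" %in% names(data)) data$sample_id
    else sprintf("s%05d", seq_len(nrow(x))),
    p, "ld", "alpha", model$alpha, carry = data
  )
}

#' Direct triage by an entropy threshold (DT)
#'
#' Defers every patient whose entropy strictly exceeds `threshold`;
#' non-deferred patients are diagnosed by [majority_diagnosis()].  With
#' `threshold = 0` the deferred set is exactly the patients with nonzero
#' entropy, which is DT's ceiling: patients on whom the members vote
#' unanimously (diagnostic entropy 0) can never be deferred, however
#' wrong the unanimous vote is.
#'
#' @param predictions Ensemble output tibble with `p_*` columns.
#' @param threshold Entropy threshold in nats (>= 0).
#' @param entropy `"diagnostic"` (default, the better-performing choice)
#'   or `"ensemble"`.
#' @return A triage tibble (see [triage()]); for DT the score columns
#'   hold the vote fractions and `score_defer` is `NA`.
#' @examples
#' pr <- tibble::tibble(p_0 = c(1, 0.9, 0.2), p_1 = c(1, 0.4, 0.9))
#' triage_dt(pr, threshold = 0)
#' @export
triage_dt <- function(predictions, threshold,
                      entropy = c("diagnostic", "ensemble")) {
  entropy <- match.arg(entropy)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0) {
    stop("`threshold` must be a single finite number >= 0.", call. = FALSE)
  }
  p <- prob_matrix(predictions)
  u <- if (entropy == "diagnostic") diagnostic_entropy(p) else ensemble_entropy(p)
  vote_pos <- rowMeans(p >= 0.5)
  cls <- as.character(majority_diagnosis(p))
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(predictions)) {
      as.character(predictions$sample_id)
    } else {
      sprintf("s%05d", seq_len(nrow(p)))
    },
    decision = ifelse(u > threshold, "defer", cls),
    score_class0 = 1 - vote_pos,
    score_class1 = vote_pos,
    score_defer = NA_real_,
    algorithm = "dt",
    param_name = "threshold",
    param_value = threshold
  )
  for (col in intersect(c("label", "subgroup"), names(predictions))) {
    out[[col]] <- predictions[[col]]
  }
  out
}
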