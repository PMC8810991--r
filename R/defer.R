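# Stage two: the defer network.
#
# A fully connected network over the K + 2 stage-one features with
# C + 1 = 3 outputs (class 0, class 1, defer), trained with the weighted
# defer loss.  No defer labels exist in the training data: the constant
# alpha-weighted defer term is what makes deferral a learnable action.

#' Specification of the defer network
#'
#' Defaults follow the reference stage-two design: two hidden layers of
#' 100 nodes, 20 epochs of SGD.  The learning rate applies to
#' standardised inputs.
#'
#' @param hidden Hidden-layer widths.
#' @param alpha Positive defer-loss weight; lower values defer more
#'   patients (see [defer_loss()]).
#' @param alpha_on Which loss term carries `alpha`; `"target"` (default)
#'   or the literal transposed form `"defer"`.
#' @param epochs,learning_rate,batch_size,optimizer,momentum,weight_decay
#'   Optimisation settings, as in [base_classifier_spec()].
#' @param seed Integer initialisation seed.
#' @return An object of class `defer_model_spec`.
#' @export
defer_model_spec <- function(hidden = c(100L, 100L), alpha = 1,
                             alpha_on = c("target", "defer"),
                             epochs = 20L, learning_rate = 0.1,
                             batch_size = 32L,
                             optimizer = c("sgd", "adam"),
                             momentum = 0.9, weight_decay = 0,
                             seed = 1L) {
  alpha_on <- match.arg(alpha_on)
  optimizer <- match.arg(optimizer)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a single finite number > 0.", call. = FALSE)
  }
  stopifnot(length(hidden) >= 1L, all(hidden >= 1L), epochs >= 1L,
            learning_rate > 0, batch_size >= 1L)
  structure(
    list(hidden = as.integer(hidden), alpha = alpha, alpha_on = alpha_on,
         epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), optimizer = optimizer,
         momentum = momentum, weight_decay = weight_decay,
         seed = as.integer(seed)),
    class = "defer_model_spec"
  )
}

#' Train the defer network
#'
#' @param features Stage-two feature tibble from
#'   [build_stage2_features()] (K member probabilities plus `u_e`,
#'   `u_d`), or a bare numeric matrix of width K + 2.
#' @param spec A [defer_model_spec()]; `spec$alpha` sets the
#'   diagnose/defer trade-off.
#' @param labels 0/1 diagnostic labels; taken from `features$label` when
#'   omitted.
#' @return A `defer_model`; pass it to [triage()].
#' @examples
#' cohort <- simulate_cohort(n_per_class = 60, seed = 1)
#' ens <- train_ensemble(cohort, base_classifier_spec(hidden = c(8, 8), epochs = 5),
#'                       k = 3, master_seed = 1)
#' s2 <- build_stage2_features(predict(ens, cohort))
#' dm <- train_defer_network(s2, defer_model_spec(hidden = c(16, 16), epochs = 5))
#' triage(dm, s2)
#' @export
train_defer_network <- function(features, spec = defer_model_spec(),
                                labels = NULL) {
  stopifnot(inherits(spec, "defer_model_spec"))
  x <- if (is.matrix(features)) features else stage2_matrix(features)
  if (is.null(labels)) {
    if (!is.matrix(features) && "label" %in% names(features)) {
      labels <- features$label
    } else {
      stop("`labels` missing and `features` has no `label` column.",
           call. = FALSE)
    }
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) {
    stop("`labels` length does not match `features` rows.", call. = FALSE)
  }
  check_two_classes(labels)
  net <- mlp_train(x, labels, n_out = 3L, hidden = spec$hidden,
                   loss = "defer", alpha = spec$alpha,
                   alpha_on = spec$alpha_on, epochs = spec$epochs,
                   learning_rate = spec$learning_rate,
                   batch_size = spec$batch_size, optimizer = spec$optimizer,
                   momentum = spec$momentum, weight_decay = spec$weight_decay,
                   seed = spec$seed)
  structure(list(net = net, spec = spec, n_in = ncol(x)),
            class = "defer_model")
}

#' @export
print.defer_model <- function(x, ...) {
  cat(sprintf(
    "Defer network: %d inputs -> %s -> 3 outputs (class 0, class 1, defer)\n",
    x$n_in, paste(x$spec$hidden, collapse = "-")))
  cat(sprintf("alpha = %g (on %s term), %d epochs, final loss %.4f\n",
              x$spec$alpha, x$spec$alpha_on, x$spec$epochs,
              utils::tail(x$net$epoch_loss, 1)))
  invisible(x)
}

# decision from softmax scores over (class 0, class 1, defer):
# argmax with ties broken toward defer (the conservative action), and
# class ties toward the positive class (matching the vote rule).
decide_from_scores <- function(p) {
  stopifnot(ncol(p) == 3L)
  defer <- p[, 3L] >= pmax(p[, 1L], p[, 2L])
  cls <- ifelse(p[, 2L] >= p[, 1L], "1", "0")
  ifelse(defer, "defer", cls)
}

triage_tibble <- function(sample_id, p, algorithm, param_name, param_value,
                          carry = NULL) {
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    decision = decide_from_scores(p),
    score_class0 = p[, 1L],
    score_class1 = p[, 2L],
    score_defer = p[, 3L],
    algorithm = algorithm,
    param_name = param_name,
    param_value = param_value
  )
  if (!is.null(carry)) {
    for (col in intersect(c("label", "subgroup"), names(carry))) {
      out[[col]] <- carry[[col]]
    }
  }
  out
}

#' Diagnose-or-defer decisions for a set of patients
#'
#' Applies a fitted defer-capable model and returns one decision per
#' patient: the predicted class (`"0"`/`"1"`) or `"defer"`.  The
#' decision is the argmax over the three softmax outputs, with ties
#' broken toward deferral (the conservative action for a diagnostic
#' aid).
#'
#' @param model A `defer_model` (from [train_defer_network()]) or an
#'   `ld_model` (from [train_ld()]).
#' @param data Stage-two features for a `defer_model`; a raw feature
#'   table for an `ld_model`.
#' @param ... Unused.
#' @return A triage tibble with columns `sample_id`, `decision`,
#'   `score_class0`, `score_class1`, `score_defer`, `algorithm`,
#'   `param_name`, `param_value` (+ `label`/`subgroup` when present in
#'   `data`).
#' @export
triage <- function(model, data, ...) UseMethod("triage")

#' @rdname triage
#' @export
triage.defer_model <- function(model, data, ...) {
  x <- if (is.matrix(data)) data else stage2_matrix(data)
  p <- mlp_prob(model$net, x)
  triage_tibble(
    if (!is.matrix(data) && "sample_id" %in% names(data)) data$sample_id
    else sprintf("s%05d", seq_len(nrow(x))),
    p, "ldu", "alpha", model$spec$alpha,
    carry = if (!is.matrix(data)) data
  )
}
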