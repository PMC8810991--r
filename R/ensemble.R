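# Stage one: a deep ensemble of fully connected diagnostic networks.
#
# K identically configured members are trained on the SAME rows and
# differ only in their random parameter initialisation (and minibatch
# order), which is the deep-ensemble recipe for epistemic uncertainty:
# no bootstrap resampling is performed.

#' Specification of a base diagnostic classifier
#'
#' Architecture and optimisation settings for one ensemble member (also
#' reused by the no-defer diagnostic network and, with one extra output,
#' by the LD baseline).  The default mirrors a compact structured-data
#' diagnostic network: fully connected, two hidden layers of 200 nodes.
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs Training epochs (>= 1).
#' @param learning_rate Positive SGD/Adam step size.  Inputs are
#'   standardised internally, so the default is on that scale.
#' @param batch_size Minibatch size.
#' @param optimizer `"sgd"` (with momentum) or `"adam"`.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty added to the weight gradients.
#' @return An object of class `base_classifier_spec`.
#' @export
base_classifier_spec <- function(hidden = c(200L, 200L), epochs = 20L,
                                 learning_rate = 0.1, batch_size = 32L,
                                 optimizer = c("sgd", "adam"),
                                 momentum = 0.9, weight_decay = 1e-4) {
  optimizer <- match.arg(optimizer)
  stopifnot(length(hidden) >= 1L, all(hidden >= 1L), epochs >= 1L,
            learning_rate > 0, batch_size >= 1L,
            momentum >= 0, momentum < 1, weight_decay >= 0)
  structure(
    list(hidden = as.integer(hidden), epochs = as.integer(epochs),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         optimizer = optimizer, momentum = momentum,
         weight_decay = weight_decay),
    class = "base_classifier_spec"
  )
}

train_base_net <- function(x, y, spec, seed, n_out = 2L, loss = "ce",
                           alpha = 1, alpha_on = "target") {
  mlp_train(x, y, n_out = n_out, hidden = spec$hidden, loss = loss,
            alpha = alpha, alpha_on = alpha_on, epochs = spec$epochs,
            learning_rate = spec$learning_rate, batch_size = spec$batch_size,
            optimizer = spec$optimizer, momentum = spec$momentum,
            weight_decay = spec$weight_decay, seed = seed)
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes.", call. = FALSE)
  }
}

#' Train a deep ensemble of diagnostic networks
#'
#' Trains `k` members on identical training rows; member `i` is
#' initialised from seed `master_seed + i - 1`, so a single integer
#' reproduces the whole ensemble.
#'
#' @param train Feature table with `f*` columns and a 0/1 `label`.
#' @param spec A [base_classifier_spec()].
#' @param k Number of members (>= 2); 50 by default.
#' @param master_seed Integer seed from which member seeds are derived.
#' @return An `ensemble_model`; use [predict()][predict.ensemble_model]
#'   to obtain member probabilities.
#' @examples
#' cohort <- simulate_cohort(n_per_class = 60, seed = 1)
#' ens <- train_ensemble(cohort, base_classifier_spec(hidden = c(8, 8), epochs = 5),
#'                       k = 3, master_seed = 1)
#' predict(ens, cohort)
#' @export
train_ensemble <- function(train, spec = base_classifier_spec(), k = 50L,
                           master_seed = 1L) {
  stopifnot(inherits(spec, "base_classifier_spec"))
  if (k < 2L) stop("`k` must be at least 2.", call. = FALSE)
  x <- feature_matrix(train)
  y <- train$label
  check_two_classes(y)
  seeds <- as.integer(master_seed) + seq_len(k) - 1L
  members <- purrr::imap(seeds, function(s, i) {
    tryCatch(
      train_base_net(x, y, spec, seed = s),
      error = function(e) {
        stop(sprintf("ensemble member %d failed: %s", i, conditionMessage(e)),
             call. = FALSE)
      }
    )
  })
  structure(
    list(members = members, spec = spec, k = as.integer(k), seeds = seeds,
         n_features = ncol(x), n_train = nrow(x)),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("Deep ensemble: %d members, %d features, %d training rows\n",
              x$k, x$n_features, x$n_train))
  cat(sprintf("member architecture: %s; seeds %d..%d\n",
              paste(x$spec$hidden, collapse = "-"),
              x$seeds[1], x$seeds[x$k]))
  invisible(x)
}

#' Member probabilities for new patients
#'
#' @param object An `ensemble_model`.
#' @param newdata Feature table whose `f*` columns match the training
#'   dimension.
#' @param ... Unused.
#' @return A tibble with `sample_id`, member positive-class
#'   probabilities `p_0 .. p_{K-1}`, and `label`/`subgroup` when present
#'   in `newdata`.
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  if (ncol(x) != object$n_features) {
    stop(sprintf("feature dimension mismatch: ensemble expects %d features, got %d.",
                 object$n_features, ncol(x)), call. = FALSE)
  }
  n <- nrow(x)
  probs <- if (n == 0L) {
    matrix(numeric(0), 0L, object$k)
  } else {
    m <- vapply(object$members, function(mm) mlp_prob(mm, x)[, 2L], numeric(n))
    if (n == 1L) matrix(m, 1L) else m
  }
  colnames(probs) <- paste0("p_", seq_len(object$k) - 1L)
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(newdata)) {
      as.character(newdata$sample_id)
    } else {
      sprintf("s%05d", seq_len(nrow(x)))
    },
    tibble::as_tibble(probs)
  )
  if ("label" %in% names(newdata)) out$label <- as.integer(newdata$label)
  if ("subgroup" %in% names(newdata)) out$subgroup <- newdata$subgroup
  out
}

# member-probability matrix from an ensemble-output tibble
prob_matrix <- function(predictions) {
  cols <- grep("^p_[0-9]+$", names(predictions), value = TRUE)
  if (length(cols) == 0L) {
    stop("no member probability columns (`p_0`, `p_1`, ...) found.",
         call. = FALSE)
  }
  cols <- cols[order(as.integer(sub("^p_", "", cols)))]
  m <- as.matrix(predictions[cols])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0 | m > 1)) {
    stop("member probabilities must be finite and in [0, 1].", call. = FALSE)
  }
  m
}

#' Majority-vote diagnosis of an ensemble
#'
#' Each member votes class 1 when its positive-class probability is at
#' least 0.5; the returned class is the majority vote, with ties going
#' to the positive class.  This is also the "diagnostic network without
#' defer option" predictor against which deferral gains are measured.
#'
#' @param predictions Ensemble output tibble (or a bare probability
#'   matrix) with one `p_*` column per member.
#' @return Integer vector of 0/1 diagnoses.
#' @examples
#' majority_diagnosis(tibble::tibble(p_0 = c(0.9, 0.1), p_1 = c(0.8, 0.2)))
#' @export
majority_diagnosis <- function(predictions) {
  p <- if (is.matrix(predictions)) predictions else prob_matrix(predictions)
  votes <- rowSums(p >= 0.5)
  as.integer(votes >= ncol(p) / 2)
}

#' Train the no-defer diagnostic network
#'
#' A single base classifier trained with plain cross-entropy; its F1 on
#' the test split is the reference that deferral methods try to beat.
#'
#' @inheritParams train_ensemble
#' @param seed Integer initialisation seed.
#' @return A `diagnostic_model` with a `predict()` method returning a
#'   tibble of `sample_id`, `p_1` (positive-class probability) and
#'   `pred` (thresholded at 0.5).
#' @export
train_diagnostic_network <- function(train, spec = base_classifier_spec(),
                                     seed = 1L) {
  stopifnot(inherits(spec, "base_classifier_spec"))
  x <- feature_matrix(train)
  check_two_classes(train$label)
  net <- train_base_net(x, train$label, spec, seed = seed)
  structure(list(net = net, spec = spec, n_features = ncol(x)),
            class = "diagnostic_model")
}

#' @export
predict.diagnostic_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  p <- mlp_prob(object$net, x)
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(newdata)) {
      as.character(newdata$sample_id)
    } else {
      sprintf("s%05d", seq_len(nrow(x)))
    },
    p_1 = if (nrow(p)) p[, 2L] else numeric(0)
  )
  out$pred <- as.integer(out$p_1 >= 0.5)
  if ("label" %in% names(newdata)) out$label <- as.integer(newdata$label)
  out
}
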