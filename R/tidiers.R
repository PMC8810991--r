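#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ensemble model
#'
#' @param x An `ensemble_model`.
#' @param ... Unused.
#' @return One row per member: `member`, `seed`, `final_loss`.
#' @export
tidy.ensemble_model <- function(x, ...) {
  tibble::tibble(
    member = seq_len(x$k),
    seed = x$seeds,
    final_loss = vapply(x$members, function(m) utils::tail(m$epoch_loss, 1),
                        numeric(1))
  )
}

#' @rdname tidy.ensemble_model
#' @return `glance()` returns a one-row summary.
#' @export
glance.ensemble_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_train = x$n_train, n_features = x$n_features,
    hidden = paste(x$spec$hidden, collapse = "-"),
    epochs = x$spec$epochs, optimizer = x$spec$optimizer
  )
}

#' Tidy a defer model
#'
#' @param x A `defer_model`.
#' @param ... Unused.
#' @return One row per training epoch with the mean defer loss.
#' @export
tidy.defer_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$net$epoch_loss),
                 loss = x$net$epoch_loss)
}

#' @rdname tidy.defer_model
#' @export
glance.defer_model <- function(x, ...) {
  tibble::tibble(
    alpha = x$spec$alpha, alpha_on = x$spec$alpha_on,
    n_inputs = x$n_in,
    hidden = paste(x$spec$hidden, collapse = "-"),
    epochs = x$spec$epochs,
    final_loss = utils::tail(x$net$epoch_loss, 1)
  )
}
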