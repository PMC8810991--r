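# Evaluation metrics for diagnose-or-defer systems.
#
# All rates are fractions in [0, 1]; formatting as percent belongs to
# the reporting layer.  Undefined ratios (0/0) are returned as NA with
# an explicit flag, never silently as 0.

f1_positive <- function(truth, pred) {
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Metrics of a triage result
#'
#' Computes the defer rate, the positive-class F1 / accuracy /
#' sensitivity / specificity over the *non-deferred* patients, and the
#' overall F1 over *all* patients under the assumption that every
#' deferred patient receives the correct diagnosis from the human
#' expert.  Quantities whose denominator is empty (e.g. F1 when every
#' patient is deferred) are `NA` and named in `flags`.
#'
#' @param triage A triage tibble (from [triage()] or [triage_dt()]).
#' @param labels 0/1 ground-truth labels: a numeric vector aligned with
#'   `triage`, or a data frame with `sample_id` and `label` to join on;
#'   taken from `triage$label` when omitted.
#' @return A one-row tibble: `n`, `n_non_deferred`, `defer_rate`, `f1`,
#'   `f1_overall`, `accuracy`, `sensitivity`, `specificity`, `flags`.
#' @examples
#' tri <- tibble::tibble(decision = c("1", "defer", "0", "defer"))
#' compute_metrics(tri, labels = c(1, 1, 0, 0))
#' @export
compute_metrics <- function(triage, labels = NULL) {
  if (is.null(labels)) {
    if (!"label" %in% names(triage)) {
      stop("`labels` missing and `triage` has no `label` column.", call. = FALSE)
    }
    labels <- triage$label
  } else if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "label") %in% names(labels)))
    idx <- match(triage$sample_id, labels$sample_id)
    if (anyNA(idx)) stop("`labels` does not cover all triaged samples.", call. = FALSE)
    labels <- labels$label[idx]
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(triage)) {
    stop("`labels` length does not match `triage` rows.", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must be 0/1.", call. = FALSE)
  }
  decision <- as.character(triage$decision)
  deferred <- decision == "defer"
  n <- length(labels)
  n_kept <- sum(!deferred)
  flags <- character(0)

  if (n_kept > 0) {
    truth <- labels[!deferred]
    pred <- as.integer(decision[!deferred])
    tp <- sum(truth == 1L & pred == 1L); tn <- sum(truth == 0L & pred == 0L)
    fp <- sum(truth == 0L & pred == 1L); fn <- sum(truth == 1L & pred == 0L)
    f1 <- f1_positive(truth, pred)
    if (is.na(f1)) flags <- c(flags, "f1_undefined")
    accuracy <- (tp + tn) / n_kept
    sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    if (is.na(sensitivity)) flags <- c(flags, "sensitivity_undefined")
    specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    if (is.na(specificity)) flags <- c(flags, "specificity_undefined")
  } else {
    f1 <- accuracy <- sensitivity <- specificity <- NA_real_
    flags <- c(flags, "all_deferred")
  }

  pred_overall <- ifelse(deferred, labels, suppressWarnings(as.integer(decision)))
  f1_overall <- f1_positive(labels, pred_overall)
  if (is.na(f1_overall)) flags <- c(flags, "f1_overall_undefined")

  tibble::tibble(
    n = n, n_non_deferred = n_kept,
    defer_rate = 1 - n_kept / n,
    f1 = f1, f1_overall = f1_overall,
    accuracy = accuracy, sensitivity = sensitivity,
    specificity = specificity,
    flags = paste(flags, collapse = ";")
  )
}

#' Lowest-deferral operating point reaching a target F1
#'
#' From a sweep table, returns the record with the smallest defer rate
#' among those whose non-deferred F1 reaches `target_f1`.  When no
#' record qualifies the returned row is all-`NA` with
#' `flag = "unreachable"` rather than an error, so sweeps over many
#' targets stay rectangular.
#'
#' @param records A sweep tibble (from [sweep_defer()]) with `f1` and
#'   `defer_rate` columns.
#' @param target_f1 Required minimum F1 on non-deferred patients.
#' @return A one-row tibble: the selected record plus a `flag` column
#'   (`""` or `"unreachable"`).
#' @export
operating_point <- function(records, target_f1) {
  stopifnot(nrow(records) > 0, is.numeric(target_f1), length(target_f1) == 1L)
  ok <- !is.na(records$f1) & records$f1 >= target_f1
  if (!any(ok)) {
    out <- records[1L, ]
    out[1L, ] <- NA
    out$flag <- "unreachable"
    return(out)
  }
  hits <- records[ok, ]
  out <- hits[order(hits$defer_rate, hits$param_value)[1L], ]
  out$flag <- ""
  out
}
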