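# Synthetic patient cohorts with controllable difficulty structure.
#
# Three regimes, chosen so every downstream behaviour of a
# defer-or-diagnose system is exercised without any external data:
#   easy               - class-specific Gaussian centroids, separable;
#   ambiguous          - both classes drawn from one shared centroid, so
#                        the Bayes error inside the region is 0.5;
#   overconfident_wrong- feature-consistent with the OPPOSITE class
#                        (placed inside its confident region), so every
#                        well-trained classifier is confidently wrong.

#' Simulate a labelled binary-diagnosis cohort
#'
#' Generates a class-balanced feature table of `2 * n_per_class`
#' patients split across three difficulty subgroups.  Easy patients sit
#' at class-specific centroids `+/- class_separation / 2` along the
#' first feature axis; ambiguous patients of both classes share the
#' midpoint centroid; overconfident-wrong patients are labelled `y` but
#' placed at `ocw_shift` times the centroid of class `1 - y`, i.e.
#' inside the opposite class's confident region, emulating cohorts where
#' an ensemble predicts the wrong diagnosis with high confidence and
#' unanimous member votes.
#'
#' The `subgroup` tag is carried for evaluation diagnostics only; no
#' model in the package ever receives it (models see `f*` columns only).
#'
#' @param n_per_class Patients per class (total rows `2 * n_per_class`).
#' @param n_features Feature dimension.
#' @param easy_fraction,ambiguous_fraction,overconfident_wrong_fraction
#'   Subgroup fractions; must sum to 1.
#' @param class_separation Distance between the two easy-region
#'   centroids, in feature units.
#' @param noise_sd Within-region feature standard deviation (> 0).
#' @param ocw_shift Placement of the overconfident-wrong centroid as a
#'   fraction of the opposite-class centroid (in (0, 1]); 0.75 keeps the
#'   samples confidently on the wrong side while leaving their member
#'   probabilities measurably less extreme than genuine easy samples.
#' @param n_modes Number of easy-region modes per class.  With the
#'   default 1 each class is a single blob at `+/- class_separation / 2`
#'   on the first axis.  With `n_modes > 1` each class occupies several
#'   randomly oriented centroids at radius `class_separation / 2`,
#'   emulating the heterogeneous presentation of real cohorts: the
#'   diagnostic task stays learnable, but locating confidently-wrong
#'   patients in *feature* space becomes hard while their ensemble
#'   probability signature is unchanged.
#' @param seed Integer RNG seed; generation is fully reproducible.
#' @return A tibble with columns `sample_id`, `f0 .. f{n_features-1}`,
#'   `label` (0/1) and `subgroup`.
#' @examples
#' cohort <- simulate_cohort(n_per_class = 100, seed = 1)
#' dplyr::count(cohort, label, subgroup)
#' @export
simulate_cohort <- function(n_per_class,
                            n_features = 16L,
                            easy_fraction = 0.6,
                            ambiguous_fraction = 0.3,
                            overconfident_wrong_fraction = 0.1,
                            class_separation = 10,
                            noise_sd = 1,
                            ocw_shift = 0.75,
                            n_modes = 1L,
                            seed = 1L) {
  check_scalar <- function(x, name, lower, upper = Inf, strict_lower = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
      (if (strict_lower) x > lower else x >= lower) && x <= upper
    if (!ok) {
      stop(sprintf("invalid `%s`: must be a number in %s%g, %g].",
                   name, if (strict_lower) "(" else "[", lower, upper),
           call. = FALSE)
    }
  }
  check_scalar(n_per_class, "n_per_class", 1)
  check_scalar(n_features, "n_features", 1)
  check_scalar(easy_fraction, "easy_fraction", 0, 1)
  check_scalar(ambiguous_fraction, "ambiguous_fraction", 0, 1)
  check_scalar(overconfident_wrong_fraction, "overconfident_wrong_fraction", 0, 1)
  check_scalar(class_separation, "class_separation", 0)
  check_scalar(noise_sd, "noise_sd", 0, strict_lower = TRUE)
  check_scalar(ocw_shift, "ocw_shift", 0, 1, strict_lower = TRUE)
  check_scalar(n_modes, "n_modes", 1)
  fr <- c(easy = easy_fraction, ambiguous = ambiguous_fraction,
          overconfident_wrong = overconfident_wrong_fraction)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("invalid fractions: `easy_fraction`, `ambiguous_fraction` and ",
         "`overconfident_wrong_fraction` must sum to 1.", call. = FALSE)
  }
  n_per_class <- as.integer(n_per_class)
  n_features <- as.integer(n_features)
  n_modes <- as.integer(n_modes)

  counts <- largest_remainder(n_per_class, fr)
  half_sep <- class_separation / 2

  withr::with_seed(as.integer(seed), {
    # mode centroids per class: the single-mode layout is the canonical
    # two-blob arrangement on the first axis; multi-mode layouts use
    # random orientations at the same radius
    modes <- lapply(0:1, function(y) {
      sign_y <- if (y == 1L) 1 else -1
      if (n_modes == 1L) {
        matrix(c(sign_y * half_sep, rep(0, n_features - 1L)), nrow = 1L)
      } else {
        NULL # filled below from a shared orthonormal frame
      }
    })
    if (n_modes > 1L) {
      # one orthonormal frame split between the classes keeps every
      # pair of modes (within and across classes) at distance
      # class_separation / sqrt(2), so the easy regions stay separable
      # whatever the draw; beyond the feature budget fall back to
      # independent random directions
      total <- 2L * n_modes
      dir <- matrix(stats::rnorm(n_features * total), nrow = n_features)
      if (total <= n_features) dir <- qr.Q(qr(dir))[, seq_len(total), drop = FALSE]
      dir <- t(dir) / sqrt(colSums(dir^2))
      modes <- list(dir[seq_len(n_modes), , drop = FALSE] * half_sep,
                    dir[n_modes + seq_len(n_modes), , drop = FALSE] * half_sep)
    }
    rows <- purrr::map(0:1, function(y) {
      purrr::imap(counts, function(n_g, g) {
        if (n_g == 0L) return(NULL)
        x <- matrix(stats::rnorm(n_g * n_features, sd = noise_sd),
                    nrow = n_g, ncol = n_features)
        centroid <- switch(
          g,
          easy = modes[[y + 1L]][sample.int(n_modes, n_g, replace = TRUE), ,
                                 drop = FALSE],
          ambiguous = matrix(0, n_g, n_features),
          overconfident_wrong =
            ocw_shift * modes[[2L - y]][sample.int(n_modes, n_g, replace = TRUE), ,
                                        drop = FALSE]
        )
        x <- x + centroid
        list(x = x, label = rep(y, n_g), subgroup = rep(g, n_g))
      })
    })
    rows <- purrr::compact(purrr::flatten(rows))
    x <- do.call(rbind, purrr::map(rows, "x"))
    label <- unlist(purrr::map(rows, "label"), use.names = FALSE)
    subgroup <- unlist(purrr::map(rows, "subgroup"), use.names = FALSE)
    ord <- sample.int(nrow(x))
    colnames(x) <- paste0("f", seq_len(n_features) - 1L)
    out <- tibble::as_tibble(x[ord, , drop = FALSE])
    tibble::tibble(
      sample_id = sprintf("s%05d", seq_len(nrow(out))),
      out,
      label = as.integer(label[ord]),
      subgroup = subgroup[ord]
    )
  })
}

# integer allocation by largest remainder; deterministic (ties resolved
# in the order easy, ambiguous, overconfident_wrong)
largest_remainder <- function(n, fractions) {
  base <- floor(fractions * n)
  missing_n <- n - sum(base)
  if (missing_n > 0) {
    rem <- fractions * n - base
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(missing_n)]] <- base[ord[seq_len(missing_n)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Stratified train/test split
#'
#' Splits a feature table into disjoint train and test tables,
#' stratified by `label` so both sides stay class-balanced.  The
#' conventional 70/30 split is the default.
#'
#' @param table A feature table (as from [simulate_cohort()] or
#'   [read_feature_table()]).
#' @param train_fraction Fraction of each class assigned to training,
#'   strictly between 0 and 1.
#' @param seed Integer seed controlling the row assignment.
#' @return A named list with tibbles `train` and `test`.
#' @examples
#' cohort <- simulate_cohort(n_per_class = 50, seed = 1)
#' parts <- split_cohort(cohort, train_fraction = 0.7, seed = 1)
#' nrow(parts$train); nrow(parts$test)
#' @export
split_cohort <- function(table, train_fraction = 0.7, seed = 1L) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      !is.finite(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  table <- tibble::as_tibble(table)
  stopifnot("label" %in% names(table))
  idx_train <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_len(nrow(table)), table$label), function(idx) {
      n_tr <- floor(length(idx) * train_fraction + 0.5)
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  train <- table[sort(idx_train), , drop = FALSE]
  test <- table[setdiff(seq_len(nrow(table)), idx_train), , drop = FALSE]
  if (nrow(train) == 0L || nrow(test) == 0L) {
    stop("split would leave an empty train or test set.", call. = FALSE)
  }
  list(train = train, test = test)
}

#' Extract the feature matrix of a feature table
#'
#' @param table A feature table with `f0 .. f{d-1}` columns.
#' @return A numeric matrix, rows in table order.
#' @export
feature_matrix <- function(table) {
  cols <- grep("^f[0-9]+$", names(table), value = TRUE)
  if (length(cols) == 0L) {
    stop("no feature columns (`f0`, `f1`, ...) found.", call. = FALSE)
  }
  cols <- cols[order(as.integer(sub("^f", "", cols)))]
  m <- as.matrix(table[cols])
  storage.mode(m) <- "double"
  m
}

#' Read/write feature tables as CSV
#'
#' Plain UTF-8 CSV with header `sample_id,f0..f{d-1},label[,subgroup]`,
#' one row per patient.
#'
#' @param table A feature table.
#' @param path File path.
#' @return `write_feature_table()` returns `table` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(table)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(out))) {
    stop("expected columns `sample_id` and `label` in ", path, call. = FALSE)
  }
  out$sample_id <- as.character(out$sample_id)
  out$label <- as.integer(out$label)
  if (anyNA(out)) stop("missing values in ", path, call. = FALSE)
  if (!all(out$label %in% c(0L, 1L))) {
    stop("`label` must be 0/1 in ", path, call. = FALSE)
  }
  out
}
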