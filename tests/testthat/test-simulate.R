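test_that("subgroup allocation matches the configured fractions exactly", {
  tab <- simulate_cohort(n_per_class = 200, easy_fraction = 0.6,
                         ambiguous_fraction = 0.3,
                         overconfident_wrong_fraction = 0.1, seed = 7)
  expect_equal(nrow(tab), 400)
  expect_equal(sum(tab$label == 1), 200)
  expect_false(anyNA(tab))
  counts <- table(tab$subgroup)
  expect_equal(unname(counts[["easy"]]), 240)
  expect_equal(unname(counts[["ambiguous"]]), 120)
  expect_equal(unname(counts[["overconfident_wrong"]]), 40)
  # tags are balanced across classes too
  by_class <- table(tab$subgroup, tab$label)
  expect_equal(unname(by_class["easy", "0"]), 120)
  expect_equal(unname(by_class["overconfident_wrong", "1"]), 20)
})

test_that("generation is deterministic per seed and regimes behave as designed", {
  a <- simulate_cohort(n_per_class = 100, seed = 3)
  b <- simulate_cohort(n_per_class = 100, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(n_per_class = 100, seed = 4)))

  # easy-only: nearest class centroid classifies perfectly
  easy <- simulate_cohort(n_per_class = 100, easy_fraction = 1,
                          ambiguous_fraction = 0,
                          overconfident_wrong_fraction = 0,
                          class_separation = 10, noise_sd = 0.5, seed = 1)
  x <- feature_matrix(easy)
  mu1 <- colMeans(x[easy$label == 1, ]); mu0 <- colMeans(x[easy$label == 0, ])
  d1 <- rowSums(sweep(x, 2, mu1)^2); d0 <- rowSums(sweep(x, 2, mu0)^2)
  expect_equal(as.integer(d1 < d0), easy$label)

  # ambiguous-only: both classes share one distribution, so any fixed
  # rule sits at chance
  amb <- simulate_cohort(n_per_class = 100, easy_fraction = 0,
                         ambiguous_fraction = 1,
                         overconfident_wrong_fraction = 0, seed = 1)
  acc <- mean(as.integer(feature_matrix(amb)[, 1] > 0) == amb$label)
  expect_gt(acc, 0.4)
  expect_lt(acc, 0.6)

  # overconfident-wrong rows sit on the opposite class's side of the
  # first axis (single-mode layout)
  ocw <- ocw_cohort(n_per_class = 200, seed = 2)
  f0 <- feature_matrix(ocw)[, 1]
  bad <- ocw$subgroup == "overconfident_wrong"
  expect_true(all(sign(f0[bad]) != sign(ocw$label[bad] - 0.5)))
})

test_that("multi-mode layouts keep classes separable and balanced", {
  tab <- simulate_cohort(n_per_class = 300, n_modes = 4,
                         class_separation = 10, seed = 5)
  expect_equal(sum(tab$label == 1), 300)
  # easy samples remain learnable despite the scattered modes: 1-nearest
  # neighbour across held-out easy rows recovers the class
  x <- feature_matrix(tab)[tab$subgroup == "easy", ]
  y <- tab$label[tab$subgroup == "easy"]
  ref <- seq_along(y) %% 2 == 0
  d2 <- as.matrix(stats::dist(x))[!ref, ref]
  pred <- y[ref][apply(d2, 1, which.min)]
  expect_gt(mean(pred == y[!ref]), 0.95)
})

test_that("subgroup proportions converge to the configured fractions", {
  tab <- simulate_cohort(n_per_class = 1000, seed = 11)
  counts <- table(factor(tab$subgroup,
                         c("easy", "ambiguous", "overconfident_wrong")))
  p <- stats::chisq.test(counts, p = c(0.6, 0.3, 0.1))$p.value
  expect_gt(p, 0.01)
})

test_that("stratified split is disjoint, covering, balanced and reproducible", {
  tab <- simulate_cohort(n_per_class = 200, seed = 1)
  parts <- split_cohort(tab, train_fraction = 0.7, seed = 9)
  expect_equal(nrow(parts$train), 280)
  expect_equal(nrow(parts$test), 120)
  expect_length(intersect(parts$train$sample_id, parts$test$sample_id), 0)
  expect_setequal(c(parts$train$sample_id, parts$test$sample_id), tab$sample_id)
  expect_lte(abs(sum(parts$train$label == 1) - 140), 1)
  expect_lte(abs(sum(parts$test$label == 1) - 60), 1)
  again <- split_cohort(tab, train_fraction = 0.7, seed = 9)
  expect_identical(parts, again)
  expect_false(identical(parts$train$sample_id,
                         split_cohort(tab, 0.7, seed = 10)$train$sample_id))
})

test_that("invalid configurations fail with the offending field named", {
  expect_error(simulate_cohort(0), "n_per_class")
  expect_error(simulate_cohort(10, noise_sd = 0), "noise_sd")
  expect_error(simulate_cohort(10, easy_fraction = 1.2), "easy_fraction")
  expect_error(simulate_cohort(10, easy_fraction = 0.5,
                               ambiguous_fraction = 0.3,
                               overconfident_wrong_fraction = 0.1),
               "sum to 1")
  tab <- simulate_cohort(n_per_class = 3, seed = 1)
  expect_error(split_cohort(tab, train_fraction = 0), "train_fraction")
  expect_error(split_cohort(tab, train_fraction = 0.01), "empty")
})

test_that("feature tables survive a CSV round trip", {
  tab <- simulate_cohort(n_per_class = 20, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  # rewriting produces byte-identical files
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path2)
  expect_identical(readLines(path), readLines(path2))
})
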