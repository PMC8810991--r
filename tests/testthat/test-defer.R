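test_that("defer loss matches hand-evaluated cases and limiting behaviour", {
  expect_equal(defer_loss(c(0, 0, 0), target = 0, alpha = 1), 2 * log(3))
  expect_equal(defer_loss(c(0, 0, 0), target = 1, alpha = 2), 3 * log(3))
  # alpha -> infinity: the weighted loss is dominated by the target term
  sc <- c(1.2, -0.3, 0.4)
  ce_target <- -(sc[1] - log(sum(exp(sc))))
  expect_equal(defer_loss(sc, 0, alpha = 1e8) / 1e8, ce_target,
               tolerance = 1e-6)
  # vectorised over rows
  m <- rbind(c(0, 0, 0), c(1, 2, 3))
  expect_length(defer_loss(m, target = c(0L, 1L), alpha = 1), 2)
})

test_that("invalid loss inputs are rejected", {
  expect_error(defer_loss(c(0, 0, 0), 0, alpha = 0), "alpha")
  expect_error(defer_loss(c(0, 0, 0), 0, alpha = -1), "alpha")
  expect_error(defer_loss(c(0, Inf, 0), 0, alpha = 1), "finite")
  expect_error(defer_loss(c(0, 0, 0), 2, alpha = 1), "target")
})

test_that("the two alpha placements coincide exactly at alpha = 1", {
  withr::with_seed(2, {
    for (rep in 1:20) {
      sc <- rnorm(4)
      tg <- sample(0:2, 1)
      expect_identical(defer_loss(sc, tg, 1, alpha_on = "target"),
                       defer_loss(sc, tg, 1, alpha_on = "defer"))
      # away from alpha = 1 the forms differ (unless the two
      # cross-entropies happen to coincide)
      lp <- deferral:::log_softmax(matrix(sc, 1))
      if (abs(lp[tg + 1] - lp[4]) > 1e-8) {
        expect_false(isTRUE(all.equal(
          defer_loss(sc, tg, 2, alpha_on = "target"),
          defer_loss(sc, tg, 2, alpha_on = "defer"))))
      }
    }
  })
})

test_that("decisions take the argmax with ties broken toward defer", {
  p <- rbind(c(0.2, 0.3, 0.5),
             c(0.7, 0.1, 0.2),
             c(0.4, 0.2, 0.4),   # class-0/defer tie -> defer
             c(0.25, 0.5, 0.25),
             c(0.45, 0.45, 0.1)) # class tie -> positive
  expect_equal(deferral:::decide_from_scores(p),
               c("defer", "0", "defer", "1", "1"))
})

test_that("extreme alpha drives the defer rate to its limits", {
  tab <- mixed_cohort(150, seed = 1)
  ens <- train_ensemble(tab, tiny_base_spec(), k = 3, master_seed = 1)
  s2 <- build_stage2_features(predict(ens, tab))
  low <- triage(train_defer_network(s2, tiny_defer_spec(alpha = 0.05)), s2)
  expect_gte(mean(low$decision == "defer"), 0.99)
  high <- triage(train_defer_network(s2, tiny_defer_spec(alpha = 50)), s2)
  expect_lte(mean(high$decision == "defer"), 0.01)
})

test_that("triage output is a well-formed per-patient decision table", {
  tab <- mixed_cohort(80, seed = 2)
  ens <- train_ensemble(tab, tiny_base_spec(), k = 3, master_seed = 1)
  s2 <- build_stage2_features(predict(ens, tab))
  dm <- train_defer_network(s2, tiny_defer_spec(alpha = 1.2))
  tri <- triage(dm, s2)
  expect_identical(tri$sample_id, tab$sample_id)
  expect_true(all(tri$decision %in% c("0", "1", "defer")))
  scores <- as.matrix(tri[c("score_class0", "score_class1", "score_defer")])
  expect_equal(rowSums(scores), rep(1, nrow(tri)))
  expect_equal(unique(tri$algorithm), "ldu")
  expect_equal(unique(tri$param_value), 1.2)
  # decisions follow the scores
  expect_equal(tri$decision, deferral:::decide_from_scores(scores))
  # determinism
  tri2 <- triage(train_defer_network(s2, tiny_defer_spec(alpha = 1.2)), s2)
  expect_identical(tri, tri2)
})

test_that("defer training validates its inputs", {
  tab <- mixed_cohort(40, seed = 3)
  ens <- train_ensemble(tab, tiny_base_spec(), k = 2, master_seed = 1)
  s2 <- build_stage2_features(predict(ens, tab))
  expect_error(train_defer_network(dplyr::select(s2, -label),
                                   tiny_defer_spec()), "label")
  expect_error(train_defer_network(s2, tiny_defer_spec(),
                                   labels = rep(1L, nrow(s2))), "both classes")
  expect_error(train_defer_network(s2, tiny_defer_spec(),
                                   labels = c(0L, 1L)), "length")
  expect_error(defer_model_spec(alpha = -1), "alpha")
})

test_that("retraining across seeds moves the defer rate only modestly", {
  parts <- split_cohort(mixed_cohort(300, seed = 4), 0.7, seed = 4)
  ens <- train_ensemble(parts$train, std_base_spec(), k = 5, master_seed = 1)
  s2_train <- build_stage2_features(predict(ens, parts$train))
  s2_test <- build_stage2_features(predict(ens, parts$test))
  rates <- vapply(1:5, function(s) {
    dm <- train_defer_network(s2_train, std_defer_spec(alpha = 1.4, seed = s))
    mean(triage(dm, s2_test)$decision == "defer")
  }, numeric(1))
  expect_lt(stats::sd(rates), 0.1)
})
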