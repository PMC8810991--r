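test_that("entropy-threshold triage defers strictly above the threshold", {
  # ensemble-entropy variant with continuously chosen entropies
  pr <- tibble::tibble(p_0 = c(1.0, 0.9, 0.5), p_1 = c(1.0, 0.9, 0.5))
  u <- ensemble_entropy(deferral:::prob_matrix(pr)) # 0, 0.21, 1.39
  tri <- triage_dt(pr, threshold = 0.5, entropy = "ensemble")
  expect_equal(tri$decision == "defer", u > 0.5)
  expect_equal(sum(tri$decision == "defer"), 1)

  # diagnostic variant: unanimous rows can never be deferred
  pr2 <- tibble::tibble(p_0 = c(0.9, 0.9, 0.2), p_1 = c(0.8, 0.4, 0.1))
  tri0 <- triage_dt(pr2, threshold = 0)
  expect_equal(tri0$decision == "defer",
               diagnostic_entropy(deferral:::prob_matrix(pr2)) > 0)
  # non-deferred decisions are the majority vote
  kept <- tri0$decision != "defer"
  expect_equal(as.integer(tri0$decision[kept]),
               majority_diagnosis(pr2)[kept])
  expect_error(triage_dt(pr2, threshold = -0.1), "threshold")
})

test_that("an all-unanimous ensemble never defers at any threshold", {
  pr <- tibble::tibble(p_0 = c(0.99, 0.01, 0.9), p_1 = c(0.8, 0.3, 0.51))
  for (thr in c(0, 0.1, 0.5, 1)) {
    expect_equal(sum(triage_dt(pr, thr)$decision == "defer"), 0)
  }
})

test_that("the defer rate of entropy triage is a step function matched by brute force", {
  withr::with_seed(9, {
    p <- matrix(runif(200 * 7), 200, 7)
    pr <- tibble::as_tibble(p, .name_repair = ~paste0("p_", 0:6))
    u <- diagnostic_entropy(p)
    thresholds <- sort(unique(c(0, u, 0.05, 0.3, 0.9)))
    rates <- vapply(thresholds, function(t) {
      mean(triage_dt(pr, t)$decision == "defer")
    }, numeric(1))
    # brute-force filter oracle
    expect_equal(rates, vapply(thresholds, function(t) mean(u > t), numeric(1)))
    # non-increasing in the threshold; ceiling at the nonzero-entropy mass
    expect_true(all(diff(rates) <= 0))
    expect_equal(max(rates), mean(u > 0))
  })
})

test_that("LD at extreme alpha collapses to classify-everything or defer-everything", {
  tab <- simulate_cohort(n_per_class = 120, easy_fraction = 1,
                         ambiguous_fraction = 0,
                         overconfident_wrong_fraction = 0, seed = 1)
  parts <- split_cohort(tab, 0.7, seed = 1)
  ld_hi <- train_ld(parts$train, tiny_base_spec(), alpha = 100, seed = 1)
  tri_hi <- triage(ld_hi, parts$test)
  expect_lte(mean(tri_hi$decision == "defer"), 0.01)
  kept <- tri_hi$decision != "defer"
  expect_gte(mean(as.integer(tri_hi$decision[kept]) ==
                    parts$test$label[kept]), 0.95)

  ld_lo <- train_ld(parts$train, tiny_base_spec(), alpha = 0.01, seed = 1)
  expect_gte(mean(triage(ld_lo, parts$test)$decision == "defer"), 0.99)
  expect_equal(unique(triage(ld_lo, parts$test)$algorithm), "ld")
})

test_that("deferral helps LD beyond the plain classifier on mixed-difficulty data", {
  parts <- split_cohort(mixed_cohort(300, seed = 5), 0.7, seed = 5)
  dn <- train_diagnostic_network(parts$train, std_base_spec(), seed = 1)
  f1_plain <- deferral:::f1_positive(parts$test$label,
                                     predict(dn, parts$test)$pred)
  ld <- train_ld(parts$train, std_base_spec(), alpha = 1.3, seed = 1)
  m <- compute_metrics(triage(ld, parts$test), parts$test$label)
  expect_gte(m$f1, f1_plain)
  expect_gt(m$defer_rate, 0)
})

test_that("entropy triage cannot touch unanimously wrong patients but LDU can defer them", {
  parts <- split_cohort(ocw_cohort(1000, seed = 8), 0.7, seed = 8)
  ens <- train_ensemble(parts$train, std_base_spec(), k = 10, master_seed = 1)
  pr_test <- predict(ens, parts$test)
  u_d <- diagnostic_entropy(deferral:::prob_matrix(pr_test))
  bad <- parts$test$subgroup == "overconfident_wrong"
  unan_bad <- bad & u_d == 0
  # DT leaves every unanimously voted ocw patient in the automated arm
  for (thr in c(0, 0.2, 0.5)) {
    tri <- triage_dt(pr_test, thr)
    expect_true(all(tri$decision[unan_bad] != "defer"))
  }
  # LDU, at a matched overall defer rate, routes some of them to the expert
  s2_train <- stage2_features_crossfit(parts$train, std_base_spec(), k = 10,
                                       master_seed = 1)
  s2_test <- build_stage2_features(pr_test)
  dm <- train_defer_network(s2_train, std_defer_spec(alpha = 1.1, seed = 1))
  tri_ldu <- triage(dm, s2_test)
  expect_gt(mean(tri_ldu$decision[unan_bad] == "defer"), 0)
})
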