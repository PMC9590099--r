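test_that("kernel density matches hand evaluation and the radius convention", {
  # two electrodes: their separation is the radius, so both kernels vanish
  two <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(kernel_density(two), c(0, 0))

  # collinear electrodes at 0, 1, 2 mm; radius = 2
  line <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  d <- kernel_density(line)
  k1 <- (3 / pi) * (1 - (1 / 2)^2)^2 / 4   # one neighbour at 1 mm
  expect_equal(d, c(k1, 2 * k1, k1))
  expect_equal(round(d, 4), c(0.1343, 0.2686, 0.1343))

  expect_error(kernel_density(matrix(0, 1, 3)), "< 2")
})

test_that("kernel density equals the direct-summation oracle on random layouts", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:25, 1)
    coords <- matrix(rnorm(n * 3, 0, 20), n, 3)
    expect_equal(kernel_density(coords), kernel_density_oracle(coords),
                 tolerance = 1e-12)
    r <- runif(1, 5, 30)  # user-supplied radius activates the truncation
    expect_equal(kernel_density(coords, radius = r),
                 kernel_density_oracle(coords, radius = r), tolerance = 1e-12)
  }
})

test_that("kernel density is invariant under rigid-body transformations", {
  set.seed(103)
  coords <- matrix(rnorm(30, 0, 15), 10, 3)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  moved <- coords %*% t(R) + matrix(c(5, -3, 12), 10, 3, byrow = TRUE)
  expect_equal(kernel_density(coords), kernel_density(moved), tolerance = 1e-10)
})

test_that("ROC integration equals the rank formulation, including ties", {
  set.seed(107)
  for (rep in 1:50) {
    n <- sample(8:40, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    expect_equal(roc_curve(scores, labels)$auc, auc_rank(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(109)
  for (rep in 1:10) {
    labels <- c(rep(TRUE, 15), rep(FALSE, 25))
    scores <- rnorm(40) + labels
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                           quiet = TRUE))))
    expect_equal(roc_curve(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("AUC-difference p-value implements the counting formula", {
  expect_equal(auc_difference_pvalue(rep(-0.01, 1000)), 2 * 1 / 1001)
  expect_equal(auc_difference_pvalue(c(-1, -2, -3, 4)), 2 * 2 / 5)
  expect_equal(auc_difference_pvalue(rep(0, 50)), 1)  # ties count on both sides
  expect_equal(auc_difference_pvalue(c(1, 1, 1)), 2 * 1 / 4)
  expect_error(auc_difference_pvalue(numeric(0)), "at least one")
})

test_that("model predictor sets match their definitions", {
  co <- small_test_cohort(n_patients = 8, seed = 113)
  an <- analyze_cohort(co)
  f <- cohort_electrode_features(co, an)
  fit_null <- fit_soz_classifier(f, "null")
  expect_setequal(attr(terms(fit_null), "term.labels"),
                  c("coarse_anatomy", "density_z"))
  fit_all <- fit_soz_classifier(f, "all")
  expect_setequal(attr(terms(fit_all), "term.labels"),
                  c("coarse_anatomy", "density_z", "conn_z", "spike_z"))
  single <- f[f$soz_flag == FALSE, ]
  expect_error(fit_soz_classifier(single, "null"), "single-class")
})

test_that("split evaluation is seeded, shares splits across models, and matches per-split AUC oracles", {
  co <- small_test_cohort(n_patients = 10, seed = 127)
  an <- analyze_cohort(co)
  f <- cohort_electrode_features(co, an)
  ev1 <- evaluate_splits(f, n_splits = 10, seed = 5)
  ev2 <- evaluate_splits(f, n_splits = 10, seed = 5)
  expect_identical(ev1$auc, ev2$auc)
  expect_true(all(ev1$auc >= 0 & ev1$auc <= 1))
  expect_true(all(ev1$p_values >= 2 / 11, na.rm = TRUE))

  # oracle: replay the same patient splits by seed and recompute AUC by rank
  set.seed(5)
  patients <- unique(f$patient_id)
  n_train <- round(2 / 3 * length(patients))
  for (s in 1:10) {
    repeat {
      tr <- sample(patients, n_train)
      train <- f[f$patient_id %in% tr, ]
      test <- f[!f$patient_id %in% tr, ]
      if (length(unique(train$soz_flag)) == 2 &&
          length(unique(test$soz_flag)) == 2) break
    }
    fit <- suppressWarnings(glm(soz_flag ~ coarse_anatomy + density_z,
                                binomial(), data = train))
    prob <- suppressWarnings(predict(fit, test, type = "response"))
    expect_equal(unname(ev1$auc[s, "null"]), unname(auc_rank(prob, test$soz_flag)),
                 tolerance = 1e-12)
  }
})

test_that("random scores give chance AUC and identical models give p = 1", {
  co <- small_test_cohort(n_patients = 12, seed = 131)
  an <- analyze_cohort(co)
  f <- cohort_electrode_features(co, an)
  set.seed(17)
  f$noise1 <- rnorm(nrow(f))
  aucs <- replicate(200, {
    test <- f[f$patient_id %in% sample(unique(f$patient_id), 4), ]
    auc_rank(rnorm(nrow(test)), test$soz_flag)
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)

  ev <- evaluate_splits(f, model_ids = c("null", "null"), n_splits = 20, seed = 7)
  expect_equal(unname(ev$auc[, 1]), unname(ev$auc[, 2]))
  expect_equal(ev$p_values[1, 2], 1)
})

test_that("stratified evaluation skips tiny strata and runs the rest", {
  co <- generate_cohort(cohort_spec(n_patients = 12, duration_s = 30,
                                    stereo_fraction = 1, seed = 137))
  an <- analyze_cohort(co)
  f <- cohort_electrode_features(co, an)
  out <- stratified_evaluation(f, n_splits = 5, seed = 3)
  expect_named(out, "stereo")
  expect_s3_class(out$stereo, "split_evaluation")
})

test_that("density bias makes the stereo null model outperform the grid stratum", {
  co <- generate_cohort(cohort_spec(n_patients = 24, duration_s = 30,
                                    stereo_fraction = 0.5, seed = 139))
  an <- analyze_cohort(co)
  f <- cohort_electrode_features(co, an)
  out <- stratified_evaluation(f, model_ids = "null", n_splits = 50, seed = 11)
  expect_gt(out$stereo$mean_auc["null"], out$`grid-strip-depth`$mean_auc["null"])
})

test_that("mixed-effects association recovers a null and a negative conn effect", {
  co0 <- generate_cohort(cohort_spec(n_patients = 16, duration_s = 30,
                                     soz_conn_reduction = 0, spike_rate_ratio = 1,
                                     stereo_fraction = 0, seed = 149))
  an0 <- analyze_cohort(co0)
  f0 <- cohort_electrode_features(co0, an0)
  me0 <- mixed_effects_association(f0, n_boot = 60, seed = 2)
  expect_gt(me0$ci[2], 1)  # CI covers 1 under the null
  expect_lt(me0$ci[1], 1)

  co1 <- generate_cohort(cohort_spec(n_patients = 16, duration_s = 30,
                                     soz_conn_reduction = 0.5, seed = 151))
  an1 <- analyze_cohort(co1)
  f1 <- cohort_electrode_features(co1, an1)
  me1 <- mixed_effects_association(f1, n_boot = 60, seed = 2)
  expect_lt(me1$or, 1)
  expect_lt(me1$ci[2], 1)
})

test_that("the estimator is invariant to balanced duplication of every patient", {
  co <- small_test_cohort(n_patients = 8, seed = 157)
  an <- analyze_cohort(co)
  f <- cohort_electrode_features(co, an)
  f2 <- f
  f2$patient_id <- paste0(f2$patient_id, "dup")
  doubled <- rbind(f, f2)
  fit1 <- mixed_effects_association(f, n_boot = 2, seed = 1)
  fit2 <- mixed_effects_association(doubled, n_boot = 2, seed = 1)
  expect_equal(fit1$coef, fit2$coef, tolerance = 1e-3)
})
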