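# Dataset assembly, regressors, subject-wise CV and importances.

# A quick synthetic dataset with a known monotone HRDN-CRM relationship;
# bypasses waveform synthesis for speed.
toy_dataset <- function(n_subjects = 8, n_per = 120, noise = 0,
                        feature_set = "hrdn_only", seed = 10) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(i) {
    crm <- runif(n_per, 0, 100)
    hrdn <- 0.12 + 0.0009 * crm + rnorm(n_per, 0, noise)
    data.frame(
      subject_id = sprintf("S%02d", i),
      session_id = sprintf("S%02d_1", i),
      phase = sample(c("baseline", "depressurization", "repressurization"),
                     n_per, replace = TRUE),
      ramp_rate = 0, window_time = seq_len(n_per) * 2,
      PPI = 0.9 + rnorm(n_per, 0, 0.02), HRV = 0.02, HRDN = hrdn,
      SBP = 120 + rnorm(n_per), DBP = 80, PP = 40 + rnorm(n_per),
      PA = 90, IPA = 1.5, SI = 0.55,
      reference_crm = crm, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "feature_names") <- crmwave:::FEATURE_SETS[[feature_set]]
  class(out) <- c("crm_dataset", "data.frame")
  out
}

test_that("dataset assembly selects phases and feature columns", {
  sessions <- planted_cohort()
  ds <- assemble_dataset(sessions, "vital_signs", "depressurization", "none")
  expect_true(all(ds$phase == "depressurization"))
  expect_true(all(ds$ramp_rate < 0))
  expect_identical(attr(ds, "feature_names"),
                   c("PPI", "SBP", "HRV", "SI", "DBP"))
  ds1 <- assemble_dataset(sessions, "hrdn_only", "full", "none")
  expect_identical(attr(ds1, "feature_names"), "HRDN")
  expect_true(all(ds1$reference_crm >= 0 & ds1$reference_crm <= 100))
  expect_error(assemble_dataset(sessions, "bogus"), "vital_signs")
})

test_that("OLS recovers an exactly linear target", {
  ds <- toy_dataset(noise = 0)
  # reference_crm = (HRDN - 0.12) / 0.0009 exactly
  fit <- fit_model(ds, model_config("ols"))
  co <- coef(fit$engine)
  names(co) <- gsub("`", "", names(co))
  expect_equal(unname(co["HRDN"]), 1 / 0.0009, tolerance = 1e-6)
  expect_equal(unname(co["(Intercept)"]), -0.12 / 0.0009, tolerance = 1e-4)
})

test_that("a noiseless monotone feature is learned almost perfectly", {
  ds <- toy_dataset(noise = 0)
  fit <- fit_model(ds, model_config("gb_tree"))
  est <- predict_crm(fit, ds)
  m <- regression_metrics(est, ds$reference_crm)
  expect_gt(m$r2, 0.99)
  expect_true(all(est >= 0 & est <= 100))
})

test_that("fits are deterministic given the seed", {
  ds <- toy_dataset(noise = 0.005)
  f1 <- fit_model(ds, model_config("gb_tree", seed = 3))
  f2 <- fit_model(ds, model_config("gb_tree", seed = 3))
  expect_identical(predict_crm(f1, ds), predict_crm(f2, ds))
})

test_that("constant training targets warn and predict the constant", {
  ds <- toy_dataset(noise = 0.01)
  ds$reference_crm <- 55
  expect_warning(fit <- fit_model(ds, model_config("gb_tree")), "constant")
  expect_true(all(predict_crm(fit, ds[1:10, ]) == 55))
})

test_that("subject-wise folds are balanced, disjoint and leak-free", {
  ds <- toy_dataset(n_subjects = 13, n_per = 30, noise = 0.01)
  cv <- subjectwise_cv(ds, k = 5, model_config("gb_tree"), seed = 2)
  sizes <- sort(vapply(cv$folds, function(f) length(f$test_subjects), 1L))
  expect_equal(sizes, c(2L, 2L, 3L, 3L, 3L))
  all_subj <- sort(unlist(lapply(cv$folds, function(f) f$test_subjects)))
  expect_equal(all_subj, sort(unique(ds$subject_id)))   # union = cohort
  # a fold's predictions must not depend on its own held-out labels
  ds2 <- ds
  held <- ds2$subject_id %in% cv$folds[[2]]$test_subjects
  ds2$reference_crm[held] <- rev(ds2$reference_crm[held])
  cv2 <- subjectwise_cv(ds2, k = 5, model_config("gb_tree"), seed = 2)
  expect_equal(cv$predictions$estimate[cv$predictions$fold == 2],
               cv2$predictions$estimate[cv2$predictions$fold == 2])
  expect_error(subjectwise_cv(toy_dataset(n_subjects = 3), k = 5),
               "subjects")
})

test_that("Gini importances are a probability vector and spot the signal", {
  ds <- toy_dataset(noise = 0.002, feature_set = "all")
  fit <- fit_model(ds, model_config("gb_tree"))
  imp <- gini_importance(fit)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "HRDN")
  one <- fit_model(toy_dataset(noise = 0.002), model_config("gb_tree"))
  expect_equal(unname(gini_importance(one)), 1)
  ols <- fit_model(ds, model_config("ols"))
  expect_error(gini_importance(ols), "gb_tree")
})
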