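test_that("metrics implement the observed-vs-predicted conventions", {
  obs <- c(2, 4, 6, 9)
  expect_equal(metrics(obs, obs)$r_squared, 1)
  expect_equal(metrics(obs, obs)$rmse, 0)
  shifted <- metrics(obs, obs + 3)
  expect_equal(shifted$r_squared, 1)       # correlation ignores offset
  expect_equal(shifted$rmse, 3)            # RMSE does not
  expect_lt(shifted$r_squared_sse, 1)
  # frozen four-point example, checked against direct formula evaluation
  m <- metrics(c(10, 14, 9, 17), c(11.2, 13.1, 10.4, 15.9))
  expect_equal(m$r_squared, 0.977024471862, tolerance = 1e-10)
  expect_equal(m$rmse, 1.164044672682, tolerance = 1e-10)
  expect_equal(m$r_squared_sse, 0.867804878049, tolerance = 1e-10)
  expect_false(metrics(rep(1, 4), c(1, 2, 3, 4))$r_squared_defined)
  expect_error(metrics(1, 1), "length")
  expect_error(metrics(c(1, NA), c(1, 2)), "finite")
})

test_that("leave-one-out produces one prediction per leaf and is deterministic", {
  study <- simulate_study(tiny_config())
  data <- study_dataset(study, "true")
  res <- loo_cv(data, "vcmax", cv_folds = 5, max_components = 5)
  expect_equal(nrow(res$predictions), nrow(study))
  expect_equal(res$per_run$n_train, rep(nrow(study) - 1, nrow(study)))
  res2 <- loo_cv(data, "vcmax", cv_folds = 5, max_components = 5)
  expect_identical(res$predictions$predicted, res2$predictions$predicted)
})

test_that("noise-free spectra give near-perfect held-out prediction", {
  study <- simulate_study(noise_free_config(n_trees = 6, n_dates = 5,
                                            n_replicate_spectra = 2,
                                            jmax_psi_coupling = 0,
                                            seed = 31))
  data <- study_dataset(study, "true")
  res <- loo_cv(data, "vcmax", cv_folds = 5, max_components = 6)
  expect_gt(res$metrics$r_squared, 0.99)
  sp <- repeated_split(data, "vcmax", n_reps = 5, seed = 2, cv_folds = 5,
                       max_components = 6)
  expect_true(all(sp$per_run$r_squared > 0.98))
})

test_that("repeated splits are bit-identical under a fixed seed", {
  study <- simulate_study(tiny_config())
  data <- study_dataset(study, "true")
  a <- repeated_split(data, "vcmax", n_reps = 6, seed = 9, cv_folds = 5,
                      max_components = 4)
  b <- repeated_split(data, "vcmax", n_reps = 6, seed = 9, cv_folds = 5,
                      max_components = 4)
  expect_identical(a$per_run, b$per_run)
  expect_equal(a$summary$mean_r_squared, mean(a$per_run$r_squared))
  expect_equal(a$per_run$n_train + a$per_run$n_test,
               rep(nrow(study), nrow(a$per_run)))
  c <- repeated_split(data, "vcmax", n_reps = 6, seed = 10, cv_folds = 5,
                      max_components = 4)
  expect_false(identical(a$per_run$r_squared, c$per_run$r_squared))
})

test_that("mean R2 improves and spreads shrink as the training fraction grows", {
  data <- default_study_dataset()
  fractions <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  mu <- sdv <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    r <- repeated_split(data, "vcmax", train_fraction = fractions[i],
                        n_reps = 40, seed = 33, cv_folds = 5,
                        max_components = 8)
    mu[i] <- r$summary$mean_r_squared
    sdv[i] <- r$summary$sd_r_squared
  }
  # monotone trends up to sampling noise: at most one material adjacent
  # violation (mean worsening by > 0.01, sd growing by > 0.005)
  expect_lte(sum(diff(mu) < -0.01), 1)
  expect_lte(sum(diff(sdv) > 0.005), 1)
  expect_gte(mu[5], mu[1])
})

test_that("the stress holdout selects the maximal-variance date pair", {
  # toy layout: three dates, middle pair has the largest pooled variance
  psi <- c(-0.30, -0.31, -0.29,   # date 1
           -0.50, -0.90, -0.20,   # date 2 (high spread)
           -0.50, -0.50, -0.50)   # date 3 (tight, near date 2 mean)
  dp <- photospec:::date_pair_variances(rep(1:3, each = 3), psi)
  expect_equal(unname(dp$pairs[which.max(dp$variance), ]), c(1, 2))
  expect_error(photospec:::date_pair_variances(rep(1:2, 3), rnorm(6)),
               "3 distinct dates")
})

test_that("the stress holdout brackets the simulated stress peak", {
  data <- default_study_dataset()
  res <- stress_holdout(data, "vcmax", cv_folds = 5, max_components = 8)
  cfg <- synth_config()
  expect_true(cfg$stress_peak_date %in% res$held_out_dates)
  expect_equal(res$per_run$n_test, sum(data$date_index %in%
                                         res$held_out_dates))
})

test_that("training-fold statistics are untouched by held-out spectra (no leakage)", {
  study <- simulate_study(tiny_config())
  data <- study_dataset(study, "true")
  res1 <- stress_holdout(data, "vcmax", cv_folds = 5, max_components = 4)
  # corrupt the held-out leaves' spectra with a trait-revealing artefact
  data2 <- data
  te <- which(data2$date_index %in% res1$held_out_dates)
  for (i in te) {
    data2$spectra$values[i, 200:210] <-
      data2$traits$vcmax[i] / 100
  }
  res2 <- stress_holdout(data2, "vcmax", cv_folds = 5, max_components = 4)
  # identical training-side results: same fold RMSEP, component count and
  # regression vector
  expect_identical(res2$model$cv_rmsep, res1$model$cv_rmsep)
  expect_identical(res2$model$ncomp, res1$model$ncomp)
  expect_identical(res2$model$regression_vector,
                   res1$model$regression_vector)
  # but the predictions on the corrupted rows do change
  expect_false(identical(res2$predictions$predicted,
                         res1$predictions$predicted))
})
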