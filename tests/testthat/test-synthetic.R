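test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(synth_config(n_trees = 0), "n_trees")
  expect_error(synth_config(vcmax_end_mean = 120), "vcmax_end_mean")
  expect_error(synth_config(jmax_ratio = -1), "jmax_ratio")
  expect_error(synth_config(psi_sd = -0.1), "psi_sd")
  expect_error(synth_config(stress_peak_date = 9, n_dates = 7),
               "stress_peak_date")
  expect_error(synth_config(psi_base = 0.5), "psi_base")
})

test_that("the whole study is reproducible from its seed", {
  s1 <- simulate_study(tiny_config())
  s2 <- simulate_study(tiny_config())
  expect_identical(s1$psi_pd, s2$psi_pd)
  expect_identical(s1$true_vcmax, s2$true_vcmax)
  expect_identical(s1$aci[[5]]$a, s2$aci[[5]]$a)
  expect_identical(s1$spectra[[3]][[2]]$reflectance,
                   s2$spectra[[3]][[2]]$reflectance)
  s3 <- simulate_study(tiny_config(seed = 999))
  expect_false(identical(s1$psi_pd, s3$psi_pd))
})

test_that("noise-free trajectories are identical across trees with exact endpoints", {
  cfg <- noise_free_config()
  traits <- simulate_traits(cfg)
  for (d in unique(traits$date_index)) {
    v <- traits$true_vcmax[traits$date_index == d]
    expect_equal(v, rep(v[1], length(v)))
  }
  expect_equal(traits$true_vcmax[traits$date_index == 1],
               rep(cfg$vcmax_start_mean, cfg$n_trees))
  expect_equal(traits$true_vcmax[traits$date_index == cfg$n_dates],
               rep(cfg$vcmax_end_mean, cfg$n_trees))
  # decline is monotone in expectation
  means <- tapply(traits$true_vcmax, traits$date_index, mean)
  expect_true(all(diff(means) < 1e-9))
})

test_that("the population Jmax/Vcmax ratio honours the configured coupling", {
  traits <- simulate_traits(synth_config(seed = 2))
  ratio <- mean(traits$true_jmax) / mean(traits$true_vcmax)
  cfg <- synth_config()
  expect_lt(abs(ratio - cfg$jmax_ratio) / cfg$jmax_ratio, 0.05)
})

test_that("water potential is non-positive and its variance peaks at the stress date", {
  cfg <- synth_config(seed = 3)
  traits <- simulate_traits(cfg)
  expect_true(all(traits$psi_pd <= 0))
  v <- tapply(traits$psi_pd, traits$date_index, var)
  expect_equal(unname(which.max(v)), cfg$stress_peak_date)
  m <- tapply(traits$psi_pd, traits$date_index, mean)
  expect_equal(unname(which.min(m)), cfg$stress_peak_date)
})

test_that("simulated curves follow the 13-step protocol and the forward model", {
  cfg <- noise_free_config()
  curve <- simulate_aci(75.7, 150.1, cfg)
  expect_equal(curve$ci,
               c(400, 300, 200, 100, 50, 0, 400, 400, 600, 800, 1200,
                 1600, 2000))
  expect_equal(curve$a,
               fvcb_assimilation(curve$ci, 75.7, 150.1, cfg$rd_true))
  expect_gt(curve$a[curve$ci == 2000][1], curve$a[curve$ci == 50])
  expect_error(simulate_aci(-5, 150, cfg), "positive")
})

test_that("replicate spectra are deterministic given the RNG state and noise-free spectra are exact", {
  cfg <- noise_free_config()
  s1 <- simulate_spectrum(90, -0.5, cfg)
  s2 <- simulate_spectrum(90, -0.5, cfg)
  expect_identical(s1$reflectance, s2$reflectance)
  expect_equal(s1$wavelengths, 350:2500)
  expect_true(all(s1$reflectance >= 0 & s1$reflectance <= 1))
})

test_that("chlorophyll absorption deepens and the red-edge ratio rises with capacity", {
  cfg <- noise_free_config()
  vgrid <- seq(45, 135, by = 5)
  r680 <- sr1 <- numeric(length(vgrid))
  for (i in seq_along(vgrid)) {
    s <- simulate_spectrum(vgrid[i], -0.5, cfg)
    r680[i] <- s$reflectance[s$wavelengths == 680]
    sr1[i] <- compute_index(s, "SR1")
  }
  expect_true(all(diff(r680) < 0))   # darker red trough with higher Vcmax
  expect_true(all(diff(sr1) > 0))    # SR1 strictly increasing
})

test_that("water status controls the SWIR wells", {
  cfg <- noise_free_config()
  wet <- simulate_spectrum(90, -0.3, cfg)
  dry <- simulate_spectrum(90, -1.2, cfg)
  at <- function(s, nm) s$reflectance[s$wavelengths == nm]
  # wetter leaf absorbs more at the 1450/1940 nm water bands
  expect_lt(at(wet, 1450), at(dry, 1450))
  expect_lt(at(wet, 1940), at(dry, 1940))
})

test_that("noise-free spectra separate distinct trait values (injectivity on a grid)", {
  cfg <- noise_free_config()
  vgrid <- seq(50, 130, by = 10)
  specs <- vapply(vgrid, function(v) {
    simulate_spectrum(v, -0.5, cfg)$reflectance
  }, numeric(2151))
  d <- as.matrix(dist(t(specs)))
  diag(d) <- Inf
  expect_gt(min(d), 1e-3)
})

test_that("studies round-trip through the plain-text export", {
  study <- simulate_study(synth_config(n_trees = 2, n_dates = 3,
                                       stress_peak_date = 2,
                                       n_replicate_spectra = 2, seed = 17))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  back <- read_study(dir)
  expect_equal(back$true_vcmax, study$true_vcmax, tolerance = 1e-12)
  expect_equal(back$aci[[4]]$a, study$aci[[4]]$a, tolerance = 1e-12)
  expect_equal(back$spectra[[2]][[2]]$reflectance,
               study$spectra[[2]][[2]]$reflectance, tolerance = 1e-12)
})
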