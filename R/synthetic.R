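#' Configuration of a synthetic dry-down study
#'
#' Defines the design constants of a simulated mid-summer study: a small
#' population of trees sampled weekly while photosynthetic capacity declines
#' roughly two-fold and a water-stress episode peaks mid-study. Defaults
#' mirror that design: 12 trees, 7 dates a week apart, mean Vcmax falling
#' from 110 to 55 umol m-2 s-1, Jmax proportional to Vcmax with ratio 1.98,
#' nine replicate spectra per leaf, and predawn water potential dipping from
#' a well-watered baseline of -0.3 MPa by up to 0.9 MPa around the stress
#' peak (date 4 of 7).
#'
#' @param n_trees Number of trees.
#' @param n_dates Number of sampling dates.
#' @param date_spacing_days Days between sampling dates.
#' @param vcmax_start_mean,vcmax_end_mean Population-mean Vcmax at the first
#'   and last date (umol m-2 s-1); the end mean must be lower (dry-down).
#' @param jmax_ratio Jmax/Vcmax ratio.
#' @param jmax_cv Coefficient of variation of the multiplicative noise on
#'   the Jmax-Vcmax coupling.
#' @param jmax_psi_coupling Fractional change of Jmax per MPa of predawn
#'   water potential relative to the study-mean stress level (so the
#'   population Jmax/Vcmax ratio is unbiased); the physiological source of
#'   the stress/SWIR confound.
#' @param tree_sd Between-tree sd of Vcmax (umol m-2 s-1).
#' @param psi_base Unstressed predawn water potential (MPa, <= 0).
#' @param psi_stress_depth Depth of the stress dip in water potential (MPa).
#' @param stress_peak_date Date index (1-based) at which stress peaks.
#' @param psi_sd Scale of water-potential noise (MPa); realised noise is
#'   larger near the stress peak so population variance peaks there.
#' @param stress_dip_per_mpa Extra Vcmax decline per MPa of water potential
#'   below `psi_base` (umol m-2 s-1 per MPa).
#' @param rd_true Day respiration used when forward-simulating gas exchange
#'   (umol m-2 s-1).
#' @param aci_noise_sd Additive noise on simulated assimilation
#'   (umol m-2 s-1).
#' @param spectral_noise_sd Additive noise on each replicate spectrum
#'   (reflectance units).
#' @param n_replicate_spectra Replicate spectra per leaf.
#' @param water_confound If `TRUE` (the default study condition), water
#'   status also blue-shifts the red edge, entangling the chlorophyll
#'   region with stress.
#' @param seed Integer seed making the whole study reproducible; `NULL`
#'   uses the current RNG state.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_trees = 12, n_dates = 7, date_spacing_days = 7,
                         vcmax_start_mean = 110, vcmax_end_mean = 55,
                         jmax_ratio = 1.98, jmax_cv = 0.05,
                         jmax_psi_coupling = 0.3,
                         tree_sd = 8, psi_base = -0.3,
                         psi_stress_depth = 0.9, stress_peak_date = 4,
                         psi_sd = 0.12, stress_dip_per_mpa = 15,
                         rd_true = 1, aci_noise_sd = 0.5,
                         spectral_noise_sd = 0.005,
                         n_replicate_spectra = 9, water_confound = TRUE,
                         seed = NULL) {
  cfg <- as.list(environment())
  fail <- function(msg) stop("invalid synth_config: ", msg, call. = FALSE)
  counts <- c(n_trees = n_trees, n_dates = n_dates,
              n_replicate_spectra = n_replicate_spectra,
              date_spacing_days = date_spacing_days)
  if (any(counts < 1)) {
    fail(sprintf("%s must be >= 1",
                 paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (!(vcmax_end_mean < vcmax_start_mean)) {
    fail("vcmax_end_mean must be below vcmax_start_mean (dry-down decline)")
  }
  if (vcmax_end_mean <= 0) fail("vcmax_end_mean must be positive")
  if (jmax_ratio <= 0) fail("jmax_ratio must be positive")
  sds <- c(tree_sd = tree_sd, psi_sd = psi_sd, jmax_cv = jmax_cv,
           aci_noise_sd = aci_noise_sd, spectral_noise_sd = spectral_noise_sd)
  if (any(sds < 0)) {
    fail(sprintf("%s must be >= 0",
                 paste(names(sds)[sds < 0], collapse = ", ")))
  }
  if (psi_base > 0) fail("psi_base must be <= 0 (a water potential)")
  if (psi_stress_depth < 0) fail("psi_stress_depth must be >= 0")
  if (stress_peak_date < 1 || stress_peak_date > n_dates) {
    fail("stress_peak_date must lie in 1..n_dates")
  }
  if (rd_true < 0) fail("rd_true must be >= 0")
  class(cfg) <- "synth_config"
  cfg
}

# Gaussian-in-time stress profile (sigma = 1 date), truncated at 2 sigma
# and renormalised to [0, 1]: dates two or more sampling intervals away
# from the peak carry exactly zero stress.
stress_profile <- function(date_index, peak) {
  g <- exp(-0.5 * (date_index - peak)^2)
  pmax(0, g - exp(-2)) / (1 - exp(-2))
}

# Logistic decline rescaled so the endpoints hit the start/end means
# exactly in expectation.
trait_trajectory <- function(date_index, n_dates, start_mean, end_mean,
                             steepness = 1.1) {
  if (n_dates == 1) return(rep(start_mean, length(date_index)))
  t <- date_index - 1
  tmax <- n_dates - 1
  l <- stats::plogis(-steepness * (t - tmax / 2))
  l0 <- stats::plogis(steepness * tmax / 2)
  l1 <- stats::plogis(-steepness * tmax / 2)
  end_mean + (start_mean - end_mean) * (l - l1) / (l0 - l1)
}

#' Simulate per-tree trait trajectories and water potential
#'
#' Draws the trees x dates layout of the study: each tree's expected Vcmax
#' follows a logistic decline from the start to the end population mean,
#' offset by a random tree effect, with an extra stress dip proportional to
#' how far predawn water potential falls below its unstressed baseline.
#' Water potential dips along a Gaussian-in-time profile centred on
#' `stress_peak_date`, with noise that grows with the stress profile so the
#' population variance is largest at the peak. Jmax is coupled to Vcmax
#' through `jmax_ratio` with multiplicative noise (`jmax_cv`) and a
#' water-potential-dependent term (`jmax_psi_coupling`).
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per (tree, date): `tree_id`, `date_index`,
#'   `day` (days since the first date), `psi_pd` (MPa), `true_vcmax` and
#'   `true_jmax` (umol m-2 s-1).
#' @export
simulate_traits <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nt <- config$n_trees
  nd <- config$n_dates
  grid <- expand.grid(tree = seq_len(nt), date_index = seq_len(nd))
  s <- stress_profile(grid$date_index, config$stress_peak_date)
  tree_effect <- stats::rnorm(nt, 0, config$tree_sd)
  psi <- pmin(0, config$psi_base - config$psi_stress_depth * s +
                config$psi_sd * (0.25 + 2.5 * s) * stats::rnorm(nrow(grid)))
  traj <- trait_trajectory(grid$date_index, nd, config$vcmax_start_mean,
                           config$vcmax_end_mean)
  dip <- config$stress_dip_per_mpa * pmax(0, config$psi_base - psi)
  vcmax <- pmax(5, traj + tree_effect[grid$tree] - dip)
  # Jmax couples to water status around the study-mean stress level, so the
  # population Jmax/Vcmax ratio stays at jmax_ratio while stressed leaves
  # fall below it and well-watered leaves sit slightly above.
  psi_ref <- config$psi_base - config$psi_stress_depth *
    mean(stress_profile(seq_len(nd), config$stress_peak_date))
  jmax <- config$jmax_ratio * vcmax *
    (1 + config$jmax_cv * stats::rnorm(nrow(grid)) +
       config$jmax_psi_coupling * (psi - psi_ref))
  jmax <- pmax(5, jmax)
  tibble::tibble(tree_id = sprintf("T%02d", grid$tree),
                 date_index = grid$date_index,
                 day = (grid$date_index - 1) * config$date_spacing_days,
                 psi_pd = psi, true_vcmax = vcmax, true_jmax = jmax)
}

#' The 13-step measurement protocol of intercellular CO2 setpoints (ppm)
#'
#' Starts at ambient 400 ppm, steps down to 0, returns to ambient twice,
#' then steps up to 2000 ppm.
#' @return Numeric vector of 13 Ci setpoints.
#' @export
aci_protocol_ci <- function() {
  c(400, 300, 200, 100, 50, 0, 400, 400, 600, 800, 1200, 1600, 2000)
}

#' Forward-simulate an A/Ci curve
#'
#' Evaluates the FvCB model at the 13 protocol setpoints for the given true
#' parameters and adds Gaussian measurement noise (`aci_noise_sd`).
#'
#' @param true_vcmax,true_jmax True parameter values (umol m-2 s-1).
#' @param config A [synth_config()] (noise level and true Rd).
#' @param k [kinetic_constants()].
#' @return An [aci_curve()].
#' @export
simulate_aci <- function(true_vcmax, true_jmax, config = synth_config(),
                         k = kinetic_constants()) {
  stopifnot(inherits(config, "synth_config"))
  if (true_vcmax <= 0 || true_jmax <= 0) {
    stop("true traits must be positive", call. = FALSE)
  }
  ci <- aci_protocol_ci()
  a <- fvcb_assimilation(ci, true_vcmax, true_jmax, config$rd_true, k = k)
  if (config$aci_noise_sd > 0) {
    a <- a + stats::rnorm(length(a), 0, config$aci_noise_sd)
  }
  aci_curve(ci, a)
}

#' Simulate one replicate leaf reflectance spectrum
#'
#' Builds reflectance on the 350-2500 nm 1-nm grid from a smooth analytic
#' green-leaf template (visible baseline, red-edge rise, gentle SWIR
#' decline) minus two trait-linked absorption systems: chlorophyll wells
#' near 470 and 665 nm whose depth increases linearly with `true_vcmax`
#' (reaching into the 680-750 nm red edge through the 665 nm Gaussian
#' shoulder), and water wells at 1450 and 1940 nm whose depth increases
#' with less negative `psi_pd` (wetter leaves absorb more). When the water
#' confound is enabled the red-edge midpoint also blue-shifts 3 nm per MPa
#' of water potential below baseline. Gaussian noise (`spectral_noise_sd`)
#' is added and the result clipped to [0, 1]. This analytic template is
#' deliberately not a radiative-transfer model: it exists to give the
#' statistical pipeline a controllable truth.
#'
#' @param true_vcmax True Vcmax (umol m-2 s-1, positive).
#' @param psi_pd Predawn water potential (MPa, <= 0).
#' @param config A [synth_config()].
#' @return A [spectrum()] on the 350-2500 nm grid.
#' @export
simulate_spectrum <- function(true_vcmax, psi_pd, config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (true_vcmax <= 0) stop("true_vcmax must be positive", call. = FALSE)
  if (psi_pd > 0) stop("psi_pd must be <= 0", call. = FALSE)
  wl <- 350:2500
  # Red-edge inflection moves to longer wavelengths as chlorophyll (and
  # with it carboxylation capacity) increases -- the basis of red-edge
  # chlorophyll indices -- and blue-shifts under water stress when the
  # confound is enabled.
  red_edge_mid <- 703 + 0.12 * (true_vcmax - 75)
  if (isTRUE(config$water_confound)) {
    red_edge_mid <- red_edge_mid + 1.5 * (psi_pd - config$psi_base)
  }
  base <- 0.10 + 0.18 * stats::plogis((wl - 430) / 25) +
    0.20 * stats::plogis((wl - red_edge_mid) / 12) -
    0.12 * stats::plogis((wl - 1500) / 150)
  chl_depth <- 0.06 + 0.0016 * true_vcmax
  # The blue absorption band saturates at moderate chlorophyll contents, so
  # its depth tracks capacity at only ~30% of the red band's sensitivity;
  # the discriminative signal lives in the red well and red edge.
  chl_blue <- 0.06 + 0.0016 * (75 + 0.3 * (true_vcmax - 75))
  chl <- chl_depth * exp(-(wl - 665)^2 / (2 * 30^2)) +
    0.7 * chl_blue * exp(-(wl - 470)^2 / (2 * 28^2))
  water_depth <- max(0.02, 0.10 * (1 + 0.8 * (psi_pd + 1.5) / 1.5))
  water <- water_depth * (0.7 * exp(-(wl - 1450)^2 / (2 * 55^2)) +
                            exp(-(wl - 1940)^2 / (2 * 85^2)))
  refl <- base - chl - water
  if (config$spectral_noise_sd > 0) {
    refl <- refl + stats::rnorm(length(wl), 0, config$spectral_noise_sd)
  }
  spectrum(wl, pmin(1, pmax(0, refl)))
}

#' Simulate a complete synthetic study
#'
#' Generates the full trees x dates table: traits and water potential
#' ([simulate_traits()]), a forward-simulated A/Ci curve per leaf
#' ([simulate_aci()]) and replicate reflectance spectra per leaf
#' ([simulate_spectrum()]). Fully reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param k [kinetic_constants()] used for the forward gas-exchange model.
#' @return A tibble (class `study_table`) with the trait columns of
#'   [simulate_traits()] plus list-columns `aci` ([aci_curve()]) and
#'   `spectra` (lists of [spectrum()] replicates).
#' @export
#' @examples
#' study <- simulate_study(synth_config(n_trees = 2, n_dates = 3, seed = 1))
#' study$aci[[1]]
simulate_study <- function(config = synth_config(), k = kinetic_constants()) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  inner <- config
  inner$seed <- NULL
  traits <- simulate_traits(inner)
  traits$aci <- lapply(seq_len(nrow(traits)), function(i) {
    simulate_aci(traits$true_vcmax[i], traits$true_jmax[i], inner, k)
  })
  traits$spectra <- lapply(seq_len(nrow(traits)), function(i) {
    lapply(seq_len(config$n_replicate_spectra), function(r) {
      simulate_spectrum(traits$true_vcmax[i], traits$psi_pd[i], inner)
    })
  })
  class(traits) <- c("study_table", class(traits))
  traits
}

#' Per-leaf mean spectra of a study as a matrix
#'
#' QCs each replicate (negative-value removal), averages replicates per
#' leaf, and stacks the means into a [spectra_matrix()].
#'
#' @param study A study table from [simulate_study()].
#' @return A [spectra_matrix()] with one row per leaf.
#' @export
study_spectra_matrix <- function(study) {
  means <- lapply(study$spectra, function(reps) {
    average_replicates(lapply(reps, qc_spectrum))
  })
  spectra_matrix(means, sample_ids = paste(study$tree_id, study$date_index,
                                           sep = "_d"))
}

#' Write / read a study as plain-text files
#'
#' `write_study()` writes one tidy CSV of traits and water potential
#' (`study.csv`), one A/Ci CSV per leaf (`aci_<leaf>.csv` with columns
#' `Ci_ppm`, `A_umol_m2_s`) and one wide spectra CSV per leaf
#' (`spectra_<leaf>.csv`, first column `wavelength_nm`, one column per
#' replicate). `read_study()` restores the same structure.
#'
#' @param study A study table from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `write_study` returns `dir` invisibly; `read_study` returns a
#'   study table.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  leaf <- paste(study$tree_id, study$date_index, sep = "_d")
  utils::write.csv(
    data.frame(leaf_id = leaf, tree_id = study$tree_id,
               date_index = study$date_index, day = study$day,
               psi_pd = study$psi_pd, true_vcmax = study$true_vcmax,
               true_jmax = study$true_jmax),
    file.path(dir, "study.csv"), row.names = FALSE)
  for (i in seq_len(nrow(study))) {
    utils::write.csv(
      data.frame(Ci_ppm = study$aci[[i]]$ci,
                 A_umol_m2_s = study$aci[[i]]$a),
      file.path(dir, sprintf("aci_%s.csv", leaf[i])), row.names = FALSE)
    reps <- study$spectra[[i]]
    wide <- data.frame(wavelength_nm = reps[[1]]$wavelengths)
    for (r in seq_along(reps)) wide[[sprintf("rep%d", r)]] <-
        reps[[r]]$reflectance
    utils::write.csv(wide, file.path(dir, sprintf("spectra_%s.csv", leaf[i])),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "study.csv"),
                         stringsAsFactors = FALSE)
  study <- tibble::as_tibble(tab[, c("tree_id", "date_index", "day",
                                     "psi_pd", "true_vcmax", "true_jmax")])
  study$aci <- lapply(tab$leaf_id, function(id) {
    d <- utils::read.csv(file.path(dir, sprintf("aci_%s.csv", id)))
    aci_curve(d$Ci_ppm, d$A_umol_m2_s)
  })
  study$spectra <- lapply(tab$leaf_id, function(id) {
    d <- utils::read.csv(file.path(dir, sprintf("spectra_%s.csv", id)))
    lapply(names(d)[-1], function(col) spectrum(d$wavelength_nm, d[[col]]))
  })
  class(study) <- c("study_table", class(study))
  study
}
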