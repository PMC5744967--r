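#' Rubisco kinetic constants at 25 degrees C
#'
#' Michaelis-Menten constants and the CO2 compensation point used by the
#' biochemical photosynthesis model. Defaults are the Bernacchi-family values
#' at 25 degrees C (the `plantecophys` defaults); all gas-exchange
#' measurements this package targets are made at 25 degrees C, so no
#' temperature response is applied.
#'
#' @param gamma_star CO2 compensation point in the absence of day
#'   respiration (ppm).
#' @param kc Michaelis constant of Rubisco for CO2 (ppm).
#' @param ko Michaelis constant of Rubisco for O2 (mbar).
#' @param o2 Partial pressure of oxygen (mbar).
#' @return An object of class `kinetic_constants` with fields `gamma_star`,
#'   `kc`, `ko`, `o2` and the derived effective Michaelis constant
#'   `km = kc * (1 + o2 / ko)`.
#' @export
#' @examples
#' kinetic_constants()
kinetic_constants <- function(gamma_star = 42.75, kc = 404.9, ko = 278.4,
                              o2 = 210) {
  vals <- c(gamma_star = gamma_star, kc = kc, ko = ko, o2 = o2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("kinetic constants must all be positive and finite", call. = FALSE)
  }
  k <- list(gamma_star = gamma_star, kc = kc, ko = ko, o2 = o2,
            km = kc * (1 + o2 / ko))
  class(k) <- "kinetic_constants"
  k
}

# Smaller root of theta*J^2 - (alpha*I + jmax)*J + alpha*I*jmax = 0:
# the realised electron transport rate under irradiance I (non-rectangular
# hyperbola light response).
electron_transport <- function(ppfd, jmax, alpha = 0.24, theta = 0.85) {
  b <- alpha * ppfd + jmax
  (b - sqrt(b^2 - 4 * theta * alpha * ppfd * jmax)) / (2 * theta)
}

#' Net CO2 assimilation under the FvCB model
#'
#' Forward-evaluates the Farquhar-von Caemmerer-Berry model of C3 leaf
#' photosynthesis: net assimilation is the minimum of the Rubisco-limited
#' rate `Ac = vcmax * (ci - gamma_star) / (ci + km)` and the
#' RuBP-regeneration-limited rate `Aj = J * (ci - gamma_star) /
#' (4 * ci + 8 * gamma_star)`, minus day respiration `rd`. `J` is the
#' realised electron transport rate from a non-rectangular hyperbola light
#' response with curvature `theta` and quantum yield `alpha`; at the
#' saturating default PPFD of 1800 umol m-2 s-1, `J` is close to `jmax`.
#'
#' Triose-phosphate-utilisation limitation is deliberately not modelled;
#' high-Ci points are treated as RuBP-regeneration limited.
#'
#' @param ci Intercellular CO2 concentration(s), ppm. May be a vector.
#' @param vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param jmax Maximum electron transport rate (umol m-2 s-1).
#' @param rd Day respiration (umol m-2 s-1).
#' @param k [kinetic_constants()].
#' @param ppfd Photosynthetic photon flux density (umol m-2 s-1).
#' @param alpha Quantum yield of electron transport (electron basis).
#' @param theta Curvature of the light response.
#' @return Net assimilation (umol m-2 s-1), same length as `ci`.
#' @export
#' @examples
#' fvcb_assimilation(400, vcmax = 75.7, jmax = 150.1, rd = 1)
fvcb_assimilation <- function(ci, vcmax, jmax, rd = 0,
                              k = kinetic_constants(), ppfd = 1800,
                              alpha = 0.24, theta = 0.85) {
  if (any(ci < 0)) stop("ci must be non-negative", call. = FALSE)
  if (vcmax <= 0 || jmax <= 0 || rd < 0 || ppfd <= 0) {
    stop("vcmax, jmax and ppfd must be positive and rd non-negative",
         call. = FALSE)
  }
  lim <- fvcb_limiting_rates(ci, vcmax, jmax, k, ppfd, alpha, theta)
  pmin(lim$ac, lim$aj) - rd
}

# Both gross limitation rates at once (used for labelling fitted points).
fvcb_limiting_rates <- function(ci, vcmax, jmax, k = kinetic_constants(),
                                ppfd = 1800, alpha = 0.24, theta = 0.85) {
  j <- electron_transport(ppfd, jmax, alpha, theta)
  list(ac = vcmax * (ci - k$gamma_star) / (ci + k$km),
       aj = j * (ci - k$gamma_star) / (4 * ci + 8 * k$gamma_star))
}

#' Construct an A/Ci curve
#'
#' An ordered set of paired (Ci, A) gas-exchange observations plus the
#' chamber conditions they were measured under.
#'
#' @param ci Intercellular CO2 (ppm), in measurement order.
#' @param a Net assimilation (umol m-2 s-1), same length as `ci`.
#' @param leaf_temp Leaf temperature (degrees C).
#' @param ppfd Chamber PPFD (umol m-2 s-1).
#' @param ca_ambient Ambient chamber CO2 (ppm); the first setpoint of the
#'   measurement protocol.
#' @return An `aci_curve` object.
#' @export
aci_curve <- function(ci, a, leaf_temp = 25, ppfd = 1800, ca_ambient = 400) {
  if (length(ci) != length(a)) stop("ci and a must have equal length",
                                    call. = FALSE)
  if (length(ci) == 0) stop("empty A/Ci curve", call. = FALSE)
  if (leaf_temp <= 0 || ppfd <= 0) {
    stop("leaf_temp and ppfd must be positive", call. = FALSE)
  }
  structure(list(ci = as.numeric(ci), a = as.numeric(a),
                 leaf_temp = leaf_temp, ppfd = ppfd,
                 ca_ambient = ca_ambient),
            class = "aci_curve")
}

#' @export
print.aci_curve <- function(x, ...) {
  cat(sprintf("<aci_curve> %d points, Ci %g-%g ppm, %g C, PPFD %g\n",
              length(x$ci), min(x$ci), max(x$ci), x$leaf_temp, x$ppfd))
  invisible(x)
}

#' Quality control of an A/Ci curve
#'
#' Applies the pre-fit screening rules: (i) assimilation at the first
#' ambient-CO2 point must be at least `min_initial_a` (default 10
#' umol m-2 s-1, the screening threshold for photosynthetically active
#' leaves); (ii) at least `min_points` usable points; (iii) all values
#' finite; (iv) A must track Ci over the initial descending limb of the
#' protocol (Spearman correlation >= `min_descending_rho`). All triggered
#' rules are reported, not just the first.
#'
#' @param curve An [aci_curve()].
#' @param min_initial_a Minimum initial assimilation (umol m-2 s-1).
#' @param min_points Minimum number of usable points.
#' @param min_descending_rho Minimum Spearman correlation between Ci and A
#'   over the leading non-increasing run of Ci setpoints.
#' @return A list with `pass` (logical) and `reasons` (character vector,
#'   empty when the curve passes).
#' @export
qc_aci <- function(curve, min_initial_a = 10, min_points = 5,
                   min_descending_rho = 0.5) {
  stopifnot(inherits(curve, "aci_curve"))
  reasons <- character()
  finite <- is.finite(curve$ci) & is.finite(curve$a)
  if (!all(finite)) reasons <- c(reasons, "non-finite values present")
  if (sum(finite) < min_points) {
    reasons <- c(reasons, sprintf("too few points (%d < %d)", sum(finite),
                                  min_points))
  }
  if (is.finite(curve$a[1]) && curve$a[1] < min_initial_a) {
    reasons <- c(reasons, sprintf("initial A below %g (A = %.2f)",
                                  min_initial_a, curve$a[1]))
  }
  # Leading run of non-increasing Ci = the descending limb of the protocol.
  dn <- which(diff(curve$ci) > 0)
  limb <- seq_len(if (length(dn)) dn[1] else length(curve$ci))
  limb <- limb[is.finite(curve$ci[limb]) & is.finite(curve$a[limb])]
  if (length(limb) >= 3) {
    rho <- suppressWarnings(
      stats::cor(curve$ci[limb], curve$a[limb], method = "spearman"))
    if (!is.na(rho) && rho < min_descending_rho) {
      reasons <- c(reasons,
                   sprintf("A does not track Ci on descending limb (rho = %.2f)",
                           rho))
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Fit the FvCB model to an A/Ci curve
#'
#' Estimates `vcmax`, `jmax` and day respiration `rd` by bounded nonlinear
#' least squares (Levenberg-Marquardt via \pkg{minpack.lm}) against
#' [fvcb_assimilation()]. A small multi-start grid (`vcmax` in 25, 50, 100,
#' 200 with `jmax = 2 * vcmax`, `rd = 1`) guards against local minima; the
#' start with the lowest residual sum of squares wins. Standard errors come
#' from the Jacobian at the optimum. Each point is labelled by the rate that
#' limits it ("Rubisco" or "RuBP", ties to Rubisco); a fit with only one
#' limitation state represented is flagged via `valid = FALSE`.
#'
#' @param curve An [aci_curve()] that passed [qc_aci()].
#' @param k [kinetic_constants()].
#' @param alpha,theta Light-response parameters, see [fvcb_assimilation()].
#' @param lower,upper Box bounds on `(vcmax, jmax, rd)`.
#' @param starts Matrix of starting values, one row per start, columns
#'   `(vcmax, jmax, rd)`.
#' @param min_points_per_regime A fit is flagged invalid unless at least
#'   this many points fall in each limitation regime at the optimum; with
#'   fewer, the parameter governing the under-represented regime is barely
#'   constrained by the data (common for strongly stressed leaves whose
#'   whole curve is regeneration-limited).
#' @return An object of class `fvcb_fit`: estimates, standard errors,
#'   `rmse`, `n_points`, per-point `limitation` labels, `converged`,
#'   `at_bound` and `valid` flags.
#' @export
fit_aci <- function(curve, k = kinetic_constants(), alpha = 0.24,
                    theta = 0.85,
                    lower = c(vcmax = 1, jmax = 1, rd = 0),
                    upper = c(vcmax = 1000, jmax = 2000, rd = 10),
                    starts = NULL, min_points_per_regime = 2) {
  stopifnot(inherits(curve, "aci_curve"))
  keep <- is.finite(curve$ci) & is.finite(curve$a) & curve$ci >= 0
  ci <- curve$ci[keep]
  a <- curve$a[keep]
  n <- length(ci)
  if (n < 5) stop("at least 5 usable points are required for fitting",
                  call. = FALSE)
  if (is.null(starts)) {
    v0 <- c(25, 50, 100, 200)
    starts <- cbind(vcmax = v0, jmax = 2 * v0, rd = 1)
  }
  resid_fn <- function(par) {
    a - fvcb_assimilation(ci, par[1], par[2], par[3], k = k,
                          ppfd = curve$ppfd, alpha = alpha, theta = theta)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(starts[i, ], lower), upper),
                         lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:3)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    res <- list(vcmax = NA_real_, jmax = NA_real_, rd = NA_real_,
                se_vcmax = NA_real_, se_jmax = NA_real_, se_rd = NA_real_,
                rmse = NA_real_, n_points = n,
                limitation = rep(NA_character_, n),
                converged = FALSE, at_bound = FALSE, valid = FALSE)
    class(res) <- "fvcb_fit"
    return(res)
  }
  par <- stats::coef(best)
  ses <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, 3))
  lim <- fvcb_limiting_rates(ci, par[1], par[2], k, curve$ppfd, alpha, theta)
  labels <- ifelse(lim$ac <= lim$aj, "Rubisco", "RuBP")
  at_bound <- any(abs(par[1:2] - lower[1:2]) < 1e-6 * pmax(1, lower[1:2])) ||
    any(abs(par[1:2] - upper[1:2]) < 1e-6 * upper[1:2])
  res <- list(vcmax = unname(par[1]), jmax = unname(par[2]),
              rd = unname(par[3]),
              se_vcmax = unname(ses[1]), se_jmax = unname(ses[2]),
              se_rd = unname(ses[3]),
              rmse = sqrt(best$deviance / n), n_points = n,
              limitation = labels, converged = TRUE, at_bound = at_bound,
              valid = sum(labels == "Rubisco") >= min_points_per_regime &&
                sum(labels == "RuBP") >= min_points_per_regime && !at_bound)
  class(res) <- "fvcb_fit"
  res
}

#' @export
print.fvcb_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<fvcb_fit> optimiser did not converge from any start\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<fvcb_fit> Vcmax %.2f (SE %.2f), Jmax %.2f (SE %.2f), Rd %.2f\n",
    x$vcmax, x$se_vcmax, x$jmax, x$se_jmax, x$rd))
  cat(sprintf("  rmse %.4g on %d points; %d Rubisco / %d RuBP limited%s\n",
              x$rmse, x$n_points, sum(x$limitation == "Rubisco"),
              sum(x$limitation == "RuBP"),
              if (x$valid) "" else " [flagged]"))
  invisible(x)
}

#' Fit all A/Ci curves in a study table
#'
#' Convenience wrapper: QC and fit each leaf's curve, returning one row per
#' leaf. Leaves failing QC get `qc_pass = FALSE` and NA estimates.
#'
#' @param study A study table from [simulate_study()] (or any tibble with
#'   `tree_id`, `date_index` and an `aci` list-column of [aci_curve()]s).
#' @param ... Passed to [fit_aci()].
#' @return A tibble with identifiers, QC flag, estimates and standard errors.
#' @export
fit_aci_table <- function(study, ...) {
  rows <- lapply(seq_len(nrow(study)), function(i) {
    curve <- study$aci[[i]]
    qc <- qc_aci(curve)
    if (qc$pass) {
      f <- fit_aci(curve, ...)
      tibble::tibble(tree_id = study$tree_id[i],
                     date_index = study$date_index[i],
                     qc_pass = TRUE, converged = f$converged,
                     valid = f$valid,
                     vcmax = f$vcmax, jmax = f$jmax, rd = f$rd,
                     se_vcmax = f$se_vcmax, se_jmax = f$se_jmax,
                     rmse = f$rmse)
    } else {
      tibble::tibble(tree_id = study$tree_id[i],
                     date_index = study$date_index[i],
                     qc_pass = FALSE, converged = NA, valid = NA,
                     vcmax = NA_real_, jmax = NA_real_, rd = NA_real_,
                     se_vcmax = NA_real_, se_jmax = NA_real_,
                     rmse = NA_real_)
    }
  })
  do.call(rbind, rows)
}
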