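#' Construct a leaf reflectance spectrum
#'
#' A reflectance vector on a strictly increasing 1-nm wavelength grid within
#' 350-2500 nm, as exported from a field spectroradiometer after white-panel
#' referencing. Cells removed by QC are held as `NA` with a per-wavelength
#' flag.
#'
#' @param wavelengths Wavelength grid (nm), strictly increasing.
#' @param reflectance Reflectance fractions, same length as `wavelengths`.
#' @param qc_flags Optional character vector of per-wavelength flags
#'   (`"ok"` or `"negative_removed"`).
#' @return A `spectrum` object.
#' @export
spectrum <- function(wavelengths, reflectance, qc_flags = NULL) {
  if (length(wavelengths) != length(reflectance)) {
    stop("wavelengths and reflectance must have equal length", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (min(wavelengths) < 350 || max(wavelengths) > 2500) {
    stop("wavelengths must lie within [350, 2500] nm", call. = FALSE)
  }
  if (any(is.infinite(reflectance))) {
    stop("reflectance must be finite", call. = FALSE)
  }
  if (is.null(qc_flags)) qc_flags <- rep("ok", length(wavelengths))
  structure(list(wavelengths = as.numeric(wavelengths),
                 reflectance = as.numeric(reflectance),
                 qc_flags = qc_flags),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bands, %g-%g nm, %d QC-masked\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              sum(x$qc_flags != "ok")))
  invisible(x)
}

#' Remove negative reflectance values from a spectrum
#'
#' Negative reflectance cells (an instrument artefact) are masked so they do
#' not enter replicate averaging at that wavelength; the flag records why.
#'
#' @param s A [spectrum()].
#' @return The spectrum with negative cells set to `NA` and flagged
#'   `"negative_removed"`.
#' @export
qc_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  neg <- !is.na(s$reflectance) & s$reflectance < 0
  if (all(neg | is.na(s$reflectance))) {
    stop("all reflectance values are negative or missing", call. = FALSE)
  }
  s$reflectance[neg] <- NA_real_
  s$qc_flags[neg] <- "negative_removed"
  s
}

#' Average replicate spectra of one leaf
#'
#' Per-wavelength arithmetic mean over the unmasked replicates; a wavelength
#' masked in every replicate stays `NA` (and is interpolated later when the
#' sample matrix is assembled).
#'
#' @param spectra List of [spectrum()] objects on identical grids.
#' @return A single mean [spectrum()].
#' @export
average_replicates <- function(spectra) {
  if (length(spectra) < 1) stop("need at least one replicate", call. = FALSE)
  wl <- spectra[[1]]$wavelengths
  for (s in spectra) {
    if (!identical(s$wavelengths, wl)) {
      stop("replicate spectra are on different wavelength grids",
           call. = FALSE)
    }
  }
  m <- do.call(rbind, lapply(spectra, `[[`, "reflectance"))
  mean_r <- colMeans(m, na.rm = TRUE)
  mean_r[is.nan(mean_r)] <- NA_real_
  flags <- ifelse(is.na(mean_r), "negative_removed", "ok")
  spectrum(wl, mean_r, flags)
}

#' Assemble a samples x wavelengths reflectance matrix
#'
#' Stacks per-leaf mean spectra into a matrix for multivariate modelling.
#' Wavelengths that are missing for a leaf (masked in all replicates) are
#' linearly interpolated from neighbouring wavelengths, with a warning.
#'
#' @param spectra List of [spectrum()] objects (one per sample) on a common
#'   grid.
#' @param sample_ids Character identifiers, one per sample.
#' @return A `spectra_matrix`: list with `values` (matrix), `wavelengths`,
#'   `sample_ids` and an (initially empty) `prep_state`.
#' @export
spectra_matrix <- function(spectra, sample_ids = NULL) {
  if (is.matrix(spectra)) stop("pass a list of spectrum objects",
                               call. = FALSE)
  wl <- spectra[[1]]$wavelengths
  vals <- do.call(rbind, lapply(spectra, function(s) {
    if (!identical(s$wavelengths, wl)) {
      stop("spectra are on different wavelength grids", call. = FALSE)
    }
    s$reflectance
  }))
  if (anyNA(vals)) {
    warning("missing reflectance cells linearly interpolated from ",
            "neighbouring wavelengths")
    for (i in which(rowSums(is.na(vals)) > 0)) {
      ok <- !is.na(vals[i, ])
      vals[i, ] <- stats::approx(wl[ok], vals[i, ok], xout = wl,
                                 rule = 2)$y
    }
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(nrow(vals)))
  structure(list(values = vals, wavelengths = wl,
                 sample_ids = as.character(sample_ids),
                 prep_state = list()),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d bands (%g-%g nm)%s\n",
              nrow(x$values), ncol(x$values), min(x$wavelengths),
              max(x$wavelengths),
              if (length(x$prep_state)) " [preprocessed]" else ""))
  invisible(x)
}

#' Restrict a spectra matrix to a wavelength window
#'
#' Subsetting happens before any preprocessing transform; models use the
#' 450-2500 nm window by default.
#'
#' @param m A [spectra_matrix()].
#' @param range Length-2 numeric, inclusive wavelength bounds (nm).
#' @return The cropped matrix.
#' @export
crop_wavelengths <- function(m, range = c(450, 2500)) {
  stopifnot(inherits(m, "spectra_matrix"))
  keep <- m$wavelengths >= range[1] & m$wavelengths <= range[2]
  if (!any(keep)) stop("no wavelengths in requested range", call. = FALSE)
  m$values <- m$values[, keep, drop = FALSE]
  m$wavelengths <- m$wavelengths[keep]
  m
}

#' Standard normal variate transform
#'
#' Standardises each spectrum across wavelengths: subtract the row mean and
#' divide by the row standard deviation (denominator n-1). Removes
#' per-spectrum additive and multiplicative scatter effects.
#'
#' @param x A numeric vector (one spectrum) or matrix (rows = spectra).
#' @return Same shape as `x`, each row with mean 0 and sd 1.
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    p <- ncol(x)
    rm <- rowMeans(x)
    rs <- sqrt(pmax(0, (rowSums(x^2) - p * rm^2) / (p - 1)))
    if (any(!is.finite(rs)) || any(rs == 0)) {
      stop("cannot SNV-transform a constant row (zero variance)",
           call. = FALSE)
    }
    return((x - rm) / rs)
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot SNV-transform a constant row (zero variance)",
         call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Savitzky-Golay second derivative
#'
#' Second derivative of each spectrum by local polynomial least squares
#' (window of `window` points, degree `polyorder`), exact for polynomials up
#' to the fitted degree. Edge points are handled by evaluating the
#' polynomial fitted to the edge window at the off-centre positions, so the
#' output has the same length as the input. Derivatives are with respect to
#' the 1-nm grid index.
#'
#' @param x Numeric vector or matrix (rows = spectra).
#' @param window Odd window length (points), > `polyorder`.
#' @param polyorder Polynomial degree, >= 2.
#' @return Second derivative, same shape as `x`.
#' @export
savgol_second_derivative <- function(x, window = 35, polyorder = 2) {
  if (window %% 2 != 1 || window <= polyorder || polyorder < 2) {
    stop("window must be odd and greater than polyorder (>= 2)",
         call. = FALSE)
  }
  if (is.matrix(x)) {
    if (ncol(x) < window) stop("row length must be at least the window",
                               call. = FALSE)
    if (anyNA(x)) stop("missing values must be interpolated before filtering",
                       call. = FALSE)
    return(sg_filter_matrix(x, window, polyorder))
  }
  if (length(x) < window) stop("row length must be at least the window",
                               call. = FALSE)
  if (anyNA(x)) stop("missing values must be interpolated before filtering",
                     call. = FALSE)
  signal::sgolayfilt(x, p = polyorder, n = window, m = 2)
}

# All rows filtered at once: interior points by convolution with the central
# projection row, edge points by the off-centre rows of the Savitzky-Golay
# projection matrix (the polynomial fit of the edge window evaluated at the
# edge positions) -- algebraically identical to filtering each row with
# signal::sgolayfilt.
sg_filter_matrix <- function(x, window, polyorder) {
  fm <- signal::sgolay(p = polyorder, n = window, m = 2)
  p <- ncol(x)
  hw <- (window - 1) / 2
  out <- matrix(0, nrow(x), p)
  centre <- fm[hw + 1, ]
  interior <- (hw + 1):(p - hw)
  acc <- matrix(0, nrow(x), length(interior))
  for (k in seq_len(window)) {
    acc <- acc + centre[k] * x[, interior + k - hw - 1, drop = FALSE]
  }
  out[, interior] <- acc
  out[, 1:hw] <- x[, 1:window, drop = FALSE] %*%
    t(fm[1:hw, , drop = FALSE])
  out[, (p - hw + 1):p] <- x[, (p - window + 1):p, drop = FALSE] %*%
    t(fm[(hw + 2):window, , drop = FALSE])
  dimnames(out) <- dimnames(x)
  out
}

# Row-wise (sample-local) half of the chain: SNV then SG second derivative.
# These involve no cross-sample statistics, so they can be computed once for
# a whole dataset regardless of later train/test splitting.
rowwise_prep <- function(values, window, polyorder) {
  savgol_second_derivative(snv(values), window, polyorder)
}

# Column statistics of the training matrix: sd first (autoscale), then the
# mean of the scaled columns (mean centering), applied in that literal
# order. Zero-variance columns are dropped.
column_stats <- function(rowprep, wavelengths, tol = 1e-12) {
  n <- nrow(rowprep)
  cm <- colMeans(rowprep)
  sds <- sqrt(pmax(0, (colSums(rowprep^2) - n * cm^2) / (n - 1)))
  keep <- is.finite(sds) & sds > tol
  if (!all(keep)) {
    warning(sprintf("%d zero-variance wavelength(s) dropped at autoscaling",
                    sum(!keep)))
  }
  scaled <- sweep(rowprep[, keep, drop = FALSE], 2, sds[keep], "/")
  mus <- colMeans(scaled)
  list(keep = which(keep), col_sd = sds[keep], col_mean = mus,
       wavelengths = wavelengths[keep])
}

apply_column_stats <- function(rowprep, stats) {
  x <- sweep(rowprep[, stats$keep, drop = FALSE], 2, stats$col_sd, "/")
  sweep(x, 2, stats$col_mean, "-")
}

#' Fit the spectral preprocessing chain
#'
#' Applies, in this exact order: standard normal variate (per sample),
#' Savitzky-Golay second derivative (per sample), autoscaling (divide each
#' wavelength by its calibration-set sd) and mean centering (subtract the
#' calibration-set mean of the scaled column). Scaling before centering as
#' listed composes to standard autoscaling; the literal order is kept so the
#' stored state replays transform-by-transform. Column statistics are
#' estimated on this (training) matrix only and replayed on new spectra with
#' [preprocess_apply()].
#'
#' @param m A raw [spectra_matrix()], already cropped to the modelling
#'   window (450-2500 nm by default elsewhere).
#' @param window,polyorder Savitzky-Golay settings, see
#'   [savgol_second_derivative()].
#' @return A list with `matrix` (the preprocessed `spectra_matrix`) and
#'   `state` (a `prep_state` replayable on test data).
#' @export
preprocess_fit <- function(m, window = 35, polyorder = 2) {
  stopifnot(inherits(m, "spectra_matrix"))
  rp <- rowwise_prep(m$values, window, polyorder)
  cs <- column_stats(rp, m$wavelengths)
  state <- list(steps = c("snv", "savgol_d2", "autoscale", "mean_center"),
                window = window, polyorder = polyorder,
                input_wavelengths = m$wavelengths,
                keep = cs$keep, col_sd = cs$col_sd, col_mean = cs$col_mean,
                wavelengths = cs$wavelengths)
  class(state) <- "prep_state"
  out <- m
  out$values <- apply_column_stats(rp, cs)
  out$wavelengths <- cs$wavelengths
  out$prep_state <- state
  list(matrix = out, state = state)
}

#' Replay a fitted preprocessing chain on new spectra
#'
#' @param state A `prep_state` from [preprocess_fit()] (or deserialised via
#'   [read_prep_state()]).
#' @param m A raw [spectra_matrix()] on the same wavelength grid the chain
#'   was fitted on.
#' @return The preprocessed `spectra_matrix`.
#' @export
preprocess_apply <- function(state, m) {
  stopifnot(inherits(state, "prep_state"), inherits(m, "spectra_matrix"))
  if (!isTRUE(all.equal(m$wavelengths, state$input_wavelengths))) {
    stop("wavelength grid does not match the fitted chain", call. = FALSE)
  }
  rp <- rowwise_prep(m$values, state$window, state$polyorder)
  out <- m
  out$values <- apply_column_stats(rp, state)
  out$wavelengths <- state$wavelengths
  out$prep_state <- state
  out
}

#' Serialize / restore a preprocessing chain
#'
#' The chain state (step order, filter settings, calibration statistics) is
#' written as JSON at full double precision, so a restored chain reproduces
#' the original transform bit-for-bit.
#'
#' @param state A `prep_state`.
#' @param path File path for the JSON sidecar.
#' @return `write_prep_state` returns `path` invisibly; `read_prep_state`
#'   returns the restored `prep_state`.
#' @export
write_prep_state <- function(state, path) {
  stopifnot(inherits(state, "prep_state"))
  jsonlite::write_json(unclass(state), path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prep_state
#' @export
read_prep_state <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  state <- list(steps = as.character(raw$steps),
                window = as.integer(raw$window),
                polyorder = as.integer(raw$polyorder),
                input_wavelengths = as.numeric(raw$input_wavelengths),
                keep = as.integer(raw$keep),
                col_sd = as.numeric(raw$col_sd),
                col_mean = as.numeric(raw$col_mean),
                wavelengths = as.numeric(raw$wavelengths))
  class(state) <- "prep_state"
  state
}
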