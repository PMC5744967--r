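# Registry cache (filled on first use).
.photospec_env <- new.env(parent = emptyenv())

#' The vegetation index registry
#'
#' Loads the versioned JSON registry of published hyperspectral indices
#' shipped with the package. The 19 `core` entries form the standard
#' comparison suite (18 narrow-band formulas plus the broad-band MODIS-like
#' NDVI); non-core entries are supplementary variants such as the
#' conventional full SIPI form.
#'
#' @param core_only Return only the 19-index core suite.
#' @return A tibble with columns `name`, `formula`, `target`, `core` and
#'   `required_wavelengths` (list-column, nm).
#' @export
#' @examples
#' vegetation_indices()
vegetation_indices <- function(core_only = TRUE) {
  if (is.null(.photospec_env$registry)) {
    path <- system.file("extdata", "vegetation_indices.json",
                        package = "photospec")
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- lapply(raw$indices, function(e) {
      tibble::tibble(name = e$name, formula = e$formula,
                     target = e$target, core = isTRUE(e$core),
                     required_wavelengths = list(formula_wavelengths(e)))
    })
    .photospec_env$registry <- do.call(rbind, rows)
  }
  reg <- .photospec_env$registry
  if (core_only) reg[reg$core, ] else reg
}

# Wavelengths an index needs, parsed from its formula (or fixed bands for
# the MODIS special case).
formula_wavelengths <- function(entry) {
  if (identical(entry$special, "modis")) return(c(620:670, 841:876))
  hits <- regmatches(entry$formula,
                     gregexpr("R([0-9]+)", entry$formula))[[1]]
  sort(unique(as.numeric(sub("^R", "", hits))))
}

# Reflectance at exact 1-nm grid points, by name ("R700" -> value at 700).
rho_at <- function(s, wavelengths) {
  idx <- match(wavelengths, s$wavelengths)
  if (anyNA(idx)) {
    stop(sprintf("spectrum does not cover wavelength(s): %s nm",
                 paste(wavelengths[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(s$reflectance[idx], paste0("R", wavelengths))
}

#' Evaluate one vegetation index on a spectrum
#'
#' Formulas are evaluated with `R<nm>` bound to the raw reflectance at the
#' 1-nm grid point `<nm>` (no band averaging for single-wavelength terms);
#' indices are always computed on raw, not preprocessed, reflectance. A zero
#' denominator yields a non-finite value rather than an error.
#'
#' @param s A [spectrum()] (raw reflectance).
#' @param definition One row of [vegetation_indices()], or an index name.
#' @return The index value (possibly `NaN`/`Inf` for degenerate spectra).
#' @export
#' @examples
#' s <- spectrum(350:2500, rep(0.3, 2151))
#' compute_index(s, "SR1")  # flat spectrum: simple ratio = 1
compute_index <- function(s, definition) {
  stopifnot(inherits(s, "spectrum"))
  if (is.character(definition)) {
    reg <- vegetation_indices(core_only = FALSE)
    hit <- which(reg$name == definition)
    if (!length(hit)) stop(sprintf("unknown index '%s'", definition),
                           call. = FALSE)
    definition <- reg[hit, ]
  }
  if (identical(definition$formula, "band_mean_ndvi")) {
    return(modis_like_ndvi(s))
  }
  wls <- definition$required_wavelengths[[1]]
  env <- as.list(rho_at(s, wls))
  eval(parse(text = definition$formula), envir = env)
}

#' Evaluate the full core index suite
#'
#' @param s A raw [spectrum()].
#' @param registry Index definitions, defaults to the core suite.
#' @return Named numeric vector of index values.
#' @export
compute_indices <- function(s, registry = vegetation_indices()) {
  vapply(seq_len(nrow(registry)),
         function(i) compute_index(s, registry[i, ]),
         numeric(1)) |>
    stats::setNames(registry$name)
}

#' MODIS-like broad-band NDVI from a narrow-band spectrum
#'
#' Emulates the satellite index from leaf spectra using the MODIS band
#' positions: red = band 1 (620-670 nm), NIR = band 2 (841-876 nm). In the
#' default `"band_mean"` mode the band reflectance is the plain mean of raw
#' reflectance over each nominal band range. The `"fwhm"` mode instead
#' restricts each band to the wavelengths where the band-limited curve
#' exceeds its half-range height (min + (max - min)/2) and averages between
#' the first and last crossing, mimicking full-width-half-maximum band
#' construction; for a flat band segment both modes coincide.
#'
#' @param s A raw [spectrum()] covering 620-670 and 841-876 nm.
#' @param mode `"band_mean"` (default) or `"fwhm"`.
#' @return NDVI = (NIR - red) / (NIR + red).
#' @export
modis_like_ndvi <- function(s, mode = c("band_mean", "fwhm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "spectrum"))
  band_value <- function(lo, hi) {
    sel <- s$wavelengths >= lo & s$wavelengths <= hi
    if (!any(sel)) {
      stop(sprintf("spectrum does not cover the %g-%g nm band", lo, hi),
           call. = FALSE)
    }
    y <- s$reflectance[sel]
    if (mode == "band_mean") return(mean(y))
    hm <- min(y) + (max(y) - min(y)) / 2
    inside <- which(y >= hm)
    mean(y[min(inside):max(inside)])
  }
  red <- band_value(620, 670)
  nir <- band_value(841, 876)
  (nir - red) / (nir + red)
}

#' Regress traits on vegetation indices
#'
#' Ordinary least squares of each trait on each index value, reporting R2,
#' slope, intercept, the slope t-test p-value and n, ranked by R2 within
#' trait. Indices with (near-)constant values are flagged `degenerate` and
#' excluded from the ranking.
#'
#' @param index_values Tibble/data.frame of index values, one row per
#'   sample, one column per index.
#' @param traits Tibble/data.frame of trait values (e.g. columns `vcmax`,
#'   `jmax`), one row per sample.
#' @return A tibble with one row per (index, trait) pair.
#' @export
index_trait_report <- function(index_values, traits) {
  index_values <- as.data.frame(index_values)
  traits <- as.data.frame(traits)
  stopifnot(nrow(index_values) == nrow(traits))
  rows <- list()
  for (trait in names(traits)) {
    y <- traits[[trait]]
    for (ix in names(index_values)) {
      x <- index_values[[ix]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      degenerate <- n < 3 || stats::sd(x[ok]) < 1e-12
      if (degenerate) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          index = ix, trait = trait, r_squared = NA_real_,
          slope = NA_real_, intercept = NA_real_, p_value = NA_real_,
          n = n, degenerate = TRUE)
        next
      }
      fit <- stats::lm(y[ok] ~ x[ok])
      sm <- summary(fit)
      rows[[length(rows) + 1]] <- tibble::tibble(
        index = ix, trait = trait, r_squared = sm$r.squared,
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        p_value = sm$coefficients[2, 4], n = n, degenerate = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$trait, -ifelse(is.na(out$r_squared), -Inf,
                                      out$r_squared)), ]
  out$rank <- stats::ave(ifelse(out$degenerate, NA, -out$r_squared),
                         out$trait, FUN = function(v) rank(v, na.last = "keep"))
  out
}
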