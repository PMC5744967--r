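#' Univariate partial least squares regression (NIPALS)
#'
#' Classical PLS1 NIPALS with deflation: each component's weight vector is
#' the (normalised) covariance of the current X residual with the current y
#' residual; scores, X-loadings and y-loadings follow, and both X and y are
#' deflated. For a single response this is deterministic (no inner
#' iteration). Regression coefficients are accumulated for every component
#' count 1..`ncomp`, so cross-validation can evaluate all model sizes from
#' one fit.
#'
#' @param X Numeric matrix, samples x wavelengths (already preprocessed;
#'   the fit additionally centres internally and stores the offsets).
#' @param y Numeric response vector.
#' @param ncomp Number of latent components, at most `min(nrow(X) - 1,
#'   ncol(X))`.
#' @param trait_name Optional label carried through to reports.
#' @return A `plsr_model`: weights `W`, loadings `P`, y-loadings `Q`,
#'   scores `T` (all per component), `coefficients` (wavelengths x ncomp,
#'   one column per component count), `regression_vector` (= last column),
#'   `intercepts`, centring offsets, and slots for a preprocessing state.
#' @export
fit_plsr <- function(X, y, ncomp, trait_name = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("y length must match nrow(X)", call. = FALSE)
  if (stats::sd(y) < 1e-12) stop("y has zero variance", call. = FALSE)
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop(sprintf("ncomp must be in 1..min(n-1, p) = %d", min(n - 1, p)),
         call. = FALSE)
  }
  x_center <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_mean
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  Q <- numeric(ncomp)
  a_used <- 0
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # X residual carries no further covariance with y
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xc, t)[, 1] / tt
    q <- sum(yc * t) / tt
    W[, a] <- w
    P[, a] <- pv
    Q[a] <- q
    Tm[, a] <- t
    Xc <- Xc - tcrossprod(t, pv)
    yc <- yc - q * t
    a_used <- a
  }
  if (a_used == 0) stop("X carries no covariance with y", call. = FALSE)
  if (a_used < ncomp) {
    warning(sprintf("rank exhausted after %d components (requested %d)",
                    a_used, ncomp))
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Q <- Q[seq_len(a_used)]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    ncomp <- a_used
  }
  # R maps X (centred) to scores: T = Xc R; coefficients per model size.
  R <- W %*% solve(t(P) %*% W)
  B <- sapply(seq_len(ncomp), function(a) {
    R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
  })
  B <- matrix(B, nrow = p)
  intercepts <- y_mean - drop(x_center %*% B)
  model <- list(ncomp = ncomp, weights = W, loadings = P, y_loadings = Q,
                scores = Tm, coefficients = B,
                regression_vector = B[, ncomp],
                intercepts = intercepts, x_center = x_center,
                y_mean = y_mean, trait_name = trait_name,
                prep_state = NULL, wavelengths = NULL, cv_rmsep = NULL)
  class(model) <- "plsr_model"
  model
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model>%s %d component(s), %d predictors%s\n",
              if (is.null(x$trait_name)) "" else paste0(" ", x$trait_name),
              x$ncomp, length(x$regression_vector),
              if (is.null(x$prep_state)) "" else " (+ preprocessing chain)"))
  invisible(x)
}

# Predictions of a fitted model on a plain (already preprocessed) matrix,
# for one or all component counts.
predict_matrix <- function(model, X, ncomp = model$ncomp) {
  drop(as.matrix(X) %*% model$coefficients[, ncomp] + model$intercepts[ncomp])
}

#' Predict a trait from spectra
#'
#' For a model trained through [train_plsr()] the stored preprocessing
#' chain (with its training-set calibration statistics) is replayed on the
#' raw spectra first; a plain matrix is assumed to be preprocessed already.
#'
#' @param object A `plsr_model`.
#' @param newdata A raw [spectra_matrix()] (when the model carries a
#'   preprocessing state) or a numeric matrix of preprocessed rows.
#' @param ncomp Number of components to use (default: the fitted choice).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (inherits(newdata, "spectra_matrix")) {
    if (!is.null(object$prep_state)) {
      want <- object$prep_state$input_wavelengths
      if (!isTRUE(all.equal(newdata$wavelengths, want))) {
        idx <- match(want, newdata$wavelengths)
        if (anyNA(idx)) {
          stop("wavelength grid does not cover the fitted chain",
               call. = FALSE)
        }
        newdata$values <- newdata$values[, idx, drop = FALSE]
        newdata$wavelengths <- want
      }
      newdata <- preprocess_apply(object$prep_state, newdata)
    }
    if (!is.null(object$wavelengths) &&
        !isTRUE(all.equal(newdata$wavelengths, object$wavelengths))) {
      stop("wavelength grid does not match the fitted model", call. = FALSE)
    }
    newdata <- newdata$values
  }
  if (ncol(newdata) != length(object$regression_vector)) {
    stop("newdata has the wrong number of predictors", call. = FALSE)
  }
  predict_matrix(object, newdata, ncomp)
}

# Inside cross-validation, asking for more components than a fold's rank
# supports is routine; the shortened fit is used as-is.
muffle_rank_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("rank exhausted", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Deterministic fold assignment for n samples.
cv_folds_assign <- function(n, k, fold_seed = 1) {
  withr::with_seed(fold_seed, sample(rep(seq_len(k), length.out = n)))
}

#' Choose the number of PLSR components by cross-validated RMSEP
#'
#' K-fold cross-validation on an (already preprocessed) matrix: RMSEP is
#' pooled over folds for each component count 1..`max_components` and the
#' global minimiser is returned; ties break toward fewer components. Fold
#' assignment uses a fixed seed so the choice is reproducible.
#'
#' @param X Preprocessed predictor matrix.
#' @param y Response vector.
#' @param max_components Largest model size to consider.
#' @param cv_folds Number of folds (must not exceed the sample count).
#' @param fold_seed Seed for the fold assignment.
#' @return The selected component count (integer) with the RMSEP curve
#'   attached as attribute `"rmsep"`.
#' @export
select_ncomp <- function(X, y, max_components = 10, cv_folds = 10,
                         fold_seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (max_components < 1) stop("max_components must be >= 1", call. = FALSE)
  if (n < cv_folds) stop("fewer samples than folds", call. = FALSE)
  folds <- cv_folds_assign(n, cv_folds, fold_seed)
  amax <- min(max_components, n - max(table(folds)) - 1, ncol(X))
  sqerr <- matrix(NA_real_, n, amax)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    fit <- muffle_rank_warning(fit_plsr(X[tr, , drop = FALSE], y[tr], amax))
    for (a in seq_len(fit$ncomp)) {
      sqerr[!tr, a] <- (predict_matrix(fit, X[!tr, , drop = FALSE], a) -
                          y[!tr])^2
    }
  }
  rmsep <- sqrt(colMeans(sqerr))
  ncomp <- which.min(rmsep)  # first minimum = fewest components on ties
  structure(as.integer(ncomp), rmsep = rmsep)
}

#' Train a trait model from raw spectra (leak-free)
#'
#' The user-level trainer: crops to the modelling window, fits the
#' preprocessing chain and selects the component count by K-fold RMSEP with
#' all cross-sample statistics (autoscaling sd, centring mean) re-estimated
#' inside each training fold, then refits chain and model on all rows. The
#' returned model carries the chain, so [predict.plsr_model()] accepts raw
#' spectra.
#'
#' @param m A raw [spectra_matrix()].
#' @param y Trait vector, one value per row of `m`.
#' @param trait_name Label for reports.
#' @param range Modelling wavelength window (nm).
#' @param window,polyorder Savitzky-Golay settings.
#' @param max_components,cv_folds,fold_seed See [select_ncomp()].
#' @param ncomp Fix the component count instead of selecting it (used when
#'   replicating a selection made elsewhere).
#' @return A `plsr_model` with `prep_state`, `wavelengths` and `cv_rmsep`
#'   filled in.
#' @export
train_plsr <- function(m, y, trait_name = NULL, range = c(450, 2500),
                       window = 35, polyorder = 2, max_components = 10,
                       cv_folds = 10, fold_seed = 1, ncomp = NULL) {
  stopifnot(inherits(m, "spectra_matrix"))
  m <- crop_wavelengths(m, range)
  rp <- rowwise_prep(m$values, window, polyorder)
  n <- nrow(rp)
  rmsep <- NULL
  if (is.null(ncomp)) {
    if (n < cv_folds) stop("fewer samples than folds", call. = FALSE)
    folds <- cv_folds_assign(n, cv_folds, fold_seed)
    amax <- min(max_components, n - max(table(folds)) - 1, ncol(rp))
    sqerr <- matrix(NA_real_, n, amax)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      cs <- suppressWarnings(column_stats(rp[tr, , drop = FALSE],
                                          m$wavelengths))
      fit <- muffle_rank_warning(
        fit_plsr(apply_column_stats(rp[tr, , drop = FALSE], cs),
                 y[tr], amax))
      Xte <- apply_column_stats(rp[!tr, , drop = FALSE], cs)
      for (a in seq_len(fit$ncomp)) {
        sqerr[!tr, a] <- (predict_matrix(fit, Xte, a) - y[!tr])^2
      }
    }
    rmsep <- sqrt(colMeans(sqerr))
    ncomp <- which.min(rmsep)
  }
  prep <- preprocess_fit(m, window, polyorder)
  model <- fit_plsr(prep$matrix$values, y, ncomp, trait_name)
  model$prep_state <- prep$state
  model$wavelengths <- prep$matrix$wavelengths
  model$cv_rmsep <- rmsep
  model
}

#' Selectivity Ratio wavelength importance
#'
#' Target projection: sample rows are projected onto the normalised
#' regression vector, giving a single predictive component; for each
#' wavelength the Selectivity Ratio is the variance of X explained by that
#' component divided by the residual variance (denominator floored at
#' 1e-12). High SR marks wavelengths whose variation is used by the model.
#'
#' @param model A `plsr_model`.
#' @param X The preprocessed predictor matrix the model was fitted on (a
#'   [spectra_matrix()] is accepted and, if raw, passed through the model's
#'   chain).
#' @return A `wavelength_importance` object: `wavelengths`, `sr` and
#'   `peak_wavelength`.
#' @export
selectivity_ratio <- function(model, X) {
  stopifnot(inherits(model, "plsr_model"))
  wavelengths <- model$wavelengths
  if (inherits(X, "spectra_matrix")) {
    if (length(X$prep_state) == 0 && !is.null(model$prep_state)) {
      X <- preprocess_apply(model$prep_state, X)
    }
    wavelengths <- X$wavelengths
    X <- X$values
  }
  b <- model$regression_vector
  nb <- sqrt(sum(b^2))
  if (nb < 1e-12) stop("degenerate (all-zero) regression vector",
                       call. = FALSE)
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  w <- b / nb
  t <- drop(Xc %*% w)
  tt <- sum(t^2)
  pv <- crossprod(Xc, t)[, 1] / tt
  explained_ss <- pv^2 * tt
  resid_ss <- colSums((Xc - tcrossprod(t, pv))^2)
  sr <- explained_ss / pmax(resid_ss, 1e-12)
  if (is.null(wavelengths)) wavelengths <- seq_along(sr)
  structure(list(wavelengths = wavelengths, sr = sr,
                 peak_wavelength = wavelengths[which.max(sr)]),
            class = "wavelength_importance")
}

#' @export
print.wavelength_importance <- function(x, ...) {
  cat(sprintf("<wavelength_importance> peak SR %.3g at %g nm\n",
              max(x$sr), x$peak_wavelength))
  invisible(x)
}

#' Serialize / restore a PLSR model as JSON
#'
#' Everything needed for out-of-sample prediction (coefficients, centring,
#' component count and the preprocessing chain) is written at full double
#' precision.
#'
#' @param model A `plsr_model`.
#' @param path JSON file path.
#' @return `write_plsr_model` returns `path` invisibly; `read_plsr_model`
#'   the restored model.
#' @export
write_plsr_model <- function(model, path) {
  stopifnot(inherits(model, "plsr_model"))
  payload <- list(
    ncomp = model$ncomp, coefficients = model$coefficients,
    intercepts = model$intercepts, x_center = model$x_center,
    y_mean = model$y_mean, trait_name = model$trait_name,
    wavelengths = model$wavelengths,
    prep_state = if (is.null(model$prep_state)) NULL else
      unclass(model$prep_state))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plsr_model
#' @export
read_plsr_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(ncomp = as.integer(raw$ncomp),
                weights = NULL, loadings = NULL, y_loadings = NULL,
                scores = NULL,
                coefficients = matrix(raw$coefficients,
                                      ncol = as.integer(raw$ncomp)),
                intercepts = as.numeric(raw$intercepts),
                x_center = as.numeric(raw$x_center),
                y_mean = as.numeric(raw$y_mean),
                trait_name = raw$trait_name,
                wavelengths = as.numeric(raw$wavelengths),
                cv_rmsep = NULL, prep_state = NULL)
  model$regression_vector <- model$coefficients[, model$ncomp]
  if (!is.null(raw$prep_state)) {
    st <- raw$prep_state
    state <- list(steps = as.character(st$steps),
                  window = as.integer(st$window),
                  polyorder = as.integer(st$polyorder),
                  input_wavelengths = as.numeric(st$input_wavelengths),
                  keep = as.integer(st$keep),
                  col_sd = as.numeric(st$col_sd),
                  col_mean = as.numeric(st$col_mean),
                  wavelengths = as.numeric(st$wavelengths))
    class(state) <- "prep_state"
    model$prep_state <- state
  }
  class(model) <- "plsr_model"
  model
}
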