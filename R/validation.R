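#' Observed-vs-predicted performance metrics
#'
#' The headline `r_squared` is the squared Pearson correlation between
#' observed and predicted values (the convention matching observed-vs-
#' predicted validation panels); the alternative prediction R2
#' (`r_squared_sse = 1 - SSE/SST`) is reported alongside. RMSE is the root
#' mean squared prediction error.
#'
#' @param observed,predicted Paired finite numeric vectors, n >= 2.
#' @return A list: `r_squared`, `r_squared_sse`, `rmse`, `n`, and
#'   `r_squared_defined` (FALSE when either vector has zero variance).
#' @export
metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("observed and predicted must be paired vectors of length >= 2",
         call. = FALSE)
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("metrics require finite values", call. = FALSE)
  }
  rmse <- sqrt(mean((predicted - observed)^2))
  defined <- stats::sd(observed) > 0 && stats::sd(predicted) > 0
  r2 <- if (defined) stats::cor(observed, predicted)^2 else NA_real_
  sst <- sum((observed - mean(observed))^2)
  r2_sse <- if (sst > 0) 1 - sum((predicted - observed)^2) / sst else
    NA_real_
  list(r_squared = r2, r_squared_sse = r2_sse, rmse = rmse,
       n = length(observed), r_squared_defined = defined)
}

#' Assemble the modelling dataset from a study table
#'
#' Joins per-leaf mean spectra with a trait value per leaf: either the
#' simulation truth (`trait_source = "true"`) or gas-exchange estimates
#' obtained by QC-ing and fitting each leaf's A/Ci curve
#' (`trait_source = "fitted"`, the structure of a real campaign). Leaves
#' failing curve QC or fitting are dropped with a message.
#'
#' @param study A study table from [simulate_study()].
#' @param trait_source `"fitted"` or `"true"`.
#' @param ... Passed to [fit_aci_table()] when fitting.
#' @return A list: `spectra` ([spectra_matrix()]), `traits` (tibble with
#'   `vcmax`, `jmax`), `psi_pd`, `date_index`, `tree_id`.
#' @export
study_dataset <- function(study, trait_source = c("fitted", "true"), ...) {
  trait_source <- match.arg(trait_source)
  if (trait_source == "true") {
    traits <- tibble::tibble(vcmax = study$true_vcmax,
                             jmax = study$true_jmax)
    keep <- rep(TRUE, nrow(study))
  } else {
    fits <- fit_aci_table(study, ...)
    keep <- fits$qc_pass & !is.na(fits$vcmax) & fits$valid %in% TRUE
    if (any(!keep)) {
      message(sprintf("%d leaf/leaves dropped (QC, fit failure or flagged fit)",
                      sum(!keep)))
    }
    traits <- tibble::tibble(vcmax = fits$vcmax[keep],
                             jmax = fits$jmax[keep])
  }
  sm <- study_spectra_matrix(study[keep, ])
  list(spectra = sm, traits = traits, psi_pd = study$psi_pd[keep],
       date_index = study$date_index[keep], tree_id = study$tree_id[keep])
}

validation_result <- function(scheme, predictions, per_run, extra = list()) {
  pooled <- metrics(predictions$observed, predictions$predicted)
  summary <- if (!is.null(per_run) && nrow(per_run) > 0 &&
                 any(is.finite(per_run$r_squared))) {
    list(mean_r_squared = mean(per_run$r_squared, na.rm = TRUE),
         sd_r_squared = stats::sd(per_run$r_squared, na.rm = TRUE),
         median_r_squared = stats::median(per_run$r_squared, na.rm = TRUE))
  } else NULL
  structure(c(list(scheme = scheme, predictions = predictions,
                   per_run = per_run, metrics = pooled, summary = summary),
              extra),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> scheme %s: pooled R2 %.3f, RMSE %.3g (n = %d)\n",
              x$scheme, x$metrics$r_squared, x$metrics$rmse, x$metrics$n))
  if (!is.null(x$summary) && nrow(x$per_run) > 1) {
    cat(sprintf("  per-run R2: mean %.3f, sd %.3f, median %.3f (%d runs)\n",
                x$summary$mean_r_squared, x$summary$sd_r_squared,
                x$summary$median_r_squared, nrow(x$per_run)))
  }
  invisible(x)
}

#' Leave-one-out cross-validation of the spectra-to-trait model
#'
#' For each leaf, the preprocessing chain is fitted, the component count
#' selected, and the model trained on all other leaves; the held-out leaf
#' is then predicted. Metrics are pooled over the held-out predictions.
#' Deterministic: there is no randomness beyond the fixed fold seed used
#' inside component selection.
#'
#' @param data A dataset from [study_dataset()].
#' @param trait `"vcmax"` or `"jmax"`.
#' @param ... Passed to [train_plsr()] (window, max_components, ...).
#' @return A `validation_result` with one prediction per leaf and the
#'   per-leaf selected component counts in `per_run`.
#' @export
loo_cv <- function(data, trait = c("vcmax", "jmax"), ...) {
  trait <- match.arg(trait)
  y <- data$traits[[trait]]
  n <- length(y)
  if (n < 5) stop("leave-one-out validation needs at least 5 observations",
                  call. = FALSE)
  preds <- numeric(n)
  ncomps <- integer(n)
  for (i in seq_len(n)) {
    m_tr <- subset_spectra(data$spectra, -i)
    model <- train_plsr(m_tr, y[-i], trait_name = trait, ...)
    preds[i] <- predict(model, subset_spectra(data$spectra, i))
    ncomps[i] <- model$ncomp
  }
  validation_result(
    "loo",
    tibble::tibble(observed = y, predicted = preds),
    tibble::tibble(run = seq_len(n), n_train = n - 1, n_test = 1,
                   n_components = ncomps, r_squared = NA_real_),
    extra = list(trait = trait))
}

subset_spectra <- function(m, idx) {
  m$values <- m$values[idx, , drop = FALSE]
  m$sample_ids <- m$sample_ids[idx]
  m
}

#' Repeated random train/test splits
#'
#' Repeats a random `train_fraction` / (1 - `train_fraction`) split
#' `n_reps` times; each repetition trains a fresh chain + model on the
#' training part and evaluates on the held-out part. Summarises the spread
#' of R2 across repetitions (mean, sd, median).
#'
#' @param data A dataset from [study_dataset()].
#' @param trait `"vcmax"` or `"jmax"`.
#' @param train_fraction Fraction of samples used for training (0-1).
#' @param n_reps Number of random splits.
#' @param seed Seed for the split draws (results are bit-identical for a
#'   fixed seed).
#' @param ... Passed to [train_plsr()].
#' @return A `validation_result`; `per_run` holds each split's metrics.
#' @export
repeated_split <- function(data, trait = c("vcmax", "jmax"),
                           train_fraction = 0.8, n_reps = 100, seed = 1,
                           ...) {
  trait <- match.arg(trait)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  y <- data$traits[[trait]]
  n <- length(y)
  n_train <- round(train_fraction * n)
  splits <- withr::with_seed(seed, lapply(seq_len(n_reps), function(r) {
    sample(n, n_train)
  }))
  runs <- list()
  obs_all <- pred_all <- numeric(0)
  for (r in seq_len(n_reps)) {
    tr <- splits[[r]]
    te <- setdiff(seq_len(n), tr)
    if (length(te) < 2) {
      warning(sprintf("repetition %d skipped: test set smaller than 2", r))
      next
    }
    model <- train_plsr(subset_spectra(data$spectra, tr), y[tr],
                        trait_name = trait, ...)
    pred <- predict(model, subset_spectra(data$spectra, te))
    mt <- metrics(y[te], pred)
    runs[[length(runs) + 1]] <- tibble::tibble(
      run = r, n_train = length(tr), n_test = length(te),
      n_components = model$ncomp, r_squared = mt$r_squared,
      rmse = mt$rmse)
    obs_all <- c(obs_all, y[te])
    pred_all <- c(pred_all, pred)
  }
  validation_result(
    "repeated_split",
    tibble::tibble(observed = obs_all, predicted = pred_all),
    do.call(rbind, runs),
    extra = list(trait = trait, train_fraction = train_fraction,
                 seed = seed))
}

# Pooled variance of psi over the observations of two adjacent sampling
# dates, for every adjacent pair.
date_pair_variances <- function(date_index, psi_pd) {
  dates <- sort(unique(date_index))
  if (length(dates) < 3) {
    stop("stress holdout needs at least 3 distinct dates", call. = FALSE)
  }
  pairs <- cbind(dates[-length(dates)], dates[-1])
  v <- apply(pairs, 1, function(pr) {
    stats::var(psi_pd[date_index %in% pr])
  })
  list(pairs = pairs, variance = v)
}

#' Hold out the dates of maximal water-stress variation
#'
#' The most rigorous validation tier: among all pairs of consecutive
#' sampling dates ("consecutive" = adjacent in the sorted date list), the
#' pair with the largest variance in predawn water potential across its
#' observations is held out; the model is trained on all other dates and
#' tested on the held-out pair. Ties go to the earlier pair (logged).
#'
#' @param data A dataset from [study_dataset()] (carries `psi_pd` and
#'   `date_index`).
#' @param trait `"vcmax"` or `"jmax"`.
#' @param ... Passed to [train_plsr()].
#' @return A `validation_result` with `held_out_dates` and the trained
#'   `model` attached.
#' @export
stress_holdout <- function(data, trait = c("vcmax", "jmax"), ...) {
  trait <- match.arg(trait)
  y <- data$traits[[trait]]
  dp <- date_pair_variances(data$date_index, data$psi_pd)
  best <- which(dp$variance == max(dp$variance))
  if (length(best) > 1) {
    message("tie in date-pair variance; earlier pair chosen")
  }
  best <- best[1]
  held <- dp$pairs[best, ]
  te <- which(data$date_index %in% held)
  tr <- setdiff(seq_along(y), te)
  model <- train_plsr(subset_spectra(data$spectra, tr), y[tr],
                      trait_name = trait, ...)
  pred <- predict(model, subset_spectra(data$spectra, te))
  mt <- metrics(y[te], pred)
  validation_result(
    "stress_holdout",
    tibble::tibble(observed = y[te], predicted = pred),
    tibble::tibble(run = 1L, n_train = length(tr), n_test = length(te),
                   n_components = model$ncomp, r_squared = mt$r_squared,
                   rmse = mt$rmse),
    extra = list(trait = trait, held_out_dates = held,
                 pair_variances = dp, model = model))
}
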