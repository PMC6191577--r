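#' Fit a PLSR model of a trait on reflectance bands
#'
#' Latent-variable (partial least squares) regression of one trait on a
#' plots-by-bands reflectance matrix, fitted on mean-centered data
#' (optionally autoscaled).  Calibration metrics follow the chemometric
#' conventions: `r2_cal = 1 - SSE/SST` on the training data,
#' `rmsec = sqrt(SSE/n)`, and `slope_cal` is the slope of regressing the
#' fitted values on the observed values.  For a least-squares fit with an
#' intercept, `slope_cal` equals `r2_cal` (the classic
#' predicted-vs-observed identity), a useful internal consistency check.
#'
#' The latent-variable decomposition is delegated to
#' [mixOmics::pls()] in regression mode.
#'
#' @param X numeric matrix, plots x bands (columns named by wavelength).
#' @param y numeric trait vector.
#' @param n_components number of latent variables (>= 1, < n and <= ncol).
#' @param scale if `TRUE`, autoscale bands to unit variance; the default
#'   `FALSE` mean-centers only.
#' @return an object of class `"plsr_fit"`: list with `model`, `fitted`,
#'   `n_components`, `r2_cal`, `rmsec`, `slope_cal`, `n`.
#' @export
fit_plsr <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("X rows and y length differ")
  if (n_components < 1) stop("n_components must be >= 1")
  if (n_components >= n)
    stop("n_components must be smaller than the number of observations")
  if (n_components > ncol(X))
    stop("n_components exceeds the number of bands")
  if (stats::sd(y) == 0) stop("degenerate: constant trait vector")
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  model <- mixOmics::pls(X, y, ncomp = n_components, mode = "regression",
                         scale = scale)
  fitted <- stats::predict(model, X)$predict[, 1, n_components]
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(model = model, fitted = fitted,
                 n_components = as.integer(n_components),
                 r2_cal = 1 - sse / sst,
                 rmsec = sqrt(sse / n),
                 slope_cal = obs_pred_slope(y, fitted),
                 n = n, scale = scale),
            class = "plsr_fit")
}

# slope of regressing predictions on observed values
obs_pred_slope <- function(obs, pred) {
  stats::cov(obs, pred) / stats::var(obs)
}

#' Cross-validated PLSR evaluation of a trait
#'
#' Partitions plots into `k_folds` seeded, size-balanced random folds;
#' pools out-of-fold predictions for every candidate component count
#' `1..max_components`; picks the count minimizing the pooled RMSEV; and
#' reports the chosen model's calibration metrics (refit on all data) next
#' to the validation metrics.  Validation R2 is defined as
#' `1 - PRESS/SST` on the pooled out-of-fold predictions; it can fall
#' below 0 when the model has no predictive power.  `slope_val` mirrors
#' `slope_cal`: the slope of pooled predictions regressed on observed
#' values.
#'
#' @inheritParams fit_plsr
#' @param max_components largest candidate component count (default 10;
#'   silently capped so every training fold keeps more observations than
#'   components).
#' @param k_folds number of folds (default 7).
#' @param seed integer seed for the fold partition; the same seed gives
#'   identical folds and therefore identical metrics.
#' @param trait_name label stored in the result.
#' @param wavelength_range optional `c(lo, hi)` recorded as metadata.
#' @return an object of class `"plsr_evaluation"`: list with `trait_name`,
#'   `n_components`, `r2_cal`, `r2_val`, `rmsec`, `rmsev`, `slope_cal`,
#'   `slope_val`, `n`, `k_folds`, `seed`, `wavelength_range`, plus
#'   `rmsev_by_ncomp` (the selection curve) and `pred_val` (pooled
#'   out-of-fold predictions of the chosen model).
#' @export
cross_validate_plsr <- function(X, y, max_components = 10L, k_folds = 7L,
                                seed = 1L, scale = FALSE,
                                trait_name = deparse(substitute(y)),
                                wavelength_range = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("X rows and y length differ")
  if (k_folds < 2L) stop("k_folds must be >= 2")
  if (k_folds > n) stop("k_folds exceeds the number of observations")
  if (stats::sd(y) == 0) stop("degenerate: constant trait vector")
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))

  min_train <- n - ceiling(n / k_folds)
  M <- min(max_components, ncol(X), min_train - 1L)
  if (M < 1L) stop("too few observations per training fold")

  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  pred <- matrix(NA_real_, n, M)
  for (f in seq_len(k_folds)) {
    te <- folds == f
    fit <- mixOmics::pls(X[!te, , drop = FALSE], y[!te], ncomp = M,
                         mode = "regression", scale = scale)
    p <- stats::predict(fit, X[te, , drop = FALSE])$predict
    pred[te, ] <- p[, 1, seq_len(M), drop = TRUE]
  }
  rmsev_by_ncomp <- sqrt(colMeans((y - pred)^2))
  ncomp <- which.min(rmsev_by_ncomp)
  press <- sum((y - pred[, ncomp])^2)
  sst <- sum((y - mean(y))^2)
  cal <- fit_plsr(X, y, ncomp, scale = scale)
  structure(list(trait_name = trait_name,
                 n_components = as.integer(ncomp),
                 r2_cal = cal$r2_cal, r2_val = 1 - press / sst,
                 rmsec = cal$rmsec, rmsev = rmsev_by_ncomp[ncomp],
                 slope_cal = cal$slope_cal,
                 slope_val = obs_pred_slope(y, pred[, ncomp]),
                 n = n, k_folds = as.integer(k_folds),
                 seed = as.integer(seed),
                 wavelength_range = wavelength_range,
                 rmsev_by_ncomp = rmsev_by_ncomp,
                 pred_val = pred[, ncomp], folds = folds),
            class = "plsr_evaluation")
}

#' @export
print.plsr_evaluation <- function(x, ...) {
  cat(sprintf("PLSR evaluation: %s (n = %d, %d-fold CV, seed %d)\n",
              x$trait_name, x$n, x$k_folds, x$seed))
  cat(sprintf("  PCs %d | R2cal %.3f R2val %.3f | RMSEC %.4g RMSEV %.4g | slope cal %.3f val %.3f\n",
              x$n_components, x$r2_cal, x$r2_val, x$rmsec, x$rmsev,
              x$slope_cal, x$slope_val))
  invisible(x)
}

#' Restrict a spectra matrix to a wavelength window
#'
#' @param m result of [spectra_to_matrix()].
#' @param range `c(lo, hi)` in nm, default the 400--1000 nm window used for
#'   PLSR of canopy traits.
#' @return the same list with `X` and `wavelengths` restricted.
#' @export
restrict_bands <- function(m, range = c(400, 1000)) {
  keep <- m$wavelengths >= range[1] & m$wavelengths <= range[2]
  if (!any(keep)) stop("no bands inside the requested range")
  list(X = m$X[, keep, drop = FALSE], wavelengths = m$wavelengths[keep],
       ids = m$ids)
}

#' PLSR evaluation table by growth stage
#'
#' Runs [cross_validate_plsr()] per date subset and on the pooled data
#' ("All"), for each requested trait, producing the standard evaluation
#' layout: PCs, R2cal, R2val, RMSEC, RMSEV, slope cal, slope val.
#'
#' @param m spectra matrix list from [spectra_to_matrix()] (already
#'   band-restricted, see [restrict_bands()]).
#' @param traits data frame aligned with `m$ids` rows, holding trait
#'   columns and `date_id`.
#' @param trait_cols character vector of trait column names.
#' @inheritParams cross_validate_plsr
#' @return data frame, one row per (stage, trait).
#' @export
plsr_evaluation_table <- function(m, traits, trait_cols,
                                  max_components = 10L, k_folds = 7L,
                                  seed = 1L, scale = FALSE) {
  stopifnot(nrow(traits) == nrow(m$X))
  stages <- c(unique(as.character(traits$date_id)), "All")
  rows <- list()
  for (st in stages) {
    sel <- if (st == "All") rep(TRUE, nrow(traits)) else
      traits$date_id == st
    for (tr in trait_cols) {
      ev <- cross_validate_plsr(m$X[sel, , drop = FALSE],
                                traits[[tr]][sel],
                                max_components = max_components,
                                k_folds = k_folds, seed = seed,
                                scale = scale, trait_name = tr,
                                wavelength_range = range(m$wavelengths))
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, trait = tr, n = ev$n, PCs = ev$n_components,
        r2_cal = ev$r2_cal, r2_val = ev$r2_val,
        rmsec = ev$rmsec, rmsev = ev$rmsev,
        slope_cal = ev$slope_cal, slope_val = ev$slope_val,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
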