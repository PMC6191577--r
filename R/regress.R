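#' Simple linear regression with R2 and significance stars
#'
#' Ordinary least squares of `y` on `x` with the coefficient of
#' determination and a two-sided t-test p-value for the slope (n - 2 df).
#' Significance stars follow the usual nominal alpha levels: `***` for
#' p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns` otherwise.
#'
#' @param x predictor vector (not constant, n >= 3).
#' @param y response vector, same length.
#' @return an object of class `"regression_result"`: list with `slope`,
#'   `intercept`, `quad` (NA for the linear form), `r2`, `p_value`,
#'   `stars`, `n`, `model_form`.
#' @examples
#' r <- fit_linear(1:10, 2 * (1:10) + 1)
#' r$slope; r$r2
#' @export
fit_linear <- function(x, y) {
  check_xy(x, y, min_n = 3L)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  p <- s$coefficients["x", "Pr(>|t|)"]
  new_regression_result(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]), quad = NA_real_,
    r2 = s$r.squared, p_value = p, n = length(x), model_form = "linear")
}

#' Quadratic regression with R2 and overall-F significance
#'
#' Least squares of `y` on `(x, x^2)`, used for the curvilinear
#' green-pixel--trait relationships that appear once canopy cover
#' saturates.  The p-value is for the overall F test of the fit.
#'
#' @param x predictor vector (not constant, n >= 4).
#' @param y response vector, same length.
#' @return a `"regression_result"` with `model_form = "quadratic"` and the
#'   `x^2` coefficient in `quad`.
#' @export
fit_quadratic <- function(x, y) {
  check_xy(x, y, min_n = 4L)
  fit <- stats::lm(y ~ x + I(x^2))
  s <- summary(fit)
  fs <- s$fstatistic
  p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  co <- stats::coef(fit)
  new_regression_result(
    slope = unname(co[2]), intercept = unname(co[1]), quad = unname(co[3]),
    r2 = s$r.squared, p_value = unname(p), n = length(x),
    model_form = "quadratic")
}

check_xy <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA")
  if (length(x) < min_n)
    stop(sprintf("need at least %d observations", min_n))
  if (stats::sd(x) == 0) stop("degenerate regression: x is constant")
}

new_regression_result <- function(slope, intercept, quad, r2, p_value, n,
                                  model_form) {
  structure(list(slope = slope, intercept = intercept, quad = quad,
                 r2 = r2, p_value = p_value,
                 stars = significance_stars(p_value), n = n,
                 model_form = model_form),
            class = "regression_result")
}

#' Significance stars at the 0.05 / 0.01 / 0.001 alpha levels
#'
#' @param p p-value(s) in (0, 1].
#' @return character vector: `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "ns")))
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): R2 = %.3f%s, p = %.3g\n",
              x$model_form, x$n, x$r2,
              ifelse(x$stars == "ns", " ns", x$stars), x$p_value))
  if (x$model_form == "quadratic")
    cat(sprintf("  y = %.4g + %.4g x + %.4g x^2\n",
                x$intercept, x$slope, x$quad))
  else
    cat(sprintf("  y = %.4g + %.4g x\n", x$intercept, x$slope))
  invisible(x)
}

#' R2-with-stars summary table of predictors against traits
#'
#' Builds the classic evaluation layout for index--trait relationships:
#' one row per predictor column, one column per trait x date (plus a
#' pooled "All" column per trait), each cell `"<R2><stars>"` from a simple
#' linear (or quadratic) regression.
#'
#' @param data data frame holding predictors, traits and a date column.
#' @param predictors character vector of predictor column names.
#' @param traits character vector of trait column names.
#' @param date_col name of the date column (default `"date_id"`); set to
#'   `NULL` for a pooled-only table.
#' @param model_form `"linear"` (default) or `"quadratic"`.
#' @param digits digits for the printed R2 (default 2).
#' @return character data frame, rownames = predictors.
#' @export
regression_summary_table <- function(data, predictors, traits,
                                     date_col = "date_id",
                                     model_form = c("linear", "quadratic"),
                                     digits = 2) {
  model_form <- match.arg(model_form)
  fitfun <- if (model_form == "linear") fit_linear else fit_quadratic
  dates <- if (is.null(date_col)) character(0) else
    unique(as.character(data[[date_col]]))
  cols <- list()
  for (tr in traits) {
    for (d in dates) {
      sub <- data[data[[date_col]] == d, ]
      cols[[paste(tr, d, sep = ".")]] <- vapply(predictors, function(p) {
        r <- fitfun(sub[[p]], sub[[tr]])
        paste0(formatC(r$r2, digits = digits, format = "f"),
               ifelse(r$stars == "ns", " ns", r$stars))
      }, character(1))
    }
    cols[[paste(tr, "All", sep = ".")]] <- vapply(predictors, function(p) {
      r <- fitfun(data[[p]], data[[tr]])
      paste0(formatC(r$r2, digits = digits, format = "f"),
             ifelse(r$stars == "ns", " ns", r$stars))
    }, character(1))
  }
  out <- as.data.frame(cols, check.names = FALSE,
                       stringsAsFactors = FALSE)
  rownames(out) <- predictors
  out
}
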