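#' Normalized-difference spectral index (NDSI) of two bands
#'
#' `NDSI(a, b) = (R_a - R_b) / (R_a + R_b)`.  With non-negative reflectance
#' every finite NDSI lies in \[-1, 1\], is antisymmetric in its band
#' arguments, and is invariant to rescaling the whole spectrum by a
#' positive constant.  A zero denominator yields `NA` (an explicit
#' undefined-value marker), never a silent zero.
#'
#' @param spectrum a [spectrum()] object.
#' @param lambda_a,lambda_b band wavelengths in nm (resolved to the nearest
#'   grid band via [band_at()]).
#' @return the index value, or `NA` if the denominator is zero.
#' @examples
#' s <- spectrum(c(670, 780), c(0.05, 0.5))
#' ndsi(s, 780, 670)   # NDVI-style contrast, 0.818...
#' @export
ndsi <- function(spectrum, lambda_a, lambda_b) {
  if (isTRUE(all.equal(lambda_a, lambda_b)))
    stop("lambda_a and lambda_b must differ")
  ra <- band_at(spectrum, lambda_a)
  rb <- band_at(spectrum, lambda_b)
  den <- ra + rb
  if (den == 0) return(NA_real_)
  (ra - rb) / den
}

#' The 12-index NDSI battery for wheat biomass and nitrogen status
#'
#' Band pairs of the standard battery of normalized-difference indices
#' evaluated against biomass and nitrogen traits of tillering wheat,
#' including NDVI (780, 670) and the red-edge family (760_730, 780_740,
#' ...).  All twelve share the symmetric normalized form
#' `(R_a - R_b)/(R_a + R_b)`; the 624_572 index in particular is computed
#' with the symmetric denominator `R_624 + R_572` matching its name.
#'
#' @return a data frame with columns `name`, `lambda_a`, `lambda_b`.
#' @seealso [index_battery()]
#' @export
ndsi_battery_definitions <- function() {
  data.frame(
    name = c("590_550", "624_572", "710_640", "760_550", "760_730",
             "780_670", "780_720", "780_740", "800_720", "820_660",
             "850_730", "952_720"),
    lambda_a = c(590, 624, 710, 760, 760, 780, 780, 780, 800, 820, 850, 952),
    lambda_b = c(550, 572, 640, 550, 730, 670, 720, 740, 720, 660, 730, 720),
    stringsAsFactors = FALSE)
}

#' Wavelengths used by the optimized-index selection
#'
#' The 19 wavelengths (nm) from which the battery's optimized
#' normalized-difference indices are formed.
#'
#' @return integer vector of 19 wavelengths.
#' @export
selected_wavelengths <- function() {
  c(550L, 572L, 590L, 624L, 640L, 656L, 660L, 670L, 710L, 720L, 730L,
    740L, 760L, 774L, 780L, 800L, 820L, 850L, 952L)
}

#' Evaluate the 12-index NDSI battery on one spectrum
#'
#' @param spectrum a [spectrum()] object whose grid resolves all 19
#'   [selected_wavelengths()].
#' @return named numeric vector of the 12 index values (named `590_550`,
#'   ..., `952_720`; `780_670` is NDVI).  Indices whose bands cannot be
#'   resolved, or whose denominator is zero, are `NA`.
#' @export
index_battery <- function(spectrum) {
  defs <- ndsi_battery_definitions()
  vals <- vapply(seq_len(nrow(defs)), function(i) {
    tryCatch(ndsi(spectrum, defs$lambda_a[i], defs$lambda_b[i]),
             error = function(e) NA_real_)
  }, numeric(1))
  names(vals) <- defs$name
  vals
}

#' NDSI battery table for a set of spectra
#'
#' @param spectra list of [spectrum()] objects.
#' @return data frame with `plot_id`, `date_id` and one column per battery
#'   index.
#' @export
battery_table <- function(spectra) {
  stopifnot(all(vapply(spectra, inherits, TRUE, "spectrum")))
  vals <- t(vapply(spectra, index_battery,
                   numeric(nrow(ndsi_battery_definitions()))))
  data.frame(
    plot_id = vapply(spectra, `[[`, "", "plot_id"),
    date_id = vapply(spectra, `[[`, "", "date_id"),
    vals, check.names = FALSE, stringsAsFactors = FALSE)
}
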