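#' A single plot reflectance spectrum
#'
#' Holds one plot's reflectance on a fixed wavelength grid.  The default
#' sensor grid runs 302--1148 nm at 2 nm bandwidth, but the grid is
#' data-defined: any strictly increasing grid is accepted.
#'
#' Reflectance is stored as a unitless fraction; values up to 1.5 are
#' tolerated (calibration against a reference standard can overshoot 1 in
#' the field).  Use `dialect = "percent"` in [read_spectra_csv()] for files
#' storing percent reflectance.
#'
#' @param wavelengths numeric, strictly increasing, in nm.
#' @param reflectance numeric, same length, finite, in \[0, 1.5\].
#' @param plot_id,date_id identifiers carried through the analysis.
#' @return an object of class `"spectrum"`.
#' @examples
#' s <- spectrum(seq(302, 1148, 2), rep(0.3, 424), "P01", "D1")
#' band_at(s, 670)
#' @export
spectrum <- function(wavelengths, reflectance, plot_id = NA_character_,
                     date_id = NA_character_) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) != length(reflectance))
    stop("wavelengths and reflectance lengths differ")
  if (length(wavelengths) < 2L) stop("a spectrum needs at least two bands")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(reflectance) || any(!is.finite(reflectance)))
    stop("reflectance must be finite")
  if (any(reflectance < 0) || any(reflectance > 1.5))
    stop("reflectance outside [0, 1.5]; use dialect = 'percent' if the data are in percent")
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 plot_id = as.character(plot_id),
                 date_id = as.character(date_id)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum %s / %s: %d bands, %g-%g nm, reflectance %.3f-%.3f\n",
              x$plot_id, x$date_id, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

#' Reflectance at (or nearest to) a requested wavelength
#'
#' Returns the band whose center is nearest to the request.  A request
#' exactly halfway between two bands resolves to the lower wavelength.
#' Requests outside the grid span, or farther than half the local grid step
#' from any band center, are errors.
#'
#' @param spectrum a [spectrum()] object.
#' @param wavelength requested wavelength in nm.
#' @return the reflectance value of the matched band.
#' @export
band_at <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "spectrum"), length(wavelength) == 1L)
  wl <- spectrum$wavelengths
  if (wavelength < wl[1] || wavelength > wl[length(wl)])
    stop(sprintf("wavelength %g nm outside grid span %g-%g nm",
                 wavelength, wl[1], wl[length(wl)]))
  idx <- nearest_band_index(wl, wavelength)
  step <- min(diff(wl))
  if (abs(wl[idx] - wavelength) > step / 2 + 1e-9)
    stop(sprintf("no band within half a grid step of %g nm", wavelength))
  spectrum$reflectance[idx]
}

# nearest grid index; exact half-step ties resolve to the lower wavelength
nearest_band_index <- function(wl, wavelength) {
  i <- findInterval(wavelength, wl, all.inside = TRUE)
  lo <- abs(wavelength - wl[i])
  hi <- abs(wl[i + 1] - wavelength)
  if (hi < lo) i + 1L else i          # tie (hi == lo) -> lower band
}

#' Stack a list of spectra into a plots-by-bands matrix
#'
#' All spectra must share one wavelength grid.
#'
#' @param spectra list of [spectrum()] objects.
#' @return a list with `X` (numeric matrix, one row per spectrum, columns
#'   named by wavelength), `wavelengths`, and `ids` (data frame of
#'   `plot_id`, `date_id`).
#' @export
spectra_to_matrix <- function(spectra) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "spectrum")))
  wl <- spectra[[1]]$wavelengths
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavelengths, wl)))
      stop("spectra are not on a common wavelength grid")
  X <- do.call(rbind, lapply(spectra, `[[`, "reflectance"))
  colnames(X) <- format(wl, trim = TRUE)
  ids <- data.frame(
    plot_id = vapply(spectra, `[[`, "", "plot_id"),
    date_id = vapply(spectra, `[[`, "", "date_id"),
    stringsAsFactors = FALSE)
  list(X = X, wavelengths = wl, ids = ids)
}

#' Write spectra to a wide CSV
#'
#' Layout: `plot_id, date_id`, then one column per band named by its
#' wavelength in nm (`302, 304, ...`).
#'
#' @param spectra list of [spectrum()] objects on a common grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  m <- spectra_to_matrix(spectra)
  df <- cbind(m$ids, as.data.frame(m$X, check.names = FALSE))
  write_csv_full(df, path)
}

#' Read spectra from CSV (wide or long layout)
#'
#' Wide layout: `plot_id, date_id, <nm>, <nm>, ...`.  Long layout:
#' `plot_id, date_id, wavelength, reflectance`.
#'
#' @param path CSV path.
#' @param format `"wide"` or `"long"`.
#' @param dialect `"fraction"` (default) or `"percent"`; percent values are
#'   divided by 100 on load.
#' @return list of [spectrum()] objects.
#' @export
read_spectra_csv <- function(path, format = c("wide", "long"),
                             dialect = c("fraction", "percent")) {
  format <- match.arg(format)
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  scl <- if (dialect == "percent") 1 / 100 else 1
  if (format == "wide") {
    bandcols <- setdiff(names(df), c("plot_id", "date_id"))
    wl <- as.numeric(bandcols)
    if (anyNA(wl)) stop("wide CSV band columns must be numeric wavelengths")
    o <- order(wl)
    lapply(seq_len(nrow(df)), function(i)
      spectrum(wl[o], as.numeric(df[i, bandcols[o]]) * scl,
               df$plot_id[i], df$date_id[i]))
  } else {
    need <- c("plot_id", "date_id", "wavelength", "reflectance")
    if (!all(need %in% names(df)))
      stop("long CSV needs columns plot_id, date_id, wavelength, reflectance")
    keys <- unique(df[, c("plot_id", "date_id")])
    lapply(seq_len(nrow(keys)), function(i) {
      sub <- df[df$plot_id == keys$plot_id[i] & df$date_id == keys$date_id[i], ]
      sub <- sub[order(sub$wavelength), ]
      spectrum(sub$wavelength, sub$reflectance * scl,
               keys$plot_id[i], keys$date_id[i])
    })
  }
}
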