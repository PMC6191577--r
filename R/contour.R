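#' Contour map: R2 of a trait against every two-band NDSI
#'
#' For every unordered pair of bands within `wavelength_range`, computes the
#' normalized-difference index `(R_i - R_j)/(R_i + R_j)` per plot and the
#' simple-linear-regression coefficient of determination against the trait.
#' The resulting square matrix ("contour map") is symmetric — swapping the
#' pair order flips the sign of the predictor, which leaves R2 unchanged —
#' and its diagonal (`NDSI == 0`) is masked.  Pairs whose index is
#' undefined for any plot (zero denominator) are masked as `NA` and
#' counted in `n_masked`.
#'
#' The inner loop is vectorized over bands; R2 is computed via the
#' squared-correlation identity `R2 = cor(y, v)^2`, which for simple linear
#' regression equals `1 - SSE/SST` from the least-squares fit.
#'
#' @param spectra list of [spectrum()] objects on a common grid.
#' @param traits numeric trait vector aligned with `spectra` (>= 3 values,
#'   not constant).
#' @param wavelength_range `c(lo, hi)` in nm; bands outside are excluded.
#'   Default 302--1048 nm, the standard span for the two-band search.
#' @param trait_name label stored in the result.
#' @return an object of class `"contour_map"`: list with `wavelengths`,
#'   `r2` (square matrix, `NA`-masked diagonal), `trait_name`,
#'   `n_dates_averaged` (1), `n`, `n_masked`.
#' @export
contour_map_for_trait <- function(spectra, traits,
                                  wavelength_range = c(302, 1048),
                                  trait_name = deparse(substitute(traits))) {
  m <- spectra_to_matrix(spectra)
  y <- as.numeric(traits)
  n <- length(y)
  if (n != nrow(m$X)) stop("traits not aligned with spectra")
  if (n < 3L) stop("insufficient data: need at least 3 aligned observations")
  if (stats::sd(y) == 0) stop("degenerate regression: trait vector is constant")
  if (length(wavelength_range) != 2L || wavelength_range[1] >= wavelength_range[2])
    stop("wavelength_range must be c(lo, hi) with lo < hi")
  keep <- m$wavelengths >= wavelength_range[1] &
          m$wavelengths <= wavelength_range[2]
  if (sum(keep) < 2L) stop("wavelength_range covers fewer than 2 bands")
  X <- m$X[, keep, drop = FALSE]
  wl <- m$wavelengths[keep]
  B <- length(wl)

  yc <- y - mean(y)
  ssy <- sum(yc^2)
  r2 <- matrix(NA_real_, B, B, dimnames = list(wl, wl))
  for (j in seq_len(B)) {
    V <- (X - X[, j]) / (X + X[, j])      # NDSI(lambda_i, lambda_j), all i
    bad <- colSums(!is.finite(V)) > 0
    V[, bad] <- 0
    Vc <- sweep(V, 2L, colMeans(V))
    ssv <- colSums(Vc^2)
    num <- colSums(Vc * yc)
    r <- num^2 / (ssv * ssy)
    r[bad | ssv == 0] <- NA_real_
    r2[, j] <- r
  }
  diag(r2) <- NA_real_
  n_masked <- sum(is.na(r2[upper.tri(r2)]))
  structure(list(wavelengths = wl, r2 = r2, trait_name = trait_name,
                 n_dates_averaged = 1L, n = n, n_masked = n_masked),
            class = "contour_map")
}

#' Average contour maps across sampling dates
#'
#' Entrywise arithmetic mean of the R2 matrices (equal weight per date).
#' Cells masked in any input map stay masked.
#'
#' @param maps list of `"contour_map"` objects on one grid for one trait.
#' @return a `"contour_map"` with `n_dates_averaged = length(maps)`.
#' @export
mean_contour_map <- function(maps) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, TRUE, "contour_map")))
  wl <- maps[[1]]$wavelengths
  tn <- maps[[1]]$trait_name
  for (mp in maps) {
    if (!isTRUE(all.equal(mp$wavelengths, wl)))
      stop("contour maps are not on a common wavelength grid")
    if (!identical(mp$trait_name, tn))
      stop("contour maps are for different traits")
  }
  r2 <- Reduce(`+`, lapply(maps, `[[`, "r2")) / length(maps)  # NA propagates
  structure(list(wavelengths = wl, r2 = r2, trait_name = tn,
                 n_dates_averaged = length(maps),
                 n = sum(vapply(maps, `[[`, 0L, "n")),
                 n_masked = sum(is.na(r2[upper.tri(r2)]))),
            class = "contour_map")
}

#' Best (optimized) wavelength pair of a contour map
#'
#' Global argmax of the off-diagonal R2 entries.  Exact ties resolve to the
#' lexicographically smallest pair (smaller `lambda_a`, then smaller
#' `lambda_b`), so the selection is deterministic.
#'
#' @param map a `"contour_map"`.
#' @return an object of class `"best_pair"`: list with `lambda_a <
#'   lambda_b` (nm) and `mean_r2`.
#' @export
select_best_pair <- function(map) {
  stopifnot(inherits(map, "contour_map"))
  m <- map$r2
  m[lower.tri(m, diag = TRUE)] <- NA_real_
  if (all(is.na(m))) stop("no valid (unmasked) wavelength pair in map")
  mx <- max(m, na.rm = TRUE)
  hits <- which(m == mx, arr.ind = TRUE)       # row < col in upper triangle
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  structure(list(lambda_a = map$wavelengths[i],
                 lambda_b = map$wavelengths[j], mean_r2 = mx,
                 trait_name = map$trait_name,
                 n_dates_averaged = map$n_dates_averaged),
            class = "best_pair")
}

#' @export
print.best_pair <- function(x, ...) {
  cat(sprintf("Best NDSI pair for %s: (%g, %g) nm, mean R2 = %.3f (%d date%s)\n",
              x$trait_name, x$lambda_a, x$lambda_b, x$mean_r2,
              x$n_dates_averaged, ifelse(x$n_dates_averaged == 1, "", "s")))
  invisible(x)
}

#' @export
print.contour_map <- function(x, ...) {
  cat(sprintf("Contour map for %s: %d bands (%g-%g nm), %d date%s, n = %d\n",
              x$trait_name, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$n_dates_averaged,
              ifelse(x$n_dates_averaged == 1, "", "s"), x$n))
  cat(sprintf("  off-diagonal R2: max %.3f, masked cells %d\n",
              max(x$r2, na.rm = TRUE), x$n_masked))
  invisible(x)
}

#' Write a contour map as CSV (wavelength header row and column)
#'
#' @param map a `"contour_map"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(map, path) {
  df <- data.frame(wavelength = map$wavelengths,
                   map$r2, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Ranked wavelength-pair list of a contour map
#'
#' @param map a `"contour_map"`.
#' @param top number of pairs to return (default 20).
#' @return data frame `lambda_a`, `lambda_b`, `r2`, sorted decreasing with
#'   lexicographic tie-break.
#' @export
rank_pairs <- function(map, top = 20L) {
  stopifnot(inherits(map, "contour_map"))
  m <- map$r2
  m[lower.tri(m, diag = TRUE)] <- NA_real_
  idx <- which(!is.na(m), arr.ind = TRUE)
  df <- data.frame(lambda_a = map$wavelengths[idx[, 1]],
                   lambda_b = map$wavelengths[idx[, 2]],
                   r2 = m[idx])
  df <- df[order(-df$r2, df$lambda_a, df$lambda_b), ]
  utils::head(df, top)
}

#' Level plot of a contour map
#'
#' Convenience display via `lattice::levelplot` (suggested package).
#'
#' @param map a `"contour_map"`.
#' @param ... passed to `lattice::levelplot`.
#' @return the lattice plot object.
#' @export
plot_contour_map <- function(map, ...) {
  if (!requireNamespace("lattice", quietly = TRUE))
    stop("package 'lattice' is needed for plotting contour maps")
  lattice::levelplot(map$r2, row.values = map$wavelengths,
                     column.values = map$wavelengths,
                     xlab = "wavelength (nm)", ylab = "wavelength (nm)",
                     main = sprintf("R2, %s", map$trait_name), ...)
}
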