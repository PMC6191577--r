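#' Soil and vegetation spectral endmembers
#'
#' Generic textbook endmember shapes on the sensor grid, used by the linear
#' mixing model of [generate_spectrum()]:
#'
#' * soil: a bright, featureless spectrum rising monotonically from ~0.10
#'   at 302 nm to ~0.40 at 1148 nm — the typical bare-soil shape;
#' * vegetation: a green-leaf spectrum parameterized by a chlorophyll proxy
#'   affine in the nitrogen concentration.  Higher N deepens the red
#'   (~670 nm) absorption (0.18 down to 0.04) and shifts the red-edge
#'   inflection from 710 to 725 nm; a Gaussian green bump sits at 550 nm
#'   and the NIR plateau is 0.48.
#'
#' By construction vegetation NIR reflectance (>= 760 nm) exceeds its red
#' reflectance, and vegetation red stays below soil red while vegetation
#' NIR stays above soil NIR, so increasing cover raises NIR, lowers red,
#' and raises NDVI.
#'
#' @param wavelengths grid in nm.
#' @return an object of class `"endmembers"`: list with `wavelengths`,
#'   `soil` (reflectance vector) and `vegetation`, a `function(n_conc)`
#'   returning the vegetation reflectance vector.
#' @export
make_endmembers <- function(wavelengths = seq(302, 1148, by = 2)) {
  wl <- as.numeric(wavelengths)
  soil <- 0.10 + 0.30 * (wl - 302) / (1148 - 302)
  soil <- pmin(pmax(soil, 0), 1)
  vegetation <- function(n_conc) {
    stopifnot(length(n_conc) == 1L, n_conc > 0)
    chl <- pmin(pmax((n_conc - 1) / 4, 0), 1)   # chlorophyll proxy in [0,1]
    r_red <- 0.18 - 0.14 * chl                  # red-band depth, affine in N
    vis <- r_red + 0.06 * exp(-((wl - 550) / 45)^2)
    edge <- 710 + 15 * chl                      # red-edge inflection (nm)
    s <- 1 / (1 + exp(-(wl - edge) / 12))
    pmin(pmax(vis + (0.48 - vis) * s, 0), 1)
  }
  structure(list(wavelengths = wl, soil = soil, vegetation = vegetation),
            class = "endmembers")
}

#' Simulate one plot reflectance spectrum by linear spectral mixing
#'
#' `R(lambda) = f * R_veg(lambda; n_conc) + (1 - f) * R_soil(lambda) + eps`,
#' where `f = fractional_cover(dry_weight, k)` and `eps` is i.i.d. Gaussian
#' band noise of SD `scenario$noise_sd_spectral` (the result is clamped to
#' \[0, 1\]).  With zero noise the spectrum is a deterministic function of
#' the plot's traits.
#'
#' @param trait one-row data frame (or list) with `dry_weight`, `n_conc`,
#'   `plot_id`, `date_id`.
#' @param endmembers a [make_endmembers()] object on the scenario grid.
#' @param scenario the [canopy_scenario()] supplying `cover_saturation_k`,
#'   `noise_sd_spectral` and the grid.
#' @return a [spectrum()] object.
#' @export
generate_spectrum <- function(trait, endmembers, scenario) {
  stopifnot(inherits(endmembers, "endmembers"),
            inherits(scenario, "canopy_scenario"))
  if (!isTRUE(all.equal(endmembers$wavelengths, scenario$wavelengths)))
    stop("endmember grid does not match the scenario sensor grid")
  f <- fractional_cover(trait$dry_weight, scenario$cover_saturation_k)
  r <- f * endmembers$vegetation(trait$n_conc) + (1 - f) * endmembers$soil
  if (scenario$noise_sd_spectral > 0)
    r <- r + stats::rnorm(length(r), sd = scenario$noise_sd_spectral)
  spectrum(scenario$wavelengths, pmin(pmax(r, 0), 1),
           trait$plot_id, trait$date_id)
}

#' Simulate spectra for a whole trait table
#'
#' Deterministic in the scenario seed (independent of whether traits and
#' spectra are generated in one session or separately).
#'
#' @param traits data frame from [generate_traits()].
#' @param scenario the [canopy_scenario()].
#' @param endmembers optional [make_endmembers()]; defaults to endmembers
#'   on the scenario grid.
#' @return list of [spectrum()] objects, one per trait row.
#' @export
generate_spectra <- function(traits, scenario,
                             endmembers = make_endmembers(scenario$wavelengths)) {
  with_seed(scenario$seed + 2L,
    lapply(seq_len(nrow(traits)), function(i)
      generate_spectrum(traits[i, ], endmembers, scenario)))
}
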