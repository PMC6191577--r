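#' Define a synthetic canopy scenario
#'
#' A scenario bundles everything the generator needs to emulate a
#' plot-level field campaign at early cereal growth stages: per-date trait
#' summaries (min/mean/max for fresh weight, dry weight, N concentration
#' and N uptake), the canopy-closure rate constant linking dry biomass to
#' fractional cover, noise scales, and the master seed.  The seed fully
#' determines every generated output (traits, spectra, images).
#'
#' @param name scenario label.
#' @param n_plots number of plots observed at each date.
#' @param dates data frame with columns `date_id` and `bbch` (integer
#'   growth-stage code).
#' @param trait_distributions named list (one entry per `date_id`); each
#'   entry a named list of `c(min, mean, max)` vectors for `fresh_weight`,
#'   `dry_weight` (kg/ha), `n_conc` (% of dry weight) and `n_uptake`
#'   (kg/ha; emulation target only — uptake itself is always derived as
#'   `dry_weight * n_conc / 100`).
#' @param cover_saturation_k canopy-closure rate constant (ha/kg) of the
#'   Beer--Lambert-style cover model `f = 1 - exp(-k * dry_weight)`.
#' @param noise_sd_spectral additive Gaussian reflectance noise SD per band.
#' @param noise_sd_trait relative trait measurement noise SD (values are
#'   jittered multiplicatively, then clamped back into \[min, max\]).
#' @param rho_dilution within-date latent correlation between dry weight
#'   and N concentration (negative: heavier plots are more diluted).
#' @param wavelengths sensor grid in nm (default 302--1148 at 2 nm).
#' @param seed master seed (integer).
#' @return an object of class `"canopy_scenario"`.
#' @seealso [scenario_2014()], [scenario_2016()], [generate_traits()],
#'   [generate_dataset()]
#' @export
canopy_scenario <- function(name, n_plots, dates, trait_distributions,
                            cover_saturation_k = 4.4e-4,
                            noise_sd_spectral = 0.005,
                            noise_sd_trait = 0.03,
                            rho_dilution = -0.35,
                            wavelengths = seq(302, 1148, by = 2),
                            seed = 1L) {
  stopifnot(is.data.frame(dates), all(c("date_id", "bbch") %in% names(dates)),
            n_plots >= 1, cover_saturation_k > 0,
            noise_sd_spectral >= 0, noise_sd_trait >= 0,
            rho_dilution > -1, rho_dilution < 1)
  dates$date_id <- as.character(dates$date_id)
  if (anyDuplicated(dates$date_id)) stop("duplicate date_id in scenario")
  need <- c("fresh_weight", "dry_weight", "n_conc", "n_uptake")
  for (d in dates$date_id) {
    td <- trait_distributions[[d]]
    if (is.null(td)) stop(sprintf("no trait distributions for date %s", d))
    for (tr in need) {
      v <- td[[tr]]
      if (is.null(v) || length(v) != 3L)
        stop(sprintf("%s / %s must be c(min, mean, max)", d, tr))
      if (v[1] > v[3] || v[2] < v[1] || v[2] > v[3])
        stop(sprintf("infeasible distribution target for %s / %s: need min <= mean <= max",
                     d, tr))
    }
  }
  structure(list(name = name, n_plots = as.integer(n_plots), dates = dates,
                 trait_distributions = trait_distributions,
                 cover_saturation_k = cover_saturation_k,
                 noise_sd_spectral = noise_sd_spectral,
                 noise_sd_trait = noise_sd_trait,
                 rho_dilution = rho_dilution,
                 wavelengths = as.numeric(wavelengths),
                 seed = as.integer(seed)),
            class = "canopy_scenario")
}

#' @export
print.canopy_scenario <- function(x, ...) {
  cat(sprintf("Canopy scenario '%s': %d plots x %d dates (BBCH %s), seed %d\n",
              x$name, x$n_plots, nrow(x$dates),
              paste(x$dates$bbch, collapse = ", "), x$seed))
  invisible(x)
}

#' The default "2014-like" scenario
#'
#' 64 plots sampled at four dates (BBCH 19, 22, 25, 30), with per-date
#' trait summaries emulating a season fertilized once just before the first
#' sampling: dry and fresh biomass rise steeply across stages while the
#' nitrogen concentration falls from 3.2% to 2.0% — the classic N-dilution
#' pattern.
#'
#' @param seed master seed (default 1).
#' @param ... overrides passed on to [canopy_scenario()].
#' @return a `"canopy_scenario"`.
#' @export
scenario_2014 <- function(seed = 1L, ...) {
  dists <- list(
    "2014-03-04" = list(fresh_weight = c(968, 1913.6, 3704),
                        dry_weight   = c(232, 450.4, 972),
                        n_conc       = c(2.2, 3.2, 4.9),
                        n_uptake     = c(6.8, 14.4, 29.2)),
    "2014-03-17" = list(fresh_weight = c(1452, 2952.4, 4812),
                        dry_weight   = c(340, 758.4, 1452),
                        n_conc       = c(1.9, 2.6, 3.6),
                        n_uptake     = c(8.0, 19.6, 34.8)),
    "2014-04-01" = list(fresh_weight = c(1900, 5306.4, 10324),
                        dry_weight   = c(472, 1218.8, 2340),
                        n_conc       = c(1.5, 2.4, 3.3),
                        n_uptake     = c(10.4, 29.2, 58.0)),
    "2014-04-14" = list(fresh_weight = c(2552, 9186.8, 15454),
                        dry_weight   = c(632, 2206.0, 4304),
                        n_conc       = c(1.3, 2.0, 3.1),
                        n_uptake     = c(10.0, 44.8, 94.0)))
  args <- list(name = "2014-like", n_plots = 64L,
               dates = data.frame(date_id = names(dists),
                                  bbch = c(19L, 22L, 25L, 30L)),
               trait_distributions = dists, seed = seed)
  do.call(canopy_scenario, utils::modifyList(args, list(...)))
}

#' The "2016-like" verification scenario
#'
#' 30 field sites sampled at two dates (BBCH 19, 22) with fertilization
#' between the samplings, so the nitrogen concentration *rises* from 3.1%
#' to 5.0% while biomass grows — the counter-case to the dilution pattern.
#' Fresh weight summaries are derived from dry weight with early-season
#' fresh:dry ratios (4.2 and 3.9), as only dry weight is summarized for
#' this campaign type.
#'
#' @inheritParams scenario_2014
#' @return a `"canopy_scenario"`.
#' @export
scenario_2016 <- function(seed = 1L, ...) {
  dists <- list(
    "2016-03-29" = list(fresh_weight = 4.2 * c(232.8, 385.5, 573.2),
                        dry_weight   = c(232.8, 385.5, 573.2),
                        n_conc       = c(2.6, 3.1, 3.8),
                        n_uptake     = c(8.1, 12.0, 17.0)),
    "2016-04-04" = list(fresh_weight = 3.9 * c(365.2, 548.1, 826.0),
                        dry_weight   = c(365.2, 548.1, 826.0),
                        n_conc       = c(4.4, 5.0, 5.4),
                        n_uptake     = c(18.1, 27.3, 41.1)))
  args <- list(name = "2016-like", n_plots = 30L,
               dates = data.frame(date_id = names(dists),
                                  bbch = c(19L, 22L)),
               trait_distributions = dists, seed = seed)
  do.call(canopy_scenario, utils::modifyList(args, list(...)))
}

#' Look up a built-in scenario by name
#'
#' @param name `"2014"` / `"2014-like"` or `"2016"` / `"2016-like"`.
#' @param seed master seed.
#' @param ... overrides passed to the scenario constructor.
#' @return a `"canopy_scenario"`.
#' @export
builtin_scenario <- function(name, seed = 1L, ...) {
  switch(sub("-like$", "", as.character(name)),
         "2014" = scenario_2014(seed = seed, ...),
         "2016" = scenario_2016(seed = seed, ...),
         stop(sprintf("unknown scenario '%s'", name)))
}
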