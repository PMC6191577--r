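#' Generate a complete synthetic plot dataset
#'
#' Runs the full generator for a scenario: trait records
#' ([generate_traits()]), mixed soil--vegetation reflectance spectra
#' ([generate_spectra()]) and, optionally, RGB canopy images whose green
#' fraction is `100 * fractional_cover(dry_weight, k)`
#' ([generate_image()]).  Everything is a deterministic function of the
#' scenario seed.  When `dir` is given the dataset is also written to disk:
#' `traits.csv`, `spectra.csv` (wide layout), `images/<plot>_<date>.png`
#' and `scenario.json`.
#'
#' @param scenario a [canopy_scenario()].
#' @param dir optional output directory (created if missing).
#' @param images generate images? (default `TRUE`).
#' @param image_size `c(width, height)` in pixels, default 128 x 128.
#' @param style image style passed to [generate_image()]; the default
#'   follows the scenario: `winter_stressed` for the 2014-like season
#'   (cold-winter leaf discoloration), `clean` otherwise.
#' @return list with `traits` (data frame, including the generated
#'   `cover_pct` target per plot-date), `spectra` (list of [spectrum()]),
#'   `images` (list of [generate_image()] results, or `NULL`), and
#'   `scenario`.
#' @export
generate_dataset <- function(scenario, dir = NULL, images = TRUE,
                             image_size = c(128L, 128L),
                             style = if (grepl("^2014", scenario$name))
                               "winter_stressed" else "clean") {
  stopifnot(inherits(scenario, "canopy_scenario"))
  traits <- generate_traits(scenario)
  spectra <- generate_spectra(traits, scenario)
  traits$cover_pct <-
    100 * fractional_cover(traits$dry_weight, scenario$cover_saturation_k)

  imgs <- NULL
  if (images) {
    imgs <- lapply(seq_len(nrow(traits)), function(i) {
      generate_image(traits$cover_pct[i], image_size[1], image_size[2],
                     style = style,
                     seed = (scenario$seed + 7919L * i) %% .Machine$integer.max)
    })
    names(imgs) <- paste(traits$plot_id, traits$date_id, sep = "_")
  }

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_traits_csv(traits, file.path(dir, "traits.csv"))
    write_spectra_csv(spectra, file.path(dir, "spectra.csv"))
    write_scenario_json(scenario, file.path(dir, "scenario.json"))
    if (images) {
      imgdir <- file.path(dir, "images")
      dir.create(imgdir, showWarnings = FALSE)
      for (nm in names(imgs))
        write_image_png(imgs[[nm]]$image,
                        file.path(imgdir, paste0(nm, ".png")))
    }
  }
  list(traits = traits, spectra = spectra, images = imgs,
       scenario = scenario)
}

#' Serialize a scenario to JSON
#'
#' @param scenario a [canopy_scenario()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario_json <- function(scenario, path) {
  x <- unclass(scenario)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
  invisible(path)
}

#' Read a scenario back from JSON
#'
#' @param path JSON path written by [write_scenario_json()].
#' @return a [canopy_scenario()].
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dists <- lapply(x$trait_distributions, function(td) lapply(td, as.numeric))
  canopy_scenario(name = x$name, n_plots = x$n_plots,
                  dates = as.data.frame(x$dates),
                  trait_distributions = dists,
                  cover_saturation_k = x$cover_saturation_k,
                  noise_sd_spectral = x$noise_sd_spectral,
                  noise_sd_trait = x$noise_sd_trait,
                  rho_dilution = x$rho_dilution,
                  wavelengths = x$wavelengths,
                  seed = x$seed)
}
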