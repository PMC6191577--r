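#' Align trait, spectral and image observations on (plot, date) keys
#'
#' Inner join of the trait table, the spectra and (optionally) the
#' green-fraction table on the `(plot_id, date_id)` key.  Sensor readings
#' and destructive samplings belong to the same plot and day, so any key
#' present in one table but not another is an inconsistency: orphans are
#' reported in the diagnostics and the analysis proceeds on the
#' intersection; only an empty intersection is an error.  Duplicate keys
#' within a table are ambiguous and raise an error.
#'
#' @param traits trait data frame with `plot_id`, `date_id` columns.
#' @param spectra list of [spectrum()] objects.
#' @param green optional data frame with `plot_id`, `date_id`,
#'   `green_pct` (from [batch_green_fraction()]).
#' @return list with `data` (traits joined with `green_pct` where
#'   available, ordered by key), `spectra` (reordered to match `data`
#'   rows) and `diagnostics` (orphaned keys per source).
#' @export
align_observations <- function(traits, spectra, green = NULL) {
  key <- function(p, d) paste(p, d, sep = "\r")
  tk <- key(traits$plot_id, traits$date_id)
  if (anyDuplicated(tk)) stop("duplicate (plot_id, date_id) keys in traits")
  sk <- key(vapply(spectra, `[[`, "", "plot_id"),
            vapply(spectra, `[[`, "", "date_id"))
  if (anyDuplicated(sk)) stop("duplicate (plot_id, date_id) keys in spectra")
  common <- intersect(tk, sk)
  gk <- NULL
  if (!is.null(green)) {
    gk <- key(green$plot_id, green$date_id)
    if (anyDuplicated(gk))
      stop("duplicate (plot_id, date_id) keys in green table")
    common <- intersect(common, gk)
  }
  if (length(common) == 0L)
    stop("empty intersection of (plot_id, date_id) keys")
  diagnostics <- list(
    traits_only = sub("\r", "_", setdiff(tk, common)),
    spectra_only = sub("\r", "_", setdiff(sk, common)),
    green_only = if (is.null(gk)) character(0) else
      sub("\r", "_", setdiff(gk, common)))
  n_orphans <- sum(lengths(diagnostics))
  if (n_orphans > 0)
    message(sprintf("align_observations: %d orphaned key(s) dropped; see diagnostics",
                    n_orphans))
  common <- sort(common)
  data <- traits[match(common, tk), , drop = FALSE]
  if (!is.null(green))
    data$green_pct <- green$green_pct[match(common, gk)]
  rownames(data) <- NULL
  list(data = data, spectra = spectra[match(common, sk)],
       diagnostics = diagnostics)
}

#' Build a pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic dataset, then analyze
#'   it) or `"analyze"` (analyze existing files).
#' @param out_dir output directory for the result bundle.
#' @param scenario a [canopy_scenario()] or a built-in scenario name
#'   (`"2014"`, `"2016"`); required in simulate mode.
#' @param traits_csv,spectra_csv,image_dir input paths (analyze mode).
#' @param thresholds [hsb_thresholds()] for green segmentation.
#' @param contour_range two-band search window in nm (default 302--1048).
#' @param plsr_range PLSR input window in nm (default 400--1000).
#' @param max_components,k_folds PLSR cross-validation settings.
#' @param quadratic_green also fit quadratic models for the green-pixel
#'   relationships (the curvilinear form seen once cover saturates)?
#' @param images simulate images / analyze an image directory?
#' @param image_size simulated image size `c(width, height)`.
#' @param seed master seed; in simulate mode overrides the scenario seed.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(mode = c("simulate", "analyze"), out_dir,
                       scenario = NULL, traits_csv = NULL,
                       spectra_csv = NULL, image_dir = NULL,
                       thresholds = hsb_thresholds(),
                       contour_range = c(302, 1048),
                       plsr_range = c(400, 1000),
                       max_components = 10L, k_folds = 7L,
                       quadratic_green = FALSE, images = TRUE,
                       image_size = c(128L, 128L), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(scenario)) stop("simulate mode needs a scenario")
    if (is.character(scenario))
      scenario <- builtin_scenario(scenario, seed = seed)
    else
      scenario$seed <- as.integer(seed)
  } else {
    for (p in c(traits_csv, spectra_csv))
      if (!is.null(p) && !file.exists(p)) stop(sprintf("input not found: %s", p))
    if (is.null(traits_csv) || is.null(spectra_csv))
      stop("analyze mode needs traits_csv and spectra_csv")
    if (images && (is.null(image_dir) || !dir.exists(image_dir)))
      stop("analyze mode with images needs an existing image_dir")
  }
  structure(list(mode = mode, out_dir = out_dir, scenario = scenario,
                 traits_csv = traits_csv, spectra_csv = spectra_csv,
                 image_dir = image_dir, thresholds = thresholds,
                 contour_range = contour_range, plsr_range = plsr_range,
                 max_components = as.integer(max_components),
                 k_folds = as.integer(k_folds),
                 quadratic_green = quadratic_green, images = images,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full canopy analysis pipeline
#'
#' Orchestrates the whole chain and writes a result bundle to
#' `config$out_dir`:
#'
#' 1. `data/` — the simulated dataset (simulate mode only);
#' 2. `green_traits.csv` — traits merged with image green fractions;
#' 3. `index_battery.csv` — the 12-index NDSI battery per plot-date;
#' 4. `contour_<trait>.csv` + `best_pairs.csv` — date-averaged two-band R2
#'    maps and the optimized pair per trait;
#' 5. `regression_linear.csv` (and `regression_green_quadratic.csv` when
#'    opted in) — R2-with-stars tables of indices and green fraction
#'    against the four traits, per date and pooled;
#' 6. `plsr_evaluation.csv` — cross-validated PLSR metrics per growth
#'    stage and pooled;
#' 7. `config.json` + `run_info.json` — provenance (config, seed, config
#'    file MD5).
#'
#' Identical config + seed gives a byte-identical bundle.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the main in-memory results (`aligned`,
#'   `battery`, `best_pairs`, `regression`, `plsr`) and `paths` of the
#'   written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  trait_cols <- c("fresh_weight", "dry_weight", "n_conc", "n_uptake")

  # --- stage 1: obtain data -------------------------------------------------
  if (config$mode == "simulate") {
    message(sprintf("simulating scenario '%s' (seed %d)",
                    config$scenario$name, config$scenario$seed))
    ds <- generate_dataset(config$scenario, dir = file.path(out, "data"),
                           images = config$images,
                           image_size = config$image_size)
    traits <- ds$traits
    spectra <- ds$spectra
    image_dir <- if (config$images) file.path(out, "data", "images") else NULL
  } else {
    traits <- read_traits_csv(config$traits_csv)
    spectra <- read_spectra_csv(config$spectra_csv, format = "wide")
    image_dir <- if (config$images) config$image_dir else NULL
  }

  # --- stage 2: green fractions from images --------------------------------
  green <- NULL
  if (!is.null(image_dir)) {
    paths <- sort(list.files(image_dir, pattern = "\\.png$",
                             full.names = TRUE))
    green <- batch_green_fraction(paths, config$thresholds)
  }

  aligned <- align_observations(traits, spectra, green)
  df <- aligned$data
  utils::write.csv(df, file.path(out, "green_traits.csv"), row.names = FALSE)

  # --- stage 3: index battery ----------------------------------------------
  battery <- battery_table(aligned$spectra)
  utils::write.csv(battery, file.path(out, "index_battery.csv"),
                   row.names = FALSE)

  # --- stage 4: contour maps and optimized pairs ---------------------------
  best <- list()
  for (tr in trait_cols) {
    maps <- lapply(unique(df$date_id), function(d) {
      sel <- df$date_id == d
      contour_map_for_trait(aligned$spectra[sel], df[[tr]][sel],
                            wavelength_range = config$contour_range,
                            trait_name = tr)
    })
    mmap <- mean_contour_map(maps)
    write_contour_csv(mmap, file.path(out, sprintf("contour_%s.csv", tr)))
    bp <- select_best_pair(mmap)
    best[[tr]] <- data.frame(trait = tr, lambda_a = bp$lambda_a,
                             lambda_b = bp$lambda_b, mean_r2 = bp$mean_r2)
  }
  best_pairs <- do.call(rbind, best)
  utils::write.csv(best_pairs, file.path(out, "best_pairs.csv"),
                   row.names = FALSE)

  # --- stage 5: simple-regression evaluation tables ------------------------
  preds <- ndsi_battery_definitions()$name
  regdf <- cbind(df, battery[, preds, drop = FALSE])
  if ("green_pct" %in% names(df)) preds <- c("green_pct", preds)
  reg <- regression_summary_table(regdf, preds, trait_cols,
                                  date_col = "date_id", model_form = "linear")
  utils::write.csv(cbind(predictor = rownames(reg), reg),
                   file.path(out, "regression_linear.csv"),
                   row.names = FALSE)
  if (config$quadratic_green && "green_pct" %in% names(df)) {
    regq <- regression_summary_table(regdf, "green_pct", trait_cols,
                                     date_col = "date_id",
                                     model_form = "quadratic")
    utils::write.csv(cbind(predictor = rownames(regq), regq),
                     file.path(out, "regression_green_quadratic.csv"),
                     row.names = FALSE)
  }

  # --- stage 6: PLSR evaluation --------------------------------------------
  m <- restrict_bands(spectra_to_matrix(aligned$spectra), config$plsr_range)
  plsr_tab <- plsr_evaluation_table(m, df, trait_cols,
                                    max_components = config$max_components,
                                    k_folds = config$k_folds,
                                    seed = config$seed)
  utils::write.csv(plsr_tab, file.path(out, "plsr_evaluation.csv"),
                   row.names = FALSE)

  # --- stage 7: provenance --------------------------------------------------
  cfg_path <- file.path(out, "config.json")
  cfg <- config
  cfg$thresholds <- unclass(cfg$thresholds)
  if (!is.null(cfg$scenario)) cfg$scenario <- unclass(cfg$scenario)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  jsonlite::write_json(
    list(seed = config$seed, config_md5 = unname(tools::md5sum(cfg_path)),
         n_observations = nrow(df),
         orphaned_keys = aligned$diagnostics),
    file.path(out, "run_info.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(aligned = aligned, battery = battery,
                 best_pairs = best_pairs, regression = reg,
                 plsr = plsr_tab,
                 paths = list.files(out, recursive = TRUE,
                                    full.names = TRUE)))
}
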