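test_that("generated traits respect ranges, identity and ordering", {
  sc <- scenario_2014(seed = 4)
  tr <- generate_traits(sc)
  expect_equal(nrow(tr), 64 * 4)
  for (d in unique(tr$date_id)) {
    td <- sc$trait_distributions[[d]]
    sub <- tr[tr$date_id == d, ]
    for (v in c("fresh_weight", "dry_weight", "n_conc")) {
      expect_gte(min(sub[[v]]), td[[v]][1])
      expect_lte(max(sub[[v]]), td[[v]][3])
    }
  }
  # uptake identity exact, dry <= fresh
  expect_identical(tr$n_uptake, tr$dry_weight * tr$n_conc / 100)
  expect_true(all(tr$dry_weight <= tr$fresh_weight))
  # dilution: mean dry weight rises, mean N concentration falls with stage
  mns <- aggregate(cbind(dry_weight, n_conc) ~ bbch, tr, mean)
  expect_true(all(diff(mns$dry_weight) > 0))
  expect_true(all(diff(mns$n_conc) < 0))
})

test_that("the 2016-like scenario reverses the concentration trend", {
  tr <- generate_traits(scenario_2016(seed = 4))
  mns <- aggregate(cbind(dry_weight, n_conc) ~ bbch, tr, mean)
  expect_true(all(diff(mns$dry_weight) > 0))
  expect_true(all(diff(mns$n_conc) > 0))   # fertilized between samplings
})

test_that("degenerate point-mass distributions give identical plots", {
  pm <- function(v) c(v, v, v)
  sc <- canopy_scenario(
    "point", n_plots = 5,
    dates = data.frame(date_id = "d1", bbch = 19L),
    trait_distributions = list(d1 = list(
      fresh_weight = pm(2000), dry_weight = pm(500),
      n_conc = pm(3), n_uptake = pm(15))),
    noise_sd_trait = 0)
  tr <- generate_traits(sc)
  expect_equal(unique(tr$dry_weight), 500)
  expect_equal(unique(tr$fresh_weight), 2000)
  expect_equal(unique(tr$n_conc), 3)
  expect_equal(unique(tr$n_uptake), 15)
})

test_that("infeasible distribution targets are configuration errors", {
  dists <- list(d1 = list(fresh_weight = c(100, 200, 300),
                          dry_weight = c(300, 200, 100),   # min > max
                          n_conc = c(1, 2, 3), n_uptake = c(1, 2, 3)))
  expect_error(
    canopy_scenario("bad", 4, data.frame(date_id = "d1", bbch = 19L), dists),
    "infeasible")
  dists$d1$dry_weight <- c(100, 400, 300)                  # mean > max
  expect_error(
    canopy_scenario("bad", 4, data.frame(date_id = "d1", bbch = 19L), dists),
    "infeasible")
})

test_that("fractional cover follows the saturating closure model", {
  expect_equal(fractional_cover(0, 1e-3), 0)
  expect_equal(fractional_cover(2206, 1e-3), 1 - exp(-2.206))
  expect_error(fractional_cover(-1, 1e-3), ">= 0")
  expect_error(fractional_cover(100, 0), "> 0")
  # strictly increasing, concave, bounded below 1
  w <- seq(0, 6000, by = 50)
  f <- fractional_cover(w, 4.4e-4)
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(diff(f)) < 0))
  expect_true(all(f < 1))
  # doubling biomass gains less than the first increment
  for (wi in c(200, 1000, 3000))
    expect_lt(fractional_cover(2 * wi, 4.4e-4) - fractional_cover(wi, 4.4e-4),
              fractional_cover(wi, 4.4e-4))
})

test_that("spectral mixing reproduces the endmember limits", {
  sc <- test_scenario(seed = 5, noise_sd_spectral = 0)
  em <- make_endmembers(sc$wavelengths)
  bare <- list(dry_weight = 0, n_conc = 3, plot_id = "P00", date_id = "d0")
  s <- generate_spectrum(bare, em, sc)
  expect_equal(s$reflectance, em$soil)                    # f = 0: pure soil
  # f -> 1 limit: huge biomass is essentially pure vegetation
  dense <- list(dry_weight = 1e7, n_conc = 3, plot_id = "P01", date_id = "d0")
  s2 <- generate_spectrum(dense, em, sc)
  expect_equal(s2$reflectance, em$vegetation(3), tolerance = 1e-8)
})

test_that("endmembers have the required spectral structure", {
  em <- make_endmembers()
  wl <- em$wavelengths
  vis <- wl >= 400 & wl <= 1000
  expect_true(all(diff(em$soil[vis]) >= 0))               # soil monotone
  for (nc in c(1.5, 2.5, 3.5, 5)) {
    v <- em$vegetation(nc)
    nir <- mean(v[wl >= 760 & wl <= 1000])
    red <- v[wl == 670]
    expect_gt(nir, red)
    expect_true(all(v >= 0 & v <= 1))
  }
  # deeper red absorption at higher nitrogen
  expect_lt(make_endmembers()$vegetation(4)[match(670, wl)],
            make_endmembers()$vegetation(2)[match(670, wl)])
})

test_that("NDVI rises strictly with dry weight at fixed N (no noise)", {
  sc <- test_scenario(seed = 6, noise_sd_spectral = 0)
  em <- make_endmembers(sc$wavelengths)
  ndvis <- vapply(c(100, 400, 900, 1800, 3200, 4300), function(w) {
    s <- generate_spectrum(list(dry_weight = w, n_conc = 2.5,
                                plot_id = "x", date_id = "d"), em, sc)
    ndsi(s, 780, 670)
  }, numeric(1))
  expect_true(all(diff(ndvis) > 0))
})

test_that("grid mismatch between endmembers and scenario is an error", {
  sc <- test_scenario(seed = 7)
  em <- make_endmembers(seq(400, 1000, 2))
  expect_error(generate_spectrum(list(dry_weight = 500, n_conc = 3,
                                      plot_id = "x", date_id = "d"), em, sc),
               "grid")
})

test_that("generated images plant the exact green-pixel count", {
  im <- generate_image(25, 128, 128, seed = 8)
  expect_equal(im$green_count, 4096)
  expect_equal(segment_green(im$image)$green_count, 4096)

  im0 <- generate_image(0, 32, 32, seed = 8)
  expect_equal(segment_green(im0$image)$green_count, 0)
  im100 <- generate_image(100, 32, 32, seed = 8)
  expect_equal(segment_green(im100$image)$green_count, 1024)

  # winter_stressed background stays out of the green band
  imw <- generate_image(61.9, 64, 64, style = "winter_stressed", seed = 9)
  res <- segment_green(imw$image)
  expect_equal(res$green_count, imw$green_count)
  expect_equal(res$green_pct, 61.9, tolerance = 100 / (64 * 64))

  expect_error(generate_image(101, 16, 16), "\\[0, 100\\]")
  expect_error(generate_image(-1, 16, 16), "\\[0, 100\\]")
})

test_that("identical scenario and seed give bit-identical outputs", {
  sc1 <- test_scenario(seed = 10, n_plots = 6)
  sc2 <- test_scenario(seed = 10, n_plots = 6)
  t1 <- generate_traits(sc1); t2 <- generate_traits(sc2)
  expect_identical(t1, t2)
  s1 <- generate_spectra(t1, sc1); s2 <- generate_spectra(t2, sc2)
  expect_identical(s1, s2)
  i1 <- generate_image(40, 24, 24, seed = 10)
  i2 <- generate_image(40, 24, 24, seed = 10)
  expect_identical(i1$image, i2$image)
  # a different seed changes the draw
  t3 <- generate_traits(test_scenario(seed = 11, n_plots = 6))
  expect_false(identical(t1$dry_weight, t3$dry_weight))
})

test_that("generator images round-trip within one-pixel rounding", {
  set.seed(12)
  for (i in 1:8) {
    tgt <- runif(1, 0, 100)
    w <- sample(32:96, 1); h <- sample(32:96, 1)
    im <- generate_image(tgt, w, h, seed = 100 + i)
    rec <- green_fraction(im$image)
    expect_lte(abs(rec - tgt), 100 / (w * h))
  }
})

test_that("scenario JSON round trip preserves the configuration", {
  sc <- scenario_2016(seed = 13)
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(sc, f)
  back <- read_scenario_json(f)
  expect_equal(back$trait_distributions, sc$trait_distributions,
               tolerance = 1e-12)
  expect_identical(back$seed, sc$seed)
  expect_identical(generate_traits(back), generate_traits(sc))
})
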