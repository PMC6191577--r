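# Shared fixture: one sampling date of the default-condition scenario,
# restricted ranges keep the unit tests quick (full-span maps are exercised
# in the acceptance suite).
local_contour_fixture <- function(seed = 41, n_plots = 16) {
  sc <- test_scenario(seed = seed, n_plots = n_plots)
  tr <- generate_traits(sc)
  sel <- tr$date_id == sc$dates$date_id[2]
  list(spectra = generate_spectra(tr, sc)[sel], traits = tr[sel, ])
}

test_that("a trait that is exactly linear in one NDSI scores R2 = 1 there", {
  fx <- local_contour_fixture()
  y <- vapply(fx$spectra, ndsi, numeric(1), 710, 640)
  y <- 3 * y + 0.5
  cm <- contour_map_for_trait(fx$spectra, y, c(600, 760), "planted")
  i <- match(640, cm$wavelengths); j <- match(710, cm$wavelengths)
  expect_equal(cm$r2[i, j], 1, tolerance = 1e-10)
  expect_equal(unname(select_best_pair(cm)$mean_r2), 1, tolerance = 1e-10)
})

test_that("contour maps are exactly symmetric with a masked diagonal", {
  fx <- local_contour_fixture()
  cm <- contour_map_for_trait(fx$spectra, fx$traits$dry_weight,
                              c(500, 700), "dry_weight")
  expect_true(all(is.na(diag(cm$r2))))
  expect_identical(cm$r2, t(cm$r2))
  off <- cm$r2[upper.tri(cm$r2)]
  expect_true(all(off[!is.na(off)] >= 0 & off[!is.na(off)] <= 1))
})

test_that("entries match an independent lm() recomputation", {
  fx <- local_contour_fixture()
  y <- fx$traits$n_uptake
  cm <- contour_map_for_trait(fx$spectra, y, c(640, 820), "n_uptake")
  set.seed(42)
  B <- length(cm$wavelengths)
  for (k in 1:40) {
    ij <- sort(sample(B, 2))
    v <- vapply(fx$spectra, ndsi, numeric(1),
                cm$wavelengths[ij[1]], cm$wavelengths[ij[2]])
    expect_equal(cm$r2[ij[1], ij[2]],
                 summary(stats::lm(y ~ v))$r.squared, tolerance = 1e-10)
  }
})

test_that("the evaluated pair count is the expected combination number", {
  fx <- local_contour_fixture()
  cm <- contour_map_for_trait(fx$spectra, fx$traits$dry_weight,
                              c(700, 760), "dry_weight")
  B <- length(cm$wavelengths)
  expect_equal(B, 31)   # 700..760 nm step 2
  off <- cm$r2[upper.tri(cm$r2)]
  expect_equal(sum(!is.na(off)) + cm$n_masked, B * (B - 1) / 2)
})

test_that("mean_contour_map averages entrywise and propagates masks", {
  fx <- local_contour_fixture()
  cm1 <- contour_map_for_trait(fx$spectra, fx$traits$dry_weight,
                               c(700, 740), "dry_weight")
  expect_identical(mean_contour_map(list(cm1))$r2, cm1$r2)
  cm2 <- cm1
  cm2$r2[] <- 0.6
  cm2$r2[1, 2] <- NA; cm2$r2[2, 1] <- NA
  cm1b <- cm1; cm1b$r2[] <- 0.4
  m <- mean_contour_map(list(cm1b, cm2))
  expect_equal(m$r2[3, 5], 0.5)
  expect_true(is.na(m$r2[1, 2]))
  expect_equal(m$n_dates_averaged, 2L)
  expect_identical(m$r2, t(m$r2))
  # grid mismatch rejected
  cm3 <- contour_map_for_trait(fx$spectra, fx$traits$dry_weight,
                               c(700, 720), "dry_weight")
  expect_error(mean_contour_map(list(cm1, cm3)), "common wavelength grid")
})

test_that("select_best_pair is a deterministic lexicographic argmax", {
  wl <- c(640, 660, 710, 730)
  r2 <- matrix(NA_real_, 4, 4)
  r2[1, 3] <- r2[3, 1] <- 0.9
  r2[2, 4] <- r2[4, 2] <- 0.9   # exact tie
  r2[1, 2] <- r2[2, 1] <- 0.5
  mp <- structure(list(wavelengths = wl, r2 = r2, trait_name = "t",
                       n_dates_averaged = 1L, n = 10L, n_masked = 0L),
                  class = "contour_map")
  bp <- select_best_pair(mp)
  expect_equal(c(bp$lambda_a, bp$lambda_b), c(640, 710))
  expect_equal(bp$mean_r2, 0.9)
  # fully masked map errors
  mp$r2[] <- NA_real_
  expect_error(select_best_pair(mp), "no valid")
})

test_that("degenerate inputs are rejected", {
  fx <- local_contour_fixture()
  expect_error(contour_map_for_trait(fx$spectra[1:2], c(1, 2),
                                     c(700, 720)), "at least 3")
  expect_error(contour_map_for_trait(fx$spectra, rep(5, length(fx$spectra)),
                                     c(700, 720)), "constant")
  expect_error(contour_map_for_trait(fx$spectra, fx$traits$dry_weight,
                                     c(720, 700)), "lo < hi")
})

test_that("rank_pairs orders by R2 with deterministic ties", {
  fx <- local_contour_fixture()
  cm <- contour_map_for_trait(fx$spectra, fx$traits$dry_weight,
                              c(700, 740), "dry_weight")
  rp <- rank_pairs(cm, top = 10)
  expect_equal(nrow(rp), 10)
  expect_true(all(diff(rp$r2) <= 0))
  expect_true(all(rp$lambda_a < rp$lambda_b))
  expect_equal(rp$r2[1], select_best_pair(cm)$mean_r2)
})
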