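test_that("rgb_to_hsb reproduces the hexcone landmarks", {
  x <- rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
             c(128, 128, 128), c(0, 0, 0), c(255, 255, 255))
  h <- rgb_to_hsb(x)
  expect_equal(h[1, ], c(hue = 0, saturation = 255, brightness = 255))
  expect_equal(h[2, ], c(hue = 85, saturation = 255, brightness = 255))
  expect_equal(h[3, ], c(hue = 170, saturation = 255, brightness = 255))
  expect_equal(h[4, ], c(hue = 0, saturation = 0, brightness = 128))
  expect_equal(h[5, ], c(hue = 0, saturation = 0, brightness = 0))
  expect_equal(h[6, ], c(hue = 0, saturation = 0, brightness = 255))
})

test_that("rgb_to_hsb rejects malformed input", {
  expect_error(rgb_to_hsb(matrix(0, 2, 4)), "n x 3")
  expect_error(rgb_to_hsb(c(1, 2, 3)), "n x 3")
  expect_error(rgb_to_hsb(matrix(c(-1, 0, 0), 1, 3)), "0, 255")
  expect_error(rgb_to_hsb(matrix(c(256, 0, 0), 1, 3)), "0, 255")
})

test_that("hsb_to_rgb inverts rgb_to_hsb for bright, saturated colors", {
  # hue resolution in RGB bytes degrades as delta = sat*bri/255 shrinks, so
  # the faithful-inversion check is restricted to delta >= ~40
  set.seed(11)
  hsb <- cbind(sample(0:255, 300, TRUE), sample(100:255, 300, TRUE),
               sample(100:255, 300, TRUE))
  rgb <- hsb_to_rgb(hsb)
  back <- rgb_to_hsb(rgb)
  expect_lte(max(abs(back[, 2] - hsb[, 2])), 3)
  expect_lte(max(abs(back[, 3] - hsb[, 3])), 1)
  dh <- abs(back[, 1] - hsb[, 1])
  expect_lte(max(pmin(dh, 255 - dh)), 2)
})

test_that("segment_green handles the boundary cases", {
  img <- array(0, c(4, 4, 3)); img[, , 2] <- 255
  expect_equal(segment_green(img)$green_pct, 100)

  # browns: hue below the green band
  brown <- hsb_to_rgb(cbind(sample(8:38, 64, TRUE), 200, 120))
  img2 <- array(brown, c(8, 8, 3))
  r2 <- segment_green(img2)
  expect_equal(r2$green_pct, 0)
  expect_equal(r2$total_count, 64)

  expect_error(segment_green(array(0, c(0, 4, 3))), "zero pixels")
  expect_error(segment_green(array(0, c(4, 4, 2))), "RGB")
})

test_that("threshold intervals are closed at both ends", {
  # find RGB colors whose byte hue is exactly 45 and exactly 120
  for (target in c(45, 120)) {
    found <- FALSE
    for (s in 255:200) {
      cand <- hsb_to_rgb(matrix(c(target, s, 255), 1, 3))
      if (rgb_to_hsb(cand)[1] == target) { found <- TRUE; break }
    }
    expect_true(found)
    img <- array(rep(cand, each = 4), c(2, 2, 3))
    expect_equal(segment_green(img)$green_pct, 100)
  }
})

test_that("green_pct is invariant to spatial shuffling of pixels", {
  im <- generate_image(37.5, 32, 32, seed = 3)
  px <- matrix(im$image, ncol = 3)
  for (k in 1:3) {
    perm <- sample(nrow(px))
    shuf <- array(px[perm, ], dim = dim(im$image))
    expect_equal(segment_green(shuf)$green_pct,
                 segment_green(im$image)$green_pct)
  }
})

test_that("widening any threshold interval never decreases the green count", {
  set.seed(5)
  img <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  base <- hsb_thresholds(c(45, 120), c(40, 200), c(40, 200))
  n0 <- segment_green(img, base)$green_count
  wider <- list(hsb_thresholds(c(30, 140), c(40, 200), c(40, 200)),
                hsb_thresholds(c(45, 120), c(0, 255), c(40, 200)),
                hsb_thresholds(c(45, 120), c(40, 200), c(0, 255)))
  for (th in wider)
    expect_gte(segment_green(img, th)$green_count, n0)
})

test_that("segmentation mask agrees with rgb_to_hsb interval membership", {
  set.seed(9)
  img <- array(sample(0:255, 24 * 24 * 3, TRUE), c(24, 24, 3))
  th <- hsb_thresholds(c(45, 120), c(10, 240), c(20, 250))
  res <- segment_green(img, th)
  h <- rgb_to_hsb(img)
  manual <- h[, , 1] >= 45 & h[, , 1] <= 120 &
            h[, , 2] >= 10 & h[, , 2] <= 240 &
            h[, , 3] >= 20 & h[, , 3] <= 250
  expect_identical(res$mask, manual)
})

test_that("crop restricts segmentation to the region of interest", {
  img <- array(0, c(8, 8, 3))           # black (never green)
  img[1:4, 1:4, 2] <- 255               # green quadrant
  expect_equal(segment_green(img)$green_pct, 25)
  expect_equal(segment_green(img, crop = c(1, 4, 1, 4))$green_pct, 100)
  expect_equal(segment_green(img, crop = c(5, 8, 5, 8))$green_pct, 0)
})

test_that("batch_green_fraction reports per-file failures without dropping rows", {
  dir <- withr::local_tempdir()
  for (nm in c("P01_d1", "P02_d1", "P03_d2")) {
    im <- generate_image(50, 16, 16, seed = nchar(nm))
    write_image_png(im$image, file.path(dir, paste0(nm, ".png")))
  }
  good <- list.files(dir, full.names = TRUE)
  out <- batch_green_fraction(good)
  expect_equal(nrow(out), 3)
  expect_setequal(out$plot_id, c("P01", "P02", "P03"))
  expect_equal(nrow(attr(out, "failures")), 0)

  bad <- file.path(dir, "P04_d2.png")
  writeLines("not a png", bad)
  expect_warning(out2 <- batch_green_fraction(c(good, bad)), "failed")
  expect_equal(nrow(out2), 3)
  expect_equal(attr(out2, "failures")$path, bad)

  empty <- batch_green_fraction(character(0))
  expect_equal(nrow(empty), 0)
})

test_that("PNG write/read round trip preserves bytes", {
  im <- generate_image(40, 16, 16, seed = 2)
  f <- withr::local_tempfile(fileext = ".png")
  write_image_png(im$image, f)
  expect_identical(read_image_png(f), im$image * 1.0)
})
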