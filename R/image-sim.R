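#' Generate a synthetic canopy image with a known green fraction
#'
#' Builds an RGB image in which exactly `round(target/100 * width * height)`
#' pixels carry colors inside the green HSB threshold band (plant material)
#' and all remaining pixels carry colors outside it (soil browns; in the
#' `winter_stressed` style also yellow-brown discolored leaf pixels, the
#' coloring cold winters induce on young wheat).  Every planted color is
#' verified through [rgb_to_hsb()] against the same thresholds the
#' segmentation uses, so the planted count is an exact ground truth for
#' the round trip.  Pixels are i.i.d. colored with no spatial texture by
#' default (`arrangement = "scattered"`); the green-fraction statistic is
#' spatially agnostic, so a contiguous `"blocked"` arrangement is provided
#' only as a cosmetic alternative.
#'
#' @param green_fraction_target target green-pixel percentage in
#'   \[0, 100\].  The pixel count is resolved by `round()` (R's
#'   round-half-to-even rule).
#' @param width,height image size in pixels.
#' @param style `"clean"` (uniformly green plants on soil) or
#'   `"winter_stressed"` (background mixes soil with yellow/brown leaves).
#' @param seed integer seed; fully determines the image.
#' @param thresholds the [hsb_thresholds()] defining "green".
#' @param arrangement `"scattered"` (default) or `"blocked"`.
#' @return an object of class `"synthetic_canopy_image"`: list with
#'   `image` (h x w x 3 byte array), `green_count` (the exact planted
#'   count), `target`, `style`, `seed`.
#' @export
generate_image <- function(green_fraction_target, width, height,
                           style = c("clean", "winter_stressed"),
                           seed = 1L, thresholds = hsb_thresholds(),
                           arrangement = c("scattered", "blocked")) {
  style <- match.arg(style)
  arrangement <- match.arg(arrangement)
  if (length(green_fraction_target) != 1L || is.na(green_fraction_target) ||
      green_fraction_target < 0 || green_fraction_target > 100)
    stop("green_fraction_target must be in [0, 100]")
  stopifnot(width >= 1, height >= 1)
  npix <- as.integer(width) * as.integer(height)
  n_green <- as.integer(round(green_fraction_target / 100 * npix))

  with_seed(seed, {
    px <- matrix(0, npix, 3L)
    if (n_green > 0)
      px[seq_len(n_green), ] <- sample_palette(n_green, "green", thresholds)
    if (n_green < npix) {
      bgstyle <- if (style == "winter_stressed") "stressed" else "soil"
      px[(n_green + 1L):npix, ] <-
        sample_palette(npix - n_green, bgstyle, thresholds)
    }
    if (arrangement == "scattered") px <- px[sample.int(npix), , drop = FALSE]
    img <- array(px, dim = c(height, width, 3L))
    structure(list(image = img, green_count = n_green,
                   target = green_fraction_target, style = style,
                   seed = as.integer(seed)),
              class = "synthetic_canopy_image")
  })
}

# Sample n RGB colors guaranteed inside ("green") or outside (other kinds)
# the segmentation thresholds; candidates are drawn in HSB away from the
# interval edges and verified through the byte round trip, resampling the
# rare boundary case that rounding pushes across.
sample_palette <- function(n, kind = c("green", "soil", "stressed"),
                           thresholds = hsb_thresholds()) {
  kind <- match.arg(kind)
  draw <- function(m) {
    hsb <- switch(kind,
      green = cbind(sample(55:110, m, TRUE), sample(90:255, m, TRUE),
                    sample(70:255, m, TRUE)),
      soil = cbind(sample(8:38, m, TRUE), sample(60:200, m, TRUE),
                   sample(40:180, m, TRUE)),
      stressed = {  # soil browns mixed with yellow-brown leaf tones
        leafy <- stats::runif(m) < 0.4
        cbind(ifelse(leafy, sample(20:42, m, TRUE), sample(8:38, m, TRUE)),
              ifelse(leafy, sample(90:230, m, TRUE), sample(60:200, m, TRUE)),
              ifelse(leafy, sample(90:220, m, TRUE), sample(40:180, m, TRUE)))
      })
    hsb_to_rgb(hsb)
  }
  inside <- function(rgb) {
    h <- rgb_to_hsb(rgb)
    h[, 1] >= thresholds$hue[1] & h[, 1] <= thresholds$hue[2] &
      h[, 2] >= thresholds$sat[1] & h[, 2] <= thresholds$sat[2] &
      h[, 3] >= thresholds$bri[1] & h[, 3] <= thresholds$bri[2]
  }
  out <- draw(n)
  ok <- if (kind == "green") inside(out) else !inside(out)
  tries <- 0L
  while (!all(ok)) {
    tries <- tries + 1L
    if (tries > 50L) stop("could not construct a palette for these thresholds")
    out[!ok, ] <- draw(sum(!ok))
    ok <- if (kind == "green") inside(out) else !inside(out)
  }
  out
}

#' @export
print.synthetic_canopy_image <- function(x, ...) {
  dm <- dim(x$image)
  cat(sprintf("Synthetic canopy image %dx%d (%s): %d green pixels planted (target %.2f%%)\n",
              dm[2], dm[1], x$style, x$green_count, x$target))
  invisible(x)
}
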