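#' HSB color thresholds for green-pixel segmentation
#'
#' Closed byte-scale intervals on hue, saturation and brightness.  The
#' default hue band 45--120 on the 0--255 scale (about 63.5--169.4 degrees)
#' is the standard green band for segmenting living plant material from soil
#' and senescent tissue in nadir canopy photographs.  Note the scale: many
#' software stacks express hue in degrees (0--360) or as a unit fraction;
#' here all three channels are bytes, the ImageJ color-threshold convention.
#'
#' @param hue,sat,bri length-2 integer vectors `c(lo, hi)` with
#'   `0 <= lo <= hi <= 255`.  Hue wraparound (`lo > hi`) is not supported;
#'   the default green band does not wrap.
#' @return an object of class `"hsb_thresholds"`.
#' @examples
#' hsb_thresholds()                    # the default green band
#' hsb_thresholds(hue = c(40, 130))    # a wider one
#' @export
hsb_thresholds <- function(hue = c(45, 120), sat = c(0, 255), bri = c(0, 255)) {
  chk <- function(v, nm) {
    if (length(v) != 2L || anyNA(v) || any(v < 0) || any(v > 255) || v[1] > v[2])
      stop(sprintf("`%s` must be c(lo, hi) with 0 <= lo <= hi <= 255", nm))
    as.numeric(v)
  }
  structure(list(hue = chk(hue, "hue"), sat = chk(sat, "sat"),
                 bri = chk(bri, "bri")),
            class = "hsb_thresholds")
}

#' @export
print.hsb_thresholds <- function(x, ...) {
  cat("HSB thresholds (byte scale 0-255, closed intervals)\n")
  cat(sprintf("  hue %g-%g  sat %g-%g  bri %g-%g\n",
              x$hue[1], x$hue[2], x$sat[1], x$sat[2], x$bri[1], x$bri[2]))
  invisible(x)
}

#' Segment green (plant) pixels in an RGB canopy image
#'
#' Converts the image to HSB bytes and classifies a pixel as green when all
#' three channels lie inside their closed threshold intervals.  The
#' green-pixel percentage is `green pixels / total pixels * 100`.
#'
#' @param image an `h x w x 3` RGB byte array (0--255), or the path of a
#'   PNG file.
#' @param thresholds an [hsb_thresholds()] object.
#' @param crop optional integer vector `c(row1, row2, col1, col2)` selecting
#'   a rectangular region of interest (e.g. the sampling frame) before
#'   segmentation.
#' @return an object of class `"green_pixel_result"`: a list with
#'   `green_count`, `total_count`, `green_pct` and the logical `mask`
#'   (`TRUE` = plant).
#' @examples
#' img <- array(0, c(4, 4, 3)); img[, , 2] <- 255   # all pure green
#' segment_green(img)$green_pct                     # 100
#' @export
segment_green <- function(image, thresholds = hsb_thresholds(), crop = NULL) {
  if (is.character(image)) image <- read_image_png(image)
  if (!inherits(thresholds, "hsb_thresholds"))
    stop("`thresholds` must be an hsb_thresholds() object")
  dm <- dim(image)
  if (is.null(dm) || length(dm) != 3L || dm[3] != 3L)
    stop("`image` must be an h x w x 3 RGB array")
  if (!is.null(crop)) {
    if (length(crop) != 4L) stop("`crop` must be c(row1, row2, col1, col2)")
    image <- image[crop[1]:crop[2], crop[3]:crop[4], , drop = FALSE]
    dm <- dim(image)
  }
  if (dm[1] * dm[2] == 0L) stop("image has zero pixels")
  x <- matrix(as.numeric(image), ncol = 3L)
  rng <- range(x)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("RGB values must be finite and in [0, 255]")
  # saturation is only computed when its interval actually constrains
  need_sat <- thresholds$sat[1] > 0 || thresholds$sat[2] < 255
  h <- hsb_bytes(x, want_sat = need_sat)
  inside <- h$hue >= thresholds$hue[1] & h$hue <= thresholds$hue[2]
  if (need_sat)
    inside <- inside & h$sat >= thresholds$sat[1] & h$sat <= thresholds$sat[2]
  if (thresholds$bri[1] > 0 || thresholds$bri[2] < 255)
    inside <- inside & h$bri >= thresholds$bri[1] & h$bri <= thresholds$bri[2]
  total <- length(inside)
  green <- sum(inside)
  dim(inside) <- dm[1:2]
  structure(list(green_count = green, total_count = total,
                 green_pct = green / total * 100, mask = inside),
            class = "green_pixel_result")
}

#' @export
print.green_pixel_result <- function(x, ...) {
  cat(sprintf("Green pixels: %d / %d (%.2f%%)\n",
              x$green_count, x$total_count, x$green_pct))
  invisible(x)
}

#' Green-pixel percentage of an image
#'
#' Convenience wrapper around [segment_green()] returning only the
#' percentage.
#'
#' @inheritParams segment_green
#' @return green-pixel percentage in \[0, 100\].
#' @export
green_fraction <- function(image, thresholds = hsb_thresholds(), crop = NULL) {
  segment_green(image, thresholds, crop)$green_pct
}

#' Green-pixel percentages for a batch of image files
#'
#' Reads each PNG, parses `<plot_id>_<date_id>` from the file name, and
#' computes the green-pixel percentage.  Unreadable files are reported in
#' the `"failures"` attribute (path + error message) rather than silently
#' dropped.
#'
#' @param paths character vector of PNG file paths named
#'   `<plot_id>_<date_id>.png`.
#' @inheritParams segment_green
#' @return a data frame with columns `plot_id`, `date_id`, `green_pct`
#'   (one row per successfully processed image) and attribute `"failures"`,
#'   a data frame with columns `path` and `error`.
#' @export
batch_green_fraction <- function(paths, thresholds = hsb_thresholds(),
                                 crop = NULL) {
  rows <- list(); fails <- list()
  for (p in paths) {
    res <- tryCatch({
      base <- sub("\\.[Pp][Nn][Gg]$", "", basename(p))
      parts <- strsplit(base, "_", fixed = TRUE)[[1]]
      if (length(parts) < 2L)
        stop("file name not parseable as <plot_id>_<date_id>")
      pct <- green_fraction(p, thresholds, crop)
      data.frame(plot_id = parts[1],
                 date_id = paste(parts[-1], collapse = "_"),
                 green_pct = pct, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(path = p, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plot_id = character(), date_id = character(),
               green_pct = numeric(), stringsAsFactors = FALSE)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(path = character(), error = character(),
               stringsAsFactors = FALSE)
  if (nrow(failures)) {
    warning(sprintf("%d of %d images failed; see attr(result, 'failures')",
                    nrow(failures), length(paths)))
  }
  attr(out, "failures") <- failures
  out
}

#' Read a PNG file as an RGB byte array
#'
#' @param path PNG file path.
#' @return `h x w x 3` array of bytes 0--255 (alpha channel dropped).
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write an RGB byte array to a PNG file
#'
#' @param image `h x w x 3` byte array (0--255).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}
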