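#' Convert RGB byte values to HSB (hue, saturation, brightness) bytes
#'
#' Applies the standard hexcone HSV transform with all three output channels
#' quantized to the 0--255 byte scale, the convention used by ImageJ's color
#' thresholder.  Hue is rescaled from degrees (\eqn{[0^\circ, 360^\circ)}) to
#' bytes as `round(H * 255/360)`; saturation and brightness are
#' `round(255 * S)` and `max(R,G,B)` respectively (brightness of byte input
#' is itself a byte, so it is exact).  Achromatic pixels (`max == min`) get
#' hue 0 and saturation 0, so black, white and gray never fall inside a
#' green hue band.
#'
#' @param rgb an `n x 3` matrix or `h x w x 3` array of byte values in
#'   0--255 (channel order R, G, B).  Fractional values are accepted but the
#'   intended inputs are integers.
#' @return an object of the same shape with channels hue, saturation,
#'   brightness, all on 0--255.
#' @examples
#' rgb_to_hsb(matrix(c(0, 255, 0), 1, 3))   # pure green -> 85, 255, 255
#' @seealso [hsb_to_rgb()], [segment_green()]
#' @export
rgb_to_hsb <- function(rgb) {
  dm <- dim(rgb)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L)) || dm[length(dm)] != 3L)
    stop("`rgb` must be an n x 3 matrix or h x w x 3 array (R, G, B)")
  x <- matrix(as.numeric(rgb), ncol = 3L)
  rng <- range(x)                               # single pass, NA-propagating
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("RGB values must be finite and in [0, 255]")
  h <- hsb_bytes(x)
  out <- cbind(h$hue, h$sat, h$bri)
  if (length(dm) == 3L) {
    out <- array(out, dim = dm)
    dimnames(out) <- NULL
  } else {
    dimnames(out) <- list(NULL, c("hue", "saturation", "brightness"))
  }
  out
}

# Vectorized, branch-free hexcone core shared by rgb_to_hsb() and
# segment_green().  Sector selection by logical masks keeps the arithmetic
# per pixel identical to the scalar hexcone formula: the selected sector's
# difference is divided by delta, offset by 0/2/4, wrapped into [0, 6) and
# quantized as round(h6 * 42.5).
hsb_bytes <- function(x, want_sat = TRUE) {
  r <- x[, 1L]; g <- x[, 2L]; b <- x[, 3L]
  mx <- pmax.int(r, g, b)
  mn <- pmin.int(r, g, b)
  d <- mx - mn
  sr <- mx == r                                  # precedence R > G > B
  sg <- !sr & (mx == g)
  sb <- !sr & !sg
  num <- (g - b) * sr + (b - r) * sg + (r - g) * sb
  h6 <- num / (d + (d == 0)) + (2 * sg + 4 * sb)
  h6 <- h6 + 6 * (h6 < 0)
  hue <- round(h6 * 42.5)                        # 42.5 = 255/6
  sat <- if (want_sat) round(d / (mx + (mx == 0)) * 255) else NULL
  list(hue = hue, sat = sat, bri = mx)
}

#' Convert HSB bytes back to RGB bytes
#'
#' Inverse hexcone transform on the 0--255 byte scale.  Used by the
#' synthetic image generator to plant pixels with prescribed HSB values;
#' because both directions share the same byte quantization, a color
#' constructed away from a threshold edge survives the round trip on the
#' same side of the threshold.
#'
#' @param hsb an `n x 3` matrix or `h x w x 3` array of hue, saturation,
#'   brightness bytes in 0--255.
#' @return RGB bytes in the same shape.
#' @export
hsb_to_rgb <- function(hsb) {
  dm <- dim(hsb)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L)) || dm[length(dm)] != 3L)
    stop("`hsb` must be an n x 3 matrix or h x w x 3 array")
  x <- matrix(as.numeric(hsb), ncol = 3L)
  if (anyNA(x) || any(x < 0) || any(x > 255))
    stop("HSB values must be finite and in [0, 255]")
  h6 <- x[, 1L] / 42.5
  s <- x[, 2L] / 255
  v <- x[, 3L] / 255
  c <- v * s
  xx <- c * (1 - abs(h6 %% 2 - 1))
  m <- v - c
  sec <- floor(h6) %% 6
  r1 <- ifelse(sec == 0 | sec == 5, c, ifelse(sec == 1 | sec == 4, xx, 0))
  g1 <- ifelse(sec == 1 | sec == 2, c, ifelse(sec == 0 | sec == 3, xx, 0))
  b1 <- ifelse(sec == 3 | sec == 4, c, ifelse(sec == 2 | sec == 5, xx, 0))
  out <- round(cbind(r1 + m, g1 + m, b1 + m) * 255)
  if (length(dm) == 3L) {
    out <- array(out, dim = dm)
    dimnames(out) <- NULL
  } else {
    dimnames(out) <- list(NULL, c("r", "g", "b"))
  }
  out
}
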