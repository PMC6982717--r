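# Rainbow anchors: u = 0, .25, .5, .75, 1 -> blue, cyan, green, yellow, red.
# Extremes are pure blue/red so the color semantics (red = large, blue = small)
# hold at the theoretical range limits of every encoder.
.rainbow_u <- c(0, 0.25, 0.5, 0.75, 1)
.rainbow_rgb <- cbind(
  R = c(0, 0, 0, 1, 1),
  G = c(0, 1, 1, 1, 0),
  B = c(1, 1, 0, 0, 0)
)

#' Map a field matrix to an RGB image through the rainbow colormap
#'
#' Scales entries by the encoder's *theoretical* range (GASF/GADF: `[-1, 1]`;
#' MTF: `[0, 1]`) rather than the per-image min/max, so colors mean the same
#' thing across instances, then interpolates the fixed five-anchor rainbow
#' (blue, cyan, green, yellow, red). Larger values map to redder colors.
#'
#' @param m A `field_matrix` (see [gasf()], [gadf()], [mtf()]), or a plain
#'   matrix together with `range`.
#' @param range Optional numeric length-2 override of the theoretical range.
#' @return An `rgb_image`: numeric array `n x n x 3` (R, G, B planes) with
#'   values in `[0, 1]`.
#' @export
colormap_rainbow <- function(m, range = NULL) {
  if (is.null(range)) range <- attr(m, "theoretical_range")
  if (is.null(range) || length(range) != 2 || !all(is.finite(range)) ||
      range[1] >= range[2])
    stop("matrix has no declared theoretical range; pass `range`", call. = FALSE)
  v <- unclass(m)
  attributes(v) <- list(dim = dim(m))
  if (any(v < range[1] - 1e-9) || any(v > range[2] + 1e-9))
    stop("matrix entries fall outside the declared theoretical range",
         call. = FALSE)
  u <- pmin(pmax((v - range[1]) / (range[2] - range[1]), 0), 1)
  img <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3)
    img[, , ch] <- approx(.rainbow_u, .rainbow_rgb[, ch], xout = u)$y
  structure(img, class = "rgb_image")
}

.check_rgb <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  if (any(img < 0) || any(img > 1))
    stop("RGB values must lie in [0, 1]", call. = FALSE)
  invisible(d)
}

#' Channel-split concatenation of per-channel images
#'
#' Builds the ConvNet input from the `m` per-sensor RGB images: for each color
#' plane (R, G, B) the like-colored monochrome planes are stacked vertically
#' in the order given by `order`, producing a single 3-plane image of height
#' `n * m` and width `n`. With six sensors at image size 128 this is the
#' `(128 x 6) x 128` layout. Reordering `order` permutes the n-row blocks of
#' every plane identically (the "spurious edge" pattern changes, the pixel
#' content does not).
#'
#' @param images List of `m` RGB arrays (`n x n x 3`), all the same size.
#' @param order Integer permutation of `1:m`; defaults to identity.
#' @return A `concat_image`: array `(n * m) x n x 3` with attribute `order`.
#' @export
concat_rgb <- function(images, order = seq_along(images)) {
  if (!is.list(images) || length(images) < 1L)
    stop("images must be a non-empty list", call. = FALSE)
  m <- length(images)
  dims <- lapply(images, .check_rgb)
  n <- dims[[1]][1]
  for (d in dims)
    if (d[1] != n || d[2] != n)
      stop("all images must be square and share the same size", call. = FALSE)
  if (length(order) != m || !setequal(order, seq_len(m)))
    stop("order must be a permutation of 1..m", call. = FALSE)
  out <- array(0, c(n * m, n, 3L))
  for (r in seq_len(m))
    out[((r - 1L) * n + 1L):(r * n), , ] <- images[[order[r]]]
  structure(out, class = "concat_image", order = as.integer(order))
}

#' Write an RGB image as an 8-bit PNG
#'
#' Quantizes values to bytes with `round(v * 255)` before writing, so a
#' subsequent [read_png()] reproduces the written pixels exactly.
#'
#' @param img RGB array (`rgb_image` or `concat_image`), values in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  .check_rgb(img)
  q <- round(unclass(img) * 255) / 255
  png::writePNG(q, target = path)
  invisible(path)
}

#' Read an 8-bit RGB PNG
#'
#' @param path PNG file path; must be a 3-channel RGB file (no alpha, not
#'   grayscale).
#' @return RGB array `H x W x 3` with values `byte / 255`.
#' @export
read_png <- function(path) {
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop("not a readable PNG file: ", conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an 8-bit RGB PNG (3 channels, no alpha)", call. = FALSE)
  structure(img, class = "rgb_image")
}
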