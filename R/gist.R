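#' Convert an image to grey-scale and cap its width at 256 pixels
#'
#' Luminance conversion (0.299 R + 0.587 G + 0.114 B) followed by an
#' aspect-preserving bilinear resize, applied only when the width exceeds
#' 256 pixels.
#'
#' @param image Numeric matrix (grey) or height x width x 3 array (RGB); any
#'   intensity scale.
#' @param max_width Width cap in pixels (default 256).
#' @return Grey-scale numeric matrix.
#' @export
preprocess_image <- function(image, max_width = 256L) {
  if (is.array(image) && length(dim(image)) == 3) {
    if (dim(image)[3] < 3) image <- image[, , 1]
    else image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] +
        0.114 * image[, , 3]
  }
  image <- as.matrix(image)
  w <- ncol(image)
  if (w > max_width) {
    s <- max_width / w
    image <- .bilinear_resize(image, round(nrow(image) * s), max_width)
  }
  image
}

# Bilinear resampling on the pixel-centre grid.
.bilinear_resize <- function(img, nh, nw) {
  h <- nrow(img); w <- ncol(img)
  ys <- (seq_len(nh) - 0.5) * h / nh + 0.5
  xs <- (seq_len(nw) - 0.5) * w / nw + 0.5
  y0 <- pmin(pmax(floor(ys - 0.5) + 0.5, 1), h)  # work in centre coords
  y0 <- floor(ys); y0 <- pmin(pmax(y0, 1), h - 1); fy <- pmin(pmax(ys - y0, 0), 1)
  x0 <- floor(xs); x0 <- pmin(pmax(x0, 1), w - 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx)
  b <- img[y0 + 1, x0, drop = FALSE] * outer(fy, 1 - fx)
  cc <- img[y0, x0 + 1, drop = FALSE] * outer(1 - fy, fx)
  d <- img[y0 + 1, x0 + 1, drop = FALSE] * outer(fy, fx)
  a + b + cc + d
}

# Frequency-domain Gabor transfer function for an h x w grid: Gaussian
# around centre frequency f0 (cycles/pixel) at orientation theta, sigma =
# f0/2 (about one octave), DC forced to zero.
.gabor_transfer <- function(h, w, f0, theta) {
  fy <- c(seq(0, floor(h / 2)), seq(-(ceiling(h / 2) - 1), -1)) / h
  fx <- c(seq(0, floor(w / 2)), seq(-(ceiling(w / 2) - 1), -1)) / w
  FX <- matrix(fx, h, w, byrow = TRUE)
  FY <- matrix(fy, h, w)
  fr <- FX * cos(theta) + FY * sin(theta)
  ft <- -FX * sin(theta) + FY * cos(theta)
  sig <- f0 / 2
  g <- exp(-((fr - f0)^2 + ft^2) / (2 * sig^2))
  g[1, 1] <- 0
  g
}

#' GIST descriptor of an image
#'
#' Filters the grey-scale image with a bank of Gabor filters (16
#' orientations x 4 scales by default; centre frequencies 0.25, 0.125,
#' 0.0625, 0.03125 cycles/pixel, one-octave bandwidth, applied in the
#' frequency domain), takes the response magnitude, and averages it within
#' each cell of a 4 x 4 spatial grid. The 16 block averages of every filter
#' are concatenated scale-major, then orientation, then block (row-major),
#' giving a descriptor of length `n_orientations * n_scales * grid^2`
#' (1,024 with the defaults). Filters are zero-mean, so the descriptor is
#' invariant to adding a constant to the image and a constant image maps to
#' the zero vector.
#'
#' @param image Grey matrix or RGB array; passed through
#'   [preprocess_image()] first.
#' @param n_orientations Number of filter orientations (default 16).
#' @param n_scales Number of filter scales (default 4).
#' @param grid Spatial pooling grid size (default 4).
#' @return Named numeric descriptor vector.
#' @export
extract_gist <- function(image, n_orientations = 16L, n_scales = 4L,
                         grid = 4L) {
  img <- preprocess_image(image)
  h <- nrow(img); w <- ncol(img)
  if (h < grid || w < grid)
    stop("image too small: need at least ", grid, "x", grid, " pixels")
  # grid blocks partition the image as evenly as possible; remainder pixels
  # go to the last row/column of blocks
  ybrk <- c(rep(floor(h / grid), grid - 1), h - floor(h / grid) * (grid - 1))
  xbrk <- c(rep(floor(w / grid), grid - 1), w - floor(w / grid) * (grid - 1))
  yidx <- rep(seq_len(grid), ybrk)
  xidx <- rep(seq_len(grid), xbrk)
  cell <- (yidx[row(img)] - 1L) * grid + xidx[col(img)]  # row-major blocks
  fimg <- stats::fft(img)
  out <- numeric(n_orientations * n_scales * grid^2)
  nm <- character(length(out))
  k <- 0L
  for (s in seq_len(n_scales)) {
    f0 <- 0.25 / 2^(s - 1)
    for (o in seq_len(n_orientations)) {
      theta <- (o - 1) * pi / n_orientations
      g <- .gabor_transfer(h, w, f0, theta)
      resp <- Mod(stats::fft(fimg * g, inverse = TRUE)) / (h * w)
      pooled <- as.vector(rowsum(as.vector(resp), cell)) /
        as.vector(table(cell))
      out[k + seq_len(grid^2)] <- pooled
      nm[k + seq_len(grid^2)] <- sprintf("s%d_o%02d_b%02d", s, o,
                                         seq_len(grid^2))
      k <- k + grid^2
    }
  }
  stats::setNames(out, nm)
}

#' GIST features for a set of images
#'
#' @param images Named list of images (matrices or RGB arrays).
#' @param category_label Category label per image (default `"unknown"`).
#' @param ... Passed to [extract_gist()].
#' @return A [feature_table()] of GIST descriptors.
#' @export
gist_feature_table <- function(images, category_label = NULL, ...) {
  if (is.null(names(images)))
    names(images) <- sprintf("image%03d", seq_along(images))
  if (is.null(category_label))
    category_label <- rep("unknown", length(images))
  descs <- t(vapply(images, extract_gist, extract_gist(images[[1]], ...), ...))
  feature_table(descs, names(images), category_label,
                unit_ids = colnames(descs))
}
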