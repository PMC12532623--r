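# Small deterministic image primitives shared by every stage.
#
# Convention used throughout the package: an image is a base R numeric or
# integer matrix with nrow = height and ncol = width, origin at the top-left,
# x running rightward along columns and y downward along rows. Pixel centres
# are at integer (x, y) with 1-based indexing; img[y, x] addresses a pixel.
# Boundary handling is replicate (Neumann) unless stated otherwise.

shift_img <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
  img[ri, ci, drop = FALSE]
}

#' Separable Gaussian smoothing with replicate boundaries
#'
#' Convolves an image with a truncated (3 sigma) sampled Gaussian kernel,
#' normalized to unit sum, applied separably along rows then columns.
#' Border pixels are replicated, matching the zero-flux boundary used by the
#' nonlinear diffusion stage.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the input.
#' @return numeric matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  r <- min(r, nr - 1L, nc - 1L)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  # mirror (half-sample symmetric) padding: the method-of-images extension,
  # so convolution agrees with zero-flux diffusion up to kernel truncation
  pad <- img[c(r:1, seq_len(nr), nr:(nr - r + 1L)), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + nr - 1L), , drop = FALSE]
  pad <- out[, c(r:1, seq_len(nc), nc:(nc - r + 1L)), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) out <- out + k[i] * pad[, i:(i + nc - 1L), drop = FALSE]
  out
}

# Bilinear resize with centre-aligned pixel mapping and clamped borders.
resize_bilinear <- function(img, nr2, nc2) {
  nr <- nrow(img); nc <- ncol(img)
  sy <- (seq_len(nr2) - 0.5) * nr / nr2 + 0.5
  sx <- (seq_len(nc2) - 0.5) * nc / nc2 + 0.5
  y0 <- pmin(pmax(floor(sy), 1), nr); y1 <- pmin(y0 + 1, nr)
  x0 <- pmin(pmax(floor(sx), 1), nc); x1 <- pmin(x0 + 1, nc)
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  cc <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  WX <- matrix(wx, nr2, nc2, byrow = TRUE)
  WY <- matrix(wy, nr2, nc2)
  (a * (1 - WX) + b * WX) * (1 - WY) + (cc * (1 - WX) + d * WX) * WY
}

# Scharr 3x3 first derivatives (normalized by 1/32), replicate boundaries.
scharr_x <- function(img) {
  (3 * (shift_img(img, -1L, 1L) - shift_img(img, -1L, -1L)) +
     10 * (shift_img(img, 0L, 1L) - shift_img(img, 0L, -1L)) +
     3 * (shift_img(img, 1L, 1L) - shift_img(img, 1L, -1L))) / 32
}

scharr_y <- function(img) {
  (3 * (shift_img(img, 1L, -1L) - shift_img(img, -1L, -1L)) +
     10 * (shift_img(img, 1L, 0L) - shift_img(img, -1L, 0L)) +
     3 * (shift_img(img, 1L, 1L) - shift_img(img, -1L, 1L))) / 32
}

disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

# Binary morphology on logical masks (TRUE = foreground) with a disc
# structuring element; pixels outside the canvas count as background.
dilate_mask <- function(mask, radius) {
  r <- as.integer(radius)
  if (r <= 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L * r, nc + 2L * r)
  pad[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- mask
  off <- disc_offsets(r)
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(off))) {
    out <- out | pad[(r + 1L + off$dy[k]):(r + nr + off$dy[k]),
                     (r + 1L + off$dx[k]):(r + nc + off$dx[k]), drop = FALSE]
  }
  out
}

erode_mask <- function(mask, radius) {
  !dilate_mask(!mask, radius)
}

# 4-connected component labelling (thin wrapper over the compiled core).
label_components <- function(mask) {
  label4_cpp(mask)
}

# Deterministic per-case child seeds from one root seed; keeps every value
# in the 32-bit signed range R's RNG accepts.
derive_seed <- function(root, index, stream = 0L) {
  v <- (as.double(root) %% 2147483647) * 48271 +
    as.double(index) * 75362 + as.double(stream) * 10007 + 12345
  as.integer(v %% 2147483647)
}
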