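# ORB-style binary feature pipeline, built from scratch: FAST-9 segment-test
# corners, Harris ranking, an image pyramid, intensity-centroid orientation,
# and a steered 256-bit BRIEF descriptor. Defaults follow the conventions of
# the original algorithm description; bit-exact parity with any third-party
# implementation is a non-goal (the test pattern here is seeded Gaussian
# sampling rather than the original learned pattern).

#' ORB extractor parameters
#'
#' @param n_features maximum number of keypoints kept (by Harris response).
#' @param n_levels number of pyramid levels.
#' @param scale_factor pyramid scale step between levels.
#' @param fast_threshold FAST intensity threshold on \[0,1\] images.
#' @param fast_n_contiguous required contiguous arc length (FAST-9).
#' @param harris_k Harris detector free parameter.
#' @param harris_block Harris block (structure-tensor summation window), px.
#' @param orientation_radius intensity-centroid patch radius, px.
#' @param patch_size BRIEF patch side length, px.
#' @param detect_sigma Gaussian pre-smoothing before detection; strict
#'   two-level silhouettes make gradients and arcs degenerate without it.
#' @param describe_sigma Gaussian pre-smoothing before description.
#' @param pattern_seed seed of the fixed BRIEF test pattern.
#' @return an `orb_params` list.
#' @export
orb_params <- function(n_features = 500L, n_levels = 4L, scale_factor = 1.2,
                       fast_threshold = 0.08, fast_n_contiguous = 9L,
                       harris_k = 0.04, harris_block = 7L,
                       orientation_radius = 15L, patch_size = 31L,
                       detect_sigma = 1, describe_sigma = 2,
                       pattern_seed = 42L) {
  p <- list(n_features = as.integer(n_features), n_levels = as.integer(n_levels),
            scale_factor = scale_factor, fast_threshold = fast_threshold,
            fast_n_contiguous = as.integer(fast_n_contiguous),
            harris_k = harris_k, harris_block = as.integer(harris_block),
            orientation_radius = as.integer(orientation_radius),
            patch_size = as.integer(patch_size), detect_sigma = detect_sigma,
            describe_sigma = describe_sigma, pattern_seed = as.integer(pattern_seed))
  class(p) <- "orb_params"
  p
}

#' FAST segment-test corner detection
#'
#' A pixel p is a corner iff at least `n_contiguous` contiguous pixels on the
#' 16-pixel Bresenham circle of radius 3 are all brighter than `I(p) + t` or
#' all darker than `I(p) - t`. The corner score is the sum of `|I(c) - I(p)|`
#' over the circle pixels satisfying the detected polarity (accumulated in
#' circle order). Non-maximum suppression keeps strict 3x3 maxima of the
#' score; plateaus yield no keypoint.
#'
#' @param image grayscale numeric matrix (at least 7x7).
#' @param intensity_threshold FAST threshold `t`.
#' @param n_contiguous required arc length (default 9).
#' @param nms apply non-maximum suppression (default TRUE).
#' @return data frame with columns `x`, `y` (1-based pixel coordinates) and
#'   `score`, ordered by score decreasing then y then x.
#' @export
fast_detect <- function(image, intensity_threshold = 0.08, n_contiguous = 9L,
                        nms = TRUE) {
  if (nrow(image) < 7L || ncol(image) < 7L) stop("image must be at least 7x7")
  sc <- fast_score_cpp(image, intensity_threshold, as.integer(n_contiguous))
  if (nms) {
    keep <- sc > 0
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      keep <- keep & (sc > shift_img_zero(sc, dy, dx))
    }
  } else {
    keep <- sc > 0
  }
  idx <- which(keep, arr.ind = TRUE)
  kp <- data.frame(x = idx[, 2L], y = idx[, 1L], score = sc[idx])
  kp[order(-kp$score, kp$y, kp$x), , drop = FALSE]
}

# shift with -Inf padding so border pixels are never suppressed by
# out-of-image neighbours during NMS
shift_img_zero <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(-Inf, nr, nc)
  ys <- max(1L, 1L - dy):min(nr, nr - dy)
  xs <- max(1L, 1L - dx):min(nc, nc - dx)
  out[ys, xs] <- img[ys + dy, xs + dx]
  out
}

#' Harris corner response at keypoints
#'
#' `det(M) - k trace(M)^2` of the gradient structure tensor summed over a
#' square block centred on each keypoint (Scharr gradients). Keypoints
#' without full block support get `NA` (they are dropped upstream, not an
#' error).
#'
#' @param image grayscale numeric matrix.
#' @param keypoints data frame with `x`, `y` columns.
#' @param k Harris free parameter.
#' @param block block side length, px.
#' @return numeric vector of responses (NA where support is missing).
#' @export
harris_response <- function(image, keypoints, k = 0.04, block = 7L) {
  ix <- scharr_x(image); iy <- scharr_y(image)
  sxx <- box_sum(ix * ix, block); syy <- box_sum(iy * iy, block)
  sxy <- box_sum(ix * iy, block)
  half <- block %/% 2L
  m <- half + 1L  # gradient needs one extra pixel of support
  n <- nrow(keypoints)
  out <- rep(NA_real_, n)
  ok <- keypoints$x > m & keypoints$x <= ncol(image) - m &
    keypoints$y > m & keypoints$y <= nrow(image) - m
  if (any(ok)) {
    ii <- cbind(keypoints$y[ok], keypoints$x[ok])
    det_m <- sxx[ii] * syy[ii] - sxy[ii]^2
    tr <- sxx[ii] + syy[ii]
    out[ok] <- det_m - k * tr^2
  }
  out
}

# Sliding block sum via integral image; result at each pixel is the sum over
# the centred block (truncated at borders).
box_sum <- function(img, block) {
  half <- block %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[-1L, -1L] <- apply(apply(img, 2L, cumsum), 1L, cumsum) |> t()
  y0 <- pmax(seq_len(nr) - half - 1L, 0L) + 1L
  y1 <- pmin(seq_len(nr) + half, nr) + 1L
  x0 <- pmax(seq_len(nc) - half - 1L, 0L) + 1L
  x1 <- pmin(seq_len(nc) + half, nc) + 1L
  ii[y1, x1] - ii[y0, x1] - ii[y1, x0] + ii[y0, x0]
}

#' Intensity-centroid orientation
#'
#' `theta = atan2(m01, m10)` from the first image moments over a circular
#' patch centred on the keypoint, with coordinates centred there; mapped to
#' `[0, 2 pi)`. Degenerate patches (both moments zero) return 0 by
#' convention. Coordinates follow the package convention (x rightward,
#' y downward).
#'
#' @param image grayscale numeric matrix.
#' @param keypoint list or one-row data frame with `x`, `y`.
#' @param radius patch radius, px (must fit inside the image).
#' @return angle in radians in `[0, 2 pi)`.
#' @export
orientation_centroid <- function(image, keypoint, radius = 15L) {
  off <- disc_offsets(radius)
  ys <- keypoint$y + off$dy; xs <- keypoint$x + off$dx
  if (min(ys) < 1L || max(ys) > nrow(image) || min(xs) < 1L || max(xs) > ncol(image))
    stop("orientation patch leaves the image")
  v <- image[cbind(ys, xs)]
  m10 <- sum(off$dx * v); m01 <- sum(off$dy * v)
  if (m10 == 0 && m01 == 0) return(0)
  atan2(m01, m10) %% (2 * pi)
}

# The fixed BRIEF test pattern: 256 point pairs drawn once from an isotropic
# Gaussian (sd = patch/5), coordinates clamped to [-9, 9] so every rotated
# sample stays inside the 31x31 patch.
brief_pattern <- function(seed = 42L, n_tests = 256L, patch_size = 31L) {
  withr::with_seed(seed, {
    v <- round(stats::rnorm(4L * n_tests, 0, patch_size / 5))
  })
  v <- pmin(pmax(v, -9), 9)
  list(ax = v[seq(1L, by = 4L, length.out = n_tests)],
       ay = v[seq(2L, by = 4L, length.out = n_tests)],
       bx = v[seq(3L, by = 4L, length.out = n_tests)],
       by = v[seq(4L, by = 4L, length.out = n_tests)])
}

#' Steered BRIEF descriptor
#'
#' Bit i is 1 iff `I(p + R_theta a_i) < I(p + R_theta b_i)` for the i-th test
#' pair of the fixed pattern rotated by the keypoint orientation; sample
#' positions are rounded to the nearest pixel. Exactly 256 bits, packed into
#' 32 bytes ([base::packBits()] order).
#'
#' @param image grayscale numeric matrix (pre-smoothed upstream).
#' @param keypoint list or one-row data frame with `x`, `y`.
#' @param pattern test pattern from `brief_pattern()` (internal default).
#' @param theta orientation in radians.
#' @return raw vector of 32 bytes.
#' @export
brief_describe <- function(image, keypoint, pattern = brief_pattern(), theta = 0) {
  ct <- cos(theta); st <- sin(theta)
  axr <- round(ct * pattern$ax - st * pattern$ay)
  ayr <- round(st * pattern$ax + ct * pattern$ay)
  bxr <- round(ct * pattern$bx - st * pattern$by)
  byr <- round(st * pattern$bx + ct * pattern$by)
  ia <- image[cbind(keypoint$y + ayr, keypoint$x + axr)]
  ib <- image[cbind(keypoint$y + byr, keypoint$x + bxr)]
  packBits(ia < ib)
}

#' Extract ORB-style keypoints and descriptors
#'
#' Builds a bilinear image pyramid, detects FAST corners per level on a
#' sigma-1-smoothed copy, ranks them by Harris response, keeps the strongest
#' `n_features` overall, assigns intensity-centroid orientations, and
#' computes steered BRIEF descriptors on a sigma-2-smoothed copy. Keypoint
#' coordinates are reported at base resolution; keypoints are sorted
#' canonically (response decreasing, then y, then x) so downstream matching
#' is storage-order independent. Deterministic.
#'
#' @param image a [binary_silhouette()] or any grayscale matrix.
#' @param params an [orb_params()] object.
#' @return a `sinus_features` list: `keypoints` (data frame with x, y,
#'   octave, scale, angle, response), `descriptors` (raw matrix, one 32-byte
#'   column per keypoint), `method = "orb"`, `nbits = 256`.
#' @export
orb_extract <- function(image, params = orb_params()) {
  img <- if (inherits(image, "binary_silhouette")) sil_gray(image)
  else matrix(as.numeric(image), nrow(image), ncol(image))
  pattern <- brief_pattern(params$pattern_seed, 256L, params$patch_size)
  margin <- params$orientation_radius + 2L
  all_kp <- NULL
  level_imgs <- list()
  for (lev in seq_len(params$n_levels) - 1L) {
    s <- params$scale_factor^lev
    nh <- round(nrow(img) / s); nw <- round(ncol(img) / s)
    if (nh < 2L * margin + 3L || nw < 2L * margin + 3L) break
    limg <- if (lev == 0L) img else resize_bilinear(img, nh, nw)
    sm1 <- gaussian_blur(limg, params$detect_sigma)
    kp <- fast_detect(sm1, params$fast_threshold, params$fast_n_contiguous)
    if (nrow(kp) > 0L) {
      kp <- kp[kp$x > margin & kp$x <= nw - margin &
                 kp$y > margin & kp$y <= nh - margin, , drop = FALSE]
    }
    if (nrow(kp) > 0L) {
      kp$response <- harris_response(sm1, kp, params$harris_k, params$harris_block)
      kp <- kp[!is.na(kp$response), , drop = FALSE]
      if (nrow(kp) > 0L) {
        kp$octave <- lev
        level_imgs[[as.character(lev)]] <- list(sm1 = sm1,
                                                sm2 = gaussian_blur(limg, params$describe_sigma))
        all_kp <- rbind(all_kp, kp)
      }
    }
  }
  if (is.null(all_kp) || nrow(all_kp) == 0L)
    stop_insufficient_features("orb", "no FAST keypoints detected")
  all_kp <- all_kp[order(-all_kp$response, all_kp$y, all_kp$x), , drop = FALSE]
  if (nrow(all_kp) > params$n_features)
    all_kp <- all_kp[seq_len(params$n_features), , drop = FALSE]
  n <- nrow(all_kp)
  desc <- matrix(as.raw(0L), 32L, n)
  angle <- numeric(n)
  for (i in seq_len(n)) {
    lev <- all_kp$octave[i]
    li <- level_imgs[[as.character(lev)]]
    kp_i <- list(x = all_kp$x[i], y = all_kp$y[i])
    angle[i] <- orientation_centroid(li$sm1, kp_i, params$orientation_radius)
    desc[, i] <- brief_describe(li$sm2, kp_i, pattern, angle[i])
  }
  sf <- params$scale_factor^all_kp$octave
  keypoints <- data.frame(
    x = (all_kp$x - 0.5) * sf + 0.5,
    y = (all_kp$y - 0.5) * sf + 0.5,
    octave = all_kp$octave,
    scale = params$patch_size * sf,
    angle = angle,
    response = all_kp$response)
  ord <- order(-keypoints$response, keypoints$y, keypoints$x)
  structure(list(keypoints = keypoints[ord, , drop = FALSE],
                 descriptors = desc[, ord, drop = FALSE],
                 method = "orb", nbits = 256L),
            class = "sinus_features")
}

#' @export
print.sinus_features <- function(x, ...) {
  cat(sprintf("sinus_features: %d %s keypoints, %d-bit descriptors\n",
              nrow(x$keypoints), toupper(x$method), x$nbits))
  invisible(x)
}

stop_insufficient_features <- function(method, msg) {
  stop(structure(class = c("sinusid_insufficient_features", "error", "condition"),
                 list(message = sprintf("insufficient features (%s): %s", method, msg),
                      call = sys.call(-1L))))
}
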