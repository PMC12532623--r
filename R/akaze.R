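# AKAZE-style binary feature pipeline, built from scratch: a nonlinear
# (edge-preserving) scale space advanced with Fast Explicit Diffusion,
# scale-normalized Hessian-determinant keypoints, gradient-sector
# orientation, and a 486-bit full M-LDB descriptor over intensity and
# first-derivative channels. This is deliberately an "AKAZE-lite": g2
# conductivity only, no sub-pixel refinement, no descriptor subsampling;
# bit-parity with third-party builds is a non-goal.

#' AKAZE extractor parameters
#'
#' @param octaves number of octaves (2x downsampling between octaves).
#' @param sublevels evolution sublevels per octave.
#' @param sigma0 base scale in pixels.
#' @param tau_max FED stability step bound.
#' @param contrast_percentile percentile of the gradient histogram defining
#'   the conductivity contrast factor k.
#' @param response_threshold minimum scale-normalized Hessian response.
#' @param n_features maximum keypoints kept (by response).
#' @param patch_scale M-LDB patch half-width as a multiple of the keypoint
#'   scale (in octave pixels).
#' @param orientation_radius_factor orientation disc radius as a multiple of
#'   the keypoint scale.
#' @return an `akaze_params` list.
#' @export
akaze_params <- function(octaves = 4L, sublevels = 4L, sigma0 = 1.6,
                         tau_max = 0.25, contrast_percentile = 70,
                         response_threshold = 1e-4, n_features = 500L,
                         patch_scale = 10, orientation_radius_factor = 6) {
  p <- list(octaves = as.integer(octaves), sublevels = as.integer(sublevels),
            sigma0 = sigma0, tau_max = tau_max,
            contrast_percentile = contrast_percentile,
            response_threshold = response_threshold,
            n_features = as.integer(n_features), patch_scale = patch_scale,
            orientation_radius_factor = orientation_radius_factor)
  class(p) <- "akaze_params"
  p
}

#' Contrast factor for the conductivity function
#'
#' The given percentile of the nonzero Scharr gradient magnitudes of the
#' lightly smoothed (sigma = 1) image, computed from a 300-bin histogram over
#' (0, max]. An all-zero gradient field falls back to k = 0.03 with a
#' warning.
#'
#' @param image grayscale numeric matrix.
#' @param percentile histogram percentile (default 70).
#' @param nbins number of histogram bins.
#' @return the contrast factor k.
#' @export
contrast_factor <- function(image, percentile = 70, nbins = 300L) {
  sm <- gaussian_blur(image, 1)
  mag <- sqrt(scharr_x(sm)^2 + scharr_y(sm)^2)
  mag <- mag[mag > 0]
  if (length(mag) == 0L) {
    warning("all gradients zero; falling back to k = 0.03")
    return(0.03)
  }
  breaks <- seq(0, max(mag), length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(mag, breaks, left.open = TRUE,
                                       rightmost.closed = TRUE), nbins),
                     nbins = nbins)
  target <- percentile / 100 * length(mag)
  bin <- which(cumsum(counts) >= target)[1L]
  breaks[bin + 1L]
}

#' Perona-Malik g2 conductivity
#'
#' `g = 1 / (1 + |grad L|^2 / k^2)`, elementwise; values in (0, 1].
#'
#' @param grad_mag gradient magnitude (matrix or vector).
#' @param k contrast factor (> 0).
#' @return conductivity of the same shape.
#' @export
conductivity_g2 <- function(grad_mag, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) stop("k must be a positive scalar")
  1 / (1 + (grad_mag / k)^2)
}

#' Fast Explicit Diffusion step schedule
#'
#' One FED cycle of n steps advances the evolution by `tau_max n(n+1)/3`
#' using steps `tau_j = tau_max / (2 cos^2(pi (2j+1) / (4n+2)))`. The
#' smallest n whose cycle time reaches the requested increment is chosen and
#' the steps are rescaled so their sum equals `total_time` exactly.
#'
#' @param total_time targeted evolution-time increment (> 0).
#' @param tau_max stability bound for a single explicit step.
#' @return a `fed_schedule` list with `n_steps`, `tau_max`, `taus`.
#' @export
fed_schedule <- function(total_time, tau_max = 0.25) {
  if (total_time <= 0) stop("total_time must be > 0")
  n <- 1L
  while (tau_max * n * (n + 1) / 3 < total_time) n <- n + 1L
  j <- seq_len(n) - 1L
  taus <- tau_max / (2 * cos(pi * (2 * j + 1) / (4 * n + 2))^2)
  taus <- taus * (total_time / sum(taus))
  structure(list(n_steps = n, tau_max = tau_max, taus = taus),
            class = "fed_schedule")
}

#' Build the nonlinear scale space
#'
#' Evolution times follow `sigma_i = sigma0 2^(o + s/sublevels)`,
#' `t_i = sigma_i^2 / 2` (expressed in each octave's own pixel units).
#' The base layer is the input smoothed to `sigma0`; between consecutive
#' layers the image evolves by explicit diffusion steps
#' `L <- L + tau div(g grad L)` with g2 conductivity (contrast factor
#' recomputed per octave) and zero-flux boundaries. Each octave after the
#' first operates on a 2x downsampled copy of the previous octave's last
#' layer. Octaves whose image would fall below 32 pixels on a side are
#' dropped with a warning.
#'
#' @param image grayscale numeric matrix.
#' @param params an [akaze_params()] object.
#' @param conductivity `"g2"` (default) or `"constant"`; the constant case
#'   (g = 1) reduces the evolution to linear diffusion and is used to verify
#'   the Gaussian limit.
#' @return a `sinus_scale_space` list of layers, each with `L`, `Lx`, `Ly`,
#'   `sigma` (base-resolution scale), `sigma_local`, `octave`, `sublevel`,
#'   `time`.
#' @export
build_nonlinear_scale_space <- function(image, params = akaze_params(),
                                        conductivity = c("g2", "constant")) {
  conductivity <- match.arg(conductivity)
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  S <- params$sublevels
  layers <- list()
  cur <- gaussian_blur(img, params$sigma0)
  cur_t <- params$sigma0^2 / 2
  for (o in seq_len(params$octaves) - 1L) {
    if (o > 0L) {
      nh <- ceiling(nrow(cur) / 2); nw <- ceiling(ncol(cur) / 2)
      if (nh < 32L || nw < 32L) {
        warning(sprintf("image too small for octave %d; using %d octaves", o, o))
        break
      }
      cur <- resize_bilinear(cur, nh, nw)
      # local scale halves with the resolution
      cur_t <- cur_t / 4
    }
    k <- if (conductivity == "g2") contrast_factor(cur, params$contrast_percentile) else NA
    for (s in seq_len(S) - 1L) {
      sigma <- params$sigma0 * 2^(o + s / S)
      sigma_local <- sigma / 2^o
      t_target <- sigma_local^2 / 2
      if (t_target > cur_t + 1e-12) {
        g <- if (conductivity == "constant") {
          matrix(1, nrow(cur), ncol(cur))
        } else {
          conductivity_g2(sqrt(scharr_x(cur)^2 + scharr_y(cur)^2), k)
        }
        sched <- fed_schedule(t_target - cur_t, params$tau_max)
        for (tau in sched$taus) cur <- fed_step_cpp(cur, g, tau)
        cur_t <- t_target
      }
      layers[[length(layers) + 1L]] <-
        list(L = cur, Lx = scharr_x(cur), Ly = scharr_y(cur),
             sigma = sigma, sigma_local = sigma_local,
             octave = o, sublevel = s, time = cur_t)
    }
  }
  structure(list(layers = layers, params = params,
                 dims = dim(img), conductivity = conductivity),
            class = "sinus_scale_space")
}

#' @export
print.sinus_scale_space <- function(x, ...) {
  cat(sprintf("sinus_scale_space: %d layers, sigma %.2f .. %.2f\n",
              length(x$layers), x$layers[[1L]]$sigma,
              x$layers[[length(x$layers)]]$sigma))
  invisible(x)
}

#' Scale-space extrema by exhaustive neighbour comparison
#'
#' Given a list of same-size response matrices (ordered fine to coarse), a
#' pixel is an extremum iff its response exceeds the threshold and is
#' strictly greater than its 8 spatial neighbours in-layer and all 9
#' neighbours in each adjacent layer that exists. Plateaus yield nothing.
#'
#' @param responses list of numeric matrices.
#' @param threshold minimum response.
#' @return data frame with `x`, `y`, `layer`, `response`.
#' @export
scale_space_extrema <- function(responses, threshold = 1e-4) {
  nl <- length(responses)
  out <- NULL
  for (l in seq_len(nl)) {
    r <- responses[[l]]
    keep <- r > threshold
    for (dl in -1:1) {
      if (l + dl < 1L || l + dl > nl) next
      other <- responses[[l + dl]]
      for (dy in -1:1) for (dx in -1:1) {
        if (dl == 0L && dy == 0L && dx == 0L) next
        keep <- keep & (r > shift_img_zero(other, dy, dx))
      }
    }
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      out <- rbind(out, data.frame(x = idx[, 2L], y = idx[, 1L],
                                   layer = l, response = r[idx]))
    }
  }
  if (is.null(out)) out <- data.frame(x = integer(), y = integer(),
                                      layer = integer(), response = numeric())
  out
}

#' Detect Hessian-determinant keypoints in a nonlinear scale space
#'
#' The response is the scale-normalized Hessian determinant
#' `(sigma^2 Lxx)(sigma^2 Lyy) - (sigma^2 Lxy)^2` with sigma the layer's
#' local scale and second derivatives from repeated Scharr filtering.
#' Responses are comparable within an octave; across octaves the pyramid
#' downsampling attenuates the discrete derivatives of coarse layers
#' somewhat, which biases competition between octaves toward the finer one.
#' Extrema are strict maxima over the 8 in-layer and 9+9 adjacent-layer
#' neighbours (within the octave); coordinates are mapped to base
#' resolution.
#'
#' @param ss a `sinus_scale_space`.
#' @param response_threshold minimum response.
#' @return data frame with `x`, `y` (base resolution), `layer_index`,
#'   `octave`, `sigma`, `sigma_local`, `response`.
#' @export
detect_hessian_extrema <- function(ss, response_threshold = 1e-4) {
  if (length(ss$layers) < 3L) stop("need at least 3 layers")
  octs <- vapply(ss$layers, function(l) l$octave, numeric(1))
  out <- NULL
  for (o in unique(octs)) {
    li <- which(octs == o)
    resp <- lapply(li, function(i) {
      lay <- ss$layers[[i]]
      s2 <- lay$sigma_local^2
      lxx <- scharr_x(lay$Lx) * s2
      lyy <- scharr_y(lay$Ly) * s2
      lxy <- scharr_y(lay$Lx) * s2
      lxx * lyy - lxy^2
    })
    ex <- scale_space_extrema(resp, response_threshold)
    if (nrow(ex) > 0L) {
      lay_idx <- li[ex$layer]
      out <- rbind(out, data.frame(
        x = (ex$x - 0.5) * 2^o + 0.5,
        y = (ex$y - 0.5) * 2^o + 0.5,
        layer_index = lay_idx,
        octave = o,
        sigma = vapply(lay_idx, function(i) ss$layers[[i]]$sigma, numeric(1)),
        sigma_local = vapply(lay_idx, function(i) ss$layers[[i]]$sigma_local, numeric(1)),
        response = ex$response))
    }
  }
  if (is.null(out)) out <- data.frame(x = numeric(), y = numeric(),
                                      layer_index = integer(), octave = numeric(),
                                      sigma = numeric(), sigma_local = numeric(),
                                      response = numeric())
  out
}

# Gradient-weighted dominant orientation: gradients sampled on the integer
# grid within radius 6 sigma of the keypoint (octave pixels), weighted by a
# Gaussian of sd 2.5 sigma; a 60-degree sector slides over the gradient
# angles and theta is the direction of the largest summed gradient vector.
akaze_orientation <- function(layer, x, y, sigma_local, radius_factor = 6) {
  r <- max(3L, round(radius_factor * sigma_local))
  off <- disc_offsets(r)
  ys <- y + off$dy; xs <- x + off$dx
  ok <- ys >= 1L & ys <= nrow(layer$L) & xs >= 1L & xs <= ncol(layer$L)
  if (!any(ok)) return(0)
  gx <- layer$Lx[cbind(ys[ok], xs[ok])]
  gy <- layer$Ly[cbind(ys[ok], xs[ok])]
  w <- exp(-(off$dy[ok]^2 + off$dx[ok]^2) / (2 * (2.5 * sigma_local)^2))
  gx <- gx * w; gy <- gy * w
  ang <- atan2(gy, gx)
  centres <- seq(0, 2 * pi, length.out = 43L)[-43L]
  best <- 0; best_norm <- -1
  for (ct in centres) {
    d <- abs((ang - ct + pi) %% (2 * pi) - pi)
    sel <- d <= pi / 6
    if (!any(sel)) next
    sx <- sum(gx[sel]); sy <- sum(gy[sel])
    nrm <- sx * sx + sy * sy
    if (nrm > best_norm) { best_norm <- nrm; best <- atan2(sy, sx) }
  }
  best %% (2 * pi)
}

#' Full M-LDB descriptor
#'
#' Over a theta-rotated square patch scaled to the keypoint (half-width
#' `patch_scale * sigma_local`), sampled on a 24x24 lattice, the patch is
#' partitioned into 2x2, 3x3 and 4x4 grids; for each cell the mean
#' intensity, mean Lx and mean Ly are computed (derivatives rotated into the
#' keypoint frame), and one bit per unordered cell pair and channel encodes
#' `mean_a > mean_b`. Total `(6 + 36 + 120) * 3 = 486` bits, padded to 61
#' bytes. Cells are ordered row-major; bits are ordered by grid (2, 3, 4),
#' then channel (intensity, Lx, Ly), then pair `(a < b)` lexicographically.
#'
#' @param layer scale-space layer (list with `L`, `Lx`, `Ly`).
#' @param x,y keypoint position in the layer's pixel coordinates.
#' @param sigma_local keypoint scale in the layer's pixels.
#' @param theta orientation in radians.
#' @param patch_scale patch half-width in units of `sigma_local`.
#' @return raw vector of 61 bytes, or NULL if the rotated patch leaves the
#'   layer (insufficient support; the keypoint is dropped upstream).
#' @export
mldb_describe <- function(layer, x, y, sigma_local, theta = 0, patch_scale = 10) {
  h <- patch_scale * sigma_local
  grid_n <- 24L
  u <- h * (2 * (seq_len(grid_n) - 0.5) / grid_n - 1)
  U <- matrix(u, grid_n, grid_n, byrow = TRUE)  # x offsets
  V <- matrix(u, grid_n, grid_n)                # y offsets
  ct <- cos(theta); st <- sin(theta)
  xs <- round(x + ct * U - st * V)
  ys <- round(y + st * U + ct * V)
  if (min(xs) < 1L || max(xs) > ncol(layer$L) || min(ys) < 1L || max(ys) > nrow(layer$L))
    return(NULL)
  ii <- cbind(as.vector(ys), as.vector(xs))
  chL <- layer$L[ii]
  gx <- layer$Lx[ii]; gy <- layer$Ly[ii]
  chX <- ct * gx + st * gy
  chY <- -st * gx + ct * gy
  bits <- logical(0)
  row_id <- matrix(rep(seq_len(grid_n), grid_n), grid_n, grid_n)  # V index
  col_id <- t(row_id)
  for (ncell in c(2L, 3L, 4L)) {
    cell_r <- ceiling(row_id / (grid_n / ncell))
    cell_c <- ceiling(col_id / (grid_n / ncell))
    cell <- as.vector((cell_r - 1L) * ncell + cell_c)  # row-major cell index
    for (ch in list(chL, chX, chY)) {
      means <- vapply(seq_len(ncell^2), function(k) mean(ch[cell == k]), numeric(1))
      pr <- utils::combn(ncell^2, 2L)
      bits <- c(bits, means[pr[1L, ]] > means[pr[2L, ]])
    }
  }
  packBits(c(bits, rep(FALSE, 2L)))
}

#' Extract AKAZE-style keypoints and descriptors
#'
#' Composes the nonlinear scale space, Hessian-determinant detection,
#' sector orientation and M-LDB description; keeps the strongest
#' `n_features` by response, drops keypoints whose rotated patch lacks
#' support, and sorts canonically (response decreasing, then y, then x).
#' Deterministic.
#'
#' @param image a [binary_silhouette()] or any grayscale matrix.
#' @param params an [akaze_params()] object.
#' @return a `sinus_features` list (486-bit descriptors in 61-byte columns).
#' @export
akaze_extract <- function(image, params = akaze_params()) {
  img <- if (inherits(image, "binary_silhouette")) sil_gray(image)
  else matrix(as.numeric(image), nrow(image), ncol(image))
  ss <- suppressWarnings(build_nonlinear_scale_space(img, params))
  kp <- detect_hessian_extrema(ss, params$response_threshold)
  if (nrow(kp) == 0L)
    stop_insufficient_features("akaze", "no Hessian extrema above threshold")
  kp <- kp[order(-kp$response, kp$y, kp$x), , drop = FALSE]
  rows <- list(); descs <- list()
  for (i in seq_len(nrow(kp))) {
    if (length(rows) >= params$n_features) break
    lay <- ss$layers[[kp$layer_index[i]]]
    xl <- (kp$x[i] - 0.5) / 2^kp$octave[i] + 0.5
    yl <- (kp$y[i] - 0.5) / 2^kp$octave[i] + 0.5
    th <- akaze_orientation(lay, round(xl), round(yl), kp$sigma_local[i],
                            params$orientation_radius_factor)
    d <- mldb_describe(lay, xl, yl, kp$sigma_local[i], th, params$patch_scale)
    if (is.null(d)) next
    r <- kp[i, , drop = FALSE]
    r$angle <- th
    rows[[length(rows) + 1L]] <- r
    descs[[length(descs) + 1L]] <- d
  }
  if (length(rows) == 0L)
    stop_insufficient_features("akaze", "no keypoint with full descriptor support")
  kp2 <- do.call(rbind, rows)
  keypoints <- data.frame(x = kp2$x, y = kp2$y, octave = kp2$octave,
                          scale = kp2$sigma, angle = kp2$angle,
                          response = kp2$response)
  desc <- do.call(cbind, descs)
  ord <- order(-keypoints$response, keypoints$y, keypoints$x)
  structure(list(keypoints = keypoints[ord, , drop = FALSE],
                 descriptors = desc[, ord, drop = FALSE],
                 method = "akaze", nbits = 486L),
            class = "sinus_features")
}
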