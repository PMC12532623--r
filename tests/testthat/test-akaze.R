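test_that("contrast factor follows the gradient histogram", {
  expect_warning(k0 <- contrast_factor(matrix(0.5, 40, 40)), "zero")
  expect_equal(k0, 0.03)
  # linear ramp: a single nonzero gradient magnitude -> k within a bin width
  ramp <- matrix(seq_len(64), 64, 64, byrow = TRUE) / 64
  k <- contrast_factor(ramp)
  mag <- sqrt(sinusid:::scharr_x(gaussian_blur(ramp, 1))^2 +
                sinusid:::scharr_y(gaussian_blur(ramp, 1))^2)
  interior <- mag[5:60, 5:60]
  g0 <- stats::median(interior[interior > 0])
  expect_lt(abs(k - g0), max(mag) / 300 + 1e-12)
  # doubling intensities doubles k, within bin resolution
  k2 <- contrast_factor(2 * ramp)
  expect_lt(abs(k2 - 2 * k), 2 * max(mag) / 300 + 1e-12)
})

test_that("g2 conductivity obeys its closed form", {
  expect_equal(conductivity_g2(0, 0.1), 1)
  expect_equal(conductivity_g2(0.1, 0.1), 0.5)
  withr::with_seed(1, m <- matrix(stats::runif(100), 10, 10))
  g <- conductivity_g2(m, 0.07)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) oracle[i, j] <- 1 / (1 + m[i, j]^2 / 0.07^2)
  expect_equal(g, oracle, tolerance = 1e-14)
  expect_true(all(g > 0 & g <= 1))
  expect_error(conductivity_g2(m, 0), "positive")
})

test_that("FED schedules satisfy the cycle-time identity and rescaling contract", {
  # n = 1: tau_0 = tau_max / (2 cos^2(pi/6)) = (2/3) tau_max before rescaling
  tau_max <- 0.25
  raw_tau0 <- tau_max / (2 * cos(pi / 6)^2)
  expect_equal(raw_tau0, 2 / 3 * tau_max, tolerance = 1e-12)
  # cycle time identity: sum tau_j = tau_max n (n+1) / 3
  for (n in c(1, 2, 4, 7)) {
    j <- 0:(n - 1)
    taus <- tau_max / (2 * cos(pi * (2 * j + 1) / (4 * n + 2))^2)
    expect_equal(sum(taus), tau_max * n * (n + 1) / 3, tolerance = 1e-9)
  }
  # requesting exactly a full cycle time yields exactly n steps
  T4 <- tau_max * 4 * 5 / 3
  s4 <- fed_schedule(T4, tau_max)
  expect_equal(s4$n_steps, 4L)
  # rescaling: sums match the target to 1e-9 for arbitrary T
  for (T in c(0.01, 0.3, 1.7, 12.9)) {
    s <- fed_schedule(T, tau_max)
    expect_lt(abs(sum(s$taus) - T), 1e-9)
    expect_true(all(s$taus > 0))
  }
  expect_error(fed_schedule(0), "total_time")
})

test_that("with g = 1 the nonlinear evolution reduces to Gaussian smoothing", {
  img <- bumpy_image(64, 64, n_bumps = 5, seed = 4)
  ss <- build_nonlinear_scale_space(img, akaze_params(octaves = 1, sublevels = 4),
                                    conductivity = "constant")
  for (lay in ss$layers) {
    ref <- gaussian_blur(img, lay$sigma)
    expect_lt(max(abs(lay$L - ref)), 0.02)
  }
})

test_that("scale-space sigmas increase strictly and double per octave", {
  img <- bumpy_image(128, 128, n_bumps = 6, seed = 5)
  ss <- build_nonlinear_scale_space(img, akaze_params(octaves = 2, sublevels = 4))
  sig <- vapply(ss$layers, function(l) l$sigma, numeric(1))
  expect_true(all(diff(sig) > 0))
  octs <- vapply(ss$layers, function(l) l$octave, numeric(1))
  s0 <- sig[octs == 0][1]
  s1 <- sig[octs == 1][1]
  expect_equal(s1 / s0, 2)
  expect_equal(length(ss$layers), 8L)
})

test_that("diffusion conserves total intensity under zero-flux boundaries", {
  img <- bumpy_image(64, 64, n_bumps = 5, seed = 6)
  ss <- build_nonlinear_scale_space(img, akaze_params(octaves = 1, sublevels = 4))
  total0 <- sum(img)
  for (lay in ss$layers) {
    expect_lt(abs(sum(lay$L) - total0) / total0, 0.005)
  }
})

test_that("extrema detection equals the brute-force 26-neighbour oracle", {
  withr::with_seed(7, {
    stack <- lapply(1:3, function(i) gaussian_blur(matrix(stats::runif(30 * 30), 30, 30), 1.5))
  })
  got <- scale_space_extrema(stack, threshold = 1e-6)
  # oracle: exhaustive strict comparison over all existing neighbours
  oracle <- NULL
  for (l in 1:3) for (y in 1:30) for (x in 1:30) {
    v <- stack[[l]][y, x]
    if (v <= 1e-6) next
    ok <- TRUE
    for (dl in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dl == 0 && dy == 0 && dx == 0) next
      ll <- l + dl; yy <- y + dy; xx <- x + dx
      if (ll < 1 || ll > 3 || yy < 1 || yy > 30 || xx < 1 || xx > 30) next
      if (v <= stack[[ll]][yy, xx]) { ok <- FALSE; break }
    }
    if (ok) oracle <- rbind(oracle, data.frame(x = x, y = y, layer = l))
  }
  got_keys <- sort(paste(got$layer, got$y, got$x))
  oracle_keys <- sort(paste(oracle$layer, oracle$y, oracle$x))
  expect_identical(got_keys, oracle_keys)
  expect_equal(nrow(scale_space_extrema(list(matrix(1, 10, 10),
                                             matrix(1, 10, 10),
                                             matrix(1, 10, 10)))), 0L)
})

test_that("the detector selects the scale of an analytic Gaussian blob", {
  # single-octave ladder spanning the blob scale: responses within one
  # resolution level are directly comparable (across octaves, downsampling
  # attenuates the discrete derivatives, so scale competition is checked
  # where the normalization makes it exact)
  n <- 96
  X <- matrix(seq_len(n), n, n, byrow = TRUE); Y <- matrix(seq_len(n), n, n)
  blob <- exp(-((X - n / 2)^2 + (Y - n / 2)^2) / (2 * 4^2))
  ss <- build_nonlinear_scale_space(blob,
                                    akaze_params(octaves = 1, sublevels = 4,
                                                 sigma0 = 3),
                                    conductivity = "constant")
  kp <- detect_hessian_extrema(ss, 1e-6)
  expect_gt(nrow(kp), 0)
  top <- kp[which.max(kp$response), ]
  # blob centre, and scale within one sublevel (factor 2^(1/4)) of sigma_b = 4
  expect_lt(abs(top$x - n / 2), 3)
  expect_lt(abs(top$y - n / 2), 3)
  expect_lte(abs(log2(top$sigma / 4)), 1 / 4 + 1e-9)
})

test_that("M-LDB has 486 bits and honours cell-mean comparisons", {
  # combinatorial identity behind the length
  expect_equal((choose(4, 2) + choose(9, 2) + choose(16, 2)) * 3, 486)
  img <- bumpy_image(80, 80, seed = 9)
  ss <- build_nonlinear_scale_space(img, akaze_params(octaves = 1, sublevels = 4))
  lay <- ss$layers[[2]]
  d <- mldb_describe(lay, x = 40, y = 40, sigma_local = 2, theta = 0)
  expect_length(d, 61L)
  expect_equal(hamming(d, d), 0L)
  # left-bright / right-dark patch: in the 2x2 grid every intensity
  # comparison between a left and a right cell must say left > right
  grad <- matrix(seq(1, 0, length.out = 80), 80, 80, byrow = TRUE)  # bright at low x
  ss2 <- build_nonlinear_scale_space(grad, akaze_params(octaves = 1, sublevels = 4))
  lay2 <- ss2$layers[[1]]
  d2 <- mldb_describe(lay2, x = 40, y = 40, sigma_local = 2, theta = 0)
  bits <- as.logical(rawToBits(d2))[1:486]
  # 2x2 grid cells row-major: 1=TL, 2=TR, 3=BL, 4=BR; intensity channel bits
  # are the first 6: pairs (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  pairs <- utils::combn(4, 2)
  left <- c(1, 3); right <- c(2, 4)
  intensity_bits <- bits[1:6]
  for (k in 1:6) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (a %in% left && b %in% right) expect_true(intensity_bits[k])
    if (a %in% right && b %in% left) expect_false(intensity_bits[k])
  }
})

test_that("akaze_extract is deterministic and rotation-robust on silhouettes", {
  s <- generate_shape(synth_params(seed = 6), 3)
  f1 <- akaze_extract(s)
  f2 <- akaze_extract(s)
  expect_identical(f1$keypoints, f2$keypoints)
  expect_identical(f1$descriptors, f2$descriptors)
  expect_gte(nrow(f1$keypoints), 10)
  expect_equal(f1$nbits, 486L)
  expect_true(all(dim(f1$descriptors) == c(61, nrow(f1$keypoints))))
  expect_error(akaze_extract(matrix(0.5, 100, 200)),
               class = "sinusid_insufficient_features")

  # 90-degree rotation: matched descriptor pairs stay close in Hamming space
  img <- sinusid:::sil_gray(s)
  f90 <- akaze_extract(rot90_image(img))
  mx <- nrow(img) + 1 - f1$keypoints$y
  my <- f1$keypoints$x
  dists <- c()
  for (i in seq_len(nrow(f1$keypoints))) {
    j <- which(abs(f90$keypoints$x - mx[i]) <= 2 & abs(f90$keypoints$y - my[i]) <= 2)
    if (length(j) == 0) next
    dists <- c(dists, hamming(f1$descriptors[, i], f90$descriptors[, j[1]]))
  }
  expect_gte(length(dists), 5)
  expect_lte(stats::median(dists), 120)
})
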