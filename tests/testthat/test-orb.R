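test_that("FAST detection matches the exhaustive arc-checking oracle", {
  # exactness on a batch of random images (full 100-image sweep lives in the
  # acceptance suite; a shorter one here keeps the unit run fast)
  for (trial in 1:10) {
    img <- withr::with_seed(trial, matrix(stats::runif(32 * 32), 32, 32))
    got <- fast_score_cpp(img, 0.05, 9L)
    want <- fast_oracle(img, 0.05, 9L)
    expect_identical(got, want)
  }
})

test_that("FAST trivial cases: uniform images and overlarge thresholds", {
  expect_equal(nrow(fast_detect(matrix(0.5, 20, 20))), 0L)
  img <- bumpy_image(30, 30, seed = 2)
  expect_equal(nrow(fast_detect(img, intensity_threshold = 2)), 0L)
  expect_error(fast_detect(matrix(0, 5, 5)), "7x7")
})

test_that("FAST finds the corners of a bright square", {
  img <- matrix(0, 40, 40)
  img[11:30, 11:30] <- 1
  kp <- fast_detect(img, intensity_threshold = 0.3)
  expect_gt(nrow(kp), 0)
  corners <- rbind(c(11, 11), c(11, 30), c(30, 11), c(30, 30))
  for (i in seq_len(nrow(kp))) {
    d <- sqrt(min((corners[, 1] - kp$y[i])^2 + (corners[, 2] - kp$x[i])^2))
    expect_lt(d, 3)
  }
})

test_that("Harris response ranks corners above edges and ignores offsets", {
  # ideal step corner vs ideal straight edge, evaluated at the centre
  corner <- matrix(0, 21, 21); corner[11:21, 11:21] <- 1
  edge <- matrix(0, 21, 21); edge[, 11:21] <- 1
  kp <- data.frame(x = 11, y = 11)
  rc <- harris_response(corner, kp)
  re <- harris_response(edge, kp)
  expect_gt(rc, re)
  flat <- harris_response(matrix(0.7, 21, 21), kp)
  expect_equal(flat, 0)
  rc_off <- harris_response(corner + 0.25, kp)
  expect_equal(rc, rc_off, tolerance = 1e-12)
  # no block support -> NA, not an error
  expect_true(is.na(harris_response(corner, data.frame(x = 2, y = 2))))
})

test_that("intensity-centroid orientation follows the dominant direction", {
  n <- 41
  ramp_x <- matrix(seq_len(n), n, n, byrow = TRUE) / n
  kp <- list(x = 21, y = 21)
  expect_equal(orientation_centroid(ramp_x, kp), 0)
  # the same patch rotated by 90 degrees
  r90 <- rot90_image(ramp_x)
  expect_equal(orientation_centroid(r90, kp), pi / 2, tolerance = 0.05)
  # radially symmetric patch -> 0 by convention
  sym <- matrix(0, n, n)
  for (y in 1:n) for (x in 1:n) sym[y, x] <- (x - 21)^2 + (y - 21)^2
  expect_equal(orientation_centroid(sym / max(sym), kp), 0)
})

test_that("BRIEF bits behave on degenerate and identical patches", {
  img <- bumpy_image(64, 64, seed = 3)
  kp <- list(x = 32, y = 32)
  d <- brief_describe(img, kp, theta = 0.7)
  expect_length(d, 32L)
  expect_equal(hamming(d, d), 0L)
  # constant patch: strict < is false everywhere -> all-zero bit string
  d0 <- brief_describe(matrix(0.4, 64, 64), kp, theta = 0)
  expect_true(all(d0 == as.raw(0)))
})

test_that("steered BRIEF is robust to in-plane rotation", {
  # blob image with corners; rotate by 90 deg exactly, re-estimate theta per
  # patch, and require median Hamming across matched keypoints <= 64/256
  img <- bumpy_image(120, 120, n_bumps = 24, seed = 8)
  f1 <- orb_extract(img, orb_params(n_levels = 1, fast_threshold = 0.05))
  img2 <- rot90_image(img)
  f2 <- orb_extract(img2, orb_params(n_levels = 1, fast_threshold = 0.05))
  # map f1 keypoints into rotated frame: (x, y) -> (nr + 1 - y, x)
  mx <- nrow(img) + 1 - f1$keypoints$y
  my <- f1$keypoints$x
  dists <- c()
  for (i in seq_len(nrow(f1$keypoints))) {
    j <- which(abs(f2$keypoints$x - mx[i]) <= 1.5 & abs(f2$keypoints$y - my[i]) <= 1.5)
    if (length(j) == 0) next
    j <- j[1]
    dists <- c(dists, hamming(f1$descriptors[, i], f2$descriptors[, j]))
  }
  expect_gte(length(dists), 20)
  expect_lte(stats::median(dists), 64)
})

test_that("orientation is equivariant under image rotation", {
  img <- bumpy_image(120, 120, n_bumps = 24, seed = 8)
  f1 <- orb_extract(img, orb_params(n_levels = 1, fast_threshold = 0.05))
  for (k in 1:3) {
    phi <- k * pi / 2
    imgk <- rot90_image(img, k)
    fk <- orb_extract(imgk, orb_params(n_levels = 1, fast_threshold = 0.05))
    # rotated coords of f1 keypoints
    x <- f1$keypoints$x; y <- f1$keypoints$y
    for (r in seq_len(k)) { tmp <- nrow(img) + 1 - y; y <- x; x <- tmp }
    errs <- c()
    for (i in seq_along(x)) {
      j <- which(abs(fk$keypoints$x - x[i]) <= 1.5 & abs(fk$keypoints$y - y[i]) <= 1.5)
      if (length(j) == 0) next
      d <- abs((fk$keypoints$angle[j[1]] - f1$keypoints$angle[i] - phi + pi) %%
                 (2 * pi) - pi)
      errs <- c(errs, d)
    }
    expect_gte(length(errs), 10)
    expect_lt(stats::median(errs), 0.1)
  }
})

test_that("orb_extract is deterministic, caps features, and feeds silhouettes", {
  s <- generate_shape(synth_params(seed = 6), 2)
  f1 <- orb_extract(s)
  f2 <- orb_extract(s)
  expect_identical(f1$keypoints, f2$keypoints)
  expect_identical(f1$descriptors, f2$descriptors)
  expect_gte(nrow(f1$keypoints), 10)
  expect_true(all(dim(f1$descriptors) == c(32, nrow(f1$keypoints))))
  expect_true(all(f1$keypoints$angle >= 0 & f1$keypoints$angle < 2 * pi))
  f_one <- orb_extract(s, orb_params(n_features = 1))
  expect_lte(nrow(f_one$keypoints), 1L)
  expect_error(orb_extract(matrix(0.5, 100, 200)),
               class = "sinusid_insufficient_features")
})
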