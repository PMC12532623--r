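# Independent, deliberately naive reference implementations used as oracles.
# Each recomputes a quantity by direct enumeration or closed form, with no
# shared code path with the package internals it checks.

# FAST segment test by explicit per-pixel arc checking (same published
# definition: >= n_contig contiguous circle pixels all brighter than I+t or
# all darker than I-t; score = sum of |I(c)-I(p)| over circle pixels of the
# detected polarity, in circle order).
fast_oracle <- function(img, t, n_contig = 9L) {
  circ_dy <- c(-3L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  circ_dx <- c(0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L, -3L, -3L, -2L, -1L)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (y in 4:(nr - 3)) {
    for (x in 4:(nc - 3)) {
      v <- img[y, x]
      cvals <- img[cbind(y + circ_dy, x + circ_dx)]
      bright <- cvals > v + t
      dark <- cvals < v - t
      has_run <- function(flags) {
        ext <- c(flags, flags)
        run <- 0L
        for (f in ext[1:(16 + n_contig)]) {
          if (f) { run <- run + 1L; if (run >= n_contig) return(TRUE) } else run <- 0L
        }
        FALSE
      }
      is_b <- has_run(bright); is_d <- has_run(dark)
      if (is_b || is_d) {
        sel <- if (is_b) bright else dark
        s <- 0
        for (k in 1:16) if (sel[k]) s <- s + abs(cvals[k] - v)
        out[y, x] <- s
      }
    }
  }
  out
}

# Hamming distance by per-bit loop over unpacked bits.
hamming_oracle <- function(d1, d2) {
  b1 <- as.integer(rawToBits(d1)); b2 <- as.integer(rawToBits(d2))
  n <- 0L
  for (i in seq_along(b1)) if (b1[i] != b2[i]) n <- n + 1L
  n
}

# Brute-force matching by an exhaustive double loop (ties: lowest target).
bf_oracle <- function(qm, tm) {
  res <- data.frame(query = integer(), target = integer(), distance = integer())
  for (i in seq_len(ncol(qm))) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(ncol(tm))) {
      d <- hamming_oracle(qm[, i], tm[, j])
      if (d < best) { best <- d; bj <- j }
    }
    res <- rbind(res, data.frame(query = i, target = bj, distance = best))
  }
  res
}

# AUC by enumerating every matched x mismatched cross pair.
auc_enum_oracle <- function(matched, mismatched) {
  wins <- 0
  for (m in matched) for (u in mismatched) {
    if (m < u) wins <- wins + 1
    else if (m == u) wins <- wins + 0.5
  }
  wins / (length(matched) * length(mismatched))
}

# Connected-component areas by an independent BFS flood fill (4-connected).
component_areas_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  areas <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- list(c(i, j)); seen[i, j] <- TRUE; a <- 0L
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]; a <- a + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + d
        if (q[1L] >= 1L && q[1L] <= nr && q[2L] >= 1L && q[2L] <= nc &&
            mask[q[1L], q[2L]] && !seen[q[1L], q[2L]]) {
          seen[q[1L], q[2L]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    areas <- c(areas, a)
  }
  areas
}

# Pixel matrix of a silhouette, stripped of metadata attributes.
px_of <- function(s) {
  m <- unclass(s)
  attributes(m) <- list(dim = dim(m))
  m
}

# Random raw descriptor matrix (nbits packed into bytes), one column per
# descriptor.
random_descriptors <- function(n, nbits, seed = 1) {
  withr::with_seed(seed, {
    nbytes <- ceiling(nbits / 8)
    pad <- nbytes * 8L - nbits
    m <- vapply(seq_len(n), function(i) {
      packBits(c(stats::runif(nbits) < 0.5, rep(FALSE, pad)))
    }, raw(nbytes))
    matrix(m, nbytes, n)
  })
}

# A filled disc silhouette (for rotation-invariance checks).
disc_silhouette <- function(radius = 30, cx = 100, cy = 50) {
  px <- matrix(1L, 100L, 200L)
  for (y in 1:100) for (x in 1:200) {
    if ((x - cx)^2 + (y - cy)^2 <= radius^2) px[y, x] <- 0L
  }
  binary_silhouette(px)
}

# Smooth random test image: sum of a few Gaussian bumps (deterministic).
bumpy_image <- function(nr, nc, n_bumps = 6, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(0, nr, nc)
    X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    Y <- matrix(seq_len(nr), nr, nc)
    for (i in seq_len(n_bumps)) {
      cx <- stats::runif(1, 1, nc); cy <- stats::runif(1, 1, nr)
      s <- stats::runif(1, 3, 10); a <- stats::runif(1, 0.3, 1)
      img <- img + a * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * s^2))
    }
    img / max(img)
  })
}

# Rotate an image by an exact multiple of 90 degrees (no resampling).
# One application maps a +x intensity gradient onto +y (y downward), i.e.
# new[y', x'] = old[nrow + 1 - x', y'].
rot90_image <- function(img, times = 1L) {
  for (i in seq_len(times %% 4L)) img <- t(img[rev(seq_len(nrow(img))), , drop = FALSE])
  img
}
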