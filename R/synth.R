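#' Parameters of the synthetic frontal-sinus generator
#'
#' The generator emulates the statistical structure the matching analysis
#' relies on: bilobed/scalloped sinus outlines with high between-individual
#' variation, small within-individual differences between the antemortem and
#' postmortem renderings (head-pose rotation, sub-pixel translation, and a
#' morphological radius change emulating slice-selection jitter), and an
#' optional fraction of near-rectangular "simple" sinuses, the known
#' false-positive risk of silhouette matching.
#'
#' @param n_lobes number of sinus lobes per case (1-4).
#' @param scallop_amp relative amplitude of boundary scalloping (0-0.5).
#' @param asymmetry left/right lobe size ratio (0.2-1.0); 1 = symmetric.
#' @param perturb_rot_deg maximum AM-to-PM rotation, degrees.
#' @param perturb_shift_px maximum AM-to-PM translation per axis, pixels.
#' @param perturb_morph_px maximum erosion/dilation radius, pixels
#'   (models slice-selection jitter).
#' @param simple_shape_frac fraction of cases rendered as near-rectangles (0-1).
#' @param seed root RNG seed; per-case child seeds are derived from it by a
#'   fixed counter scheme so cohorts are extensible without reshuffling.
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_lobes = 3L, scallop_amp = 0.18, asymmetry = 0.7,
                         perturb_rot_deg = 3, perturb_shift_px = 2,
                         perturb_morph_px = 1, simple_shape_frac = 0,
                         seed = 1L) {
  p <- list(n_lobes = as.integer(n_lobes), scallop_amp = scallop_amp,
            asymmetry = asymmetry, perturb_rot_deg = perturb_rot_deg,
            perturb_shift_px = perturb_shift_px,
            perturb_morph_px = as.integer(perturb_morph_px),
            simple_shape_frac = simple_shape_frac, seed = as.integer(seed))
  if (p$n_lobes < 1L || p$n_lobes > 4L) stop("n_lobes must be in 1..4")
  if (p$scallop_amp < 0 || p$scallop_amp > 0.5) stop("scallop_amp must be in [0, 0.5]")
  if (p$asymmetry < 0.2 || p$asymmetry > 1) stop("asymmetry must be in [0.2, 1]")
  if (p$perturb_rot_deg < 0) stop("perturb_rot_deg must be >= 0")
  if (p$perturb_shift_px < 0) stop("perturb_shift_px must be >= 0")
  if (p$perturb_morph_px < 0) stop("perturb_morph_px must be >= 0")
  if (p$simple_shape_frac < 0 || p$simple_shape_frac > 1)
    stop("simple_shape_frac must be in [0, 1]")
  class(p) <- "synth_params"
  p
}

# Even-odd scanline fill of a closed polygon onto an nr x nc logical mask.
# Polygon vertices are continuous (x, y) coordinates in pixel units.
rasterize_polygon <- function(px, py, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  n <- length(px)
  x1 <- px; y1 <- py
  x2 <- px[c(2:n, 1L)]; y2 <- py[c(2:n, 1L)]
  for (row in seq_len(nr)) {
    yc <- row  # sample at pixel centre y = row
    crosses <- ((y1 <= yc) & (y2 > yc)) | ((y2 <= yc) & (y1 > yc))
    if (!any(crosses)) next
    xi <- x1[crosses] + (yc - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      lo <- ceiling(xi[k]); hi <- floor(xi[k + 1L])
      if (hi >= lo) {
        lo <- max(lo, 1L); hi <- min(hi, nc)
        if (hi >= lo) mask[row, lo:hi] <- TRUE
      }
    }
  }
  mask
}

# Fit a foreground mask into the 200x100 canvas: scale preserving aspect so
# the shape fills most of the canvas, centre it, and keep a clear border.
fit_to_canvas <- function(xs, ys, fill = 0.92) {
  W <- 200L; H <- 100L
  rx <- range(xs); ry <- range(ys)
  w <- diff(rx); h <- diff(ry)
  s <- min((W - 8) * fill / w, (H - 8) * fill / h)
  cx <- mean(rx); cy <- mean(ry)
  list(x = (xs - cx) * s + (W + 1) / 2, y = (ys - cy) * s + (H + 1) / 2)
}

#' Generate one synthetic sinus silhouette
#'
#' Renders a radial scalloped-lobe model: 1-4 overlapping lobes placed along
#' a horizontal axis, each a closed polygon `r(phi) = r0 (1 + a sin(k phi +
#' phase))` with per-case random radii, vertical squash, scallop frequency
#' and phase; lobes left of centre are scaled by the asymmetry ratio. With
#' probability `simple_shape_frac` the case is instead rendered as a
#' near-rectangle. The union is rasterized, reduced to its largest
#' 4-connected component, and fitted to the 200x100 canvas without touching
#' the border. Deterministic given `(params$seed, case_index)`.
#'
#' @param params a [synth_params()] object.
#' @param case_index non-negative integer selecting the case.
#' @return a [binary_silhouette()] with session `"AM"`.
#' @export
generate_shape <- function(params, case_index = 0L) {
  stopifnot(inherits(params, "synth_params"))
  seed <- derive_seed(params$seed, case_index, stream = 0L)
  withr::with_seed(seed, {
    simple <- stats::runif(1) < params$simple_shape_frac
    if (simple) {
      mask <- render_simple_rectangle()
    } else {
      mask <- render_scalloped_lobes(params)
    }
  })
  lab <- label_components(mask)
  if (max(lab) == 0L) stop("degenerate parameters: empty shape")
  if (max(lab) > 1L) {
    areas <- tabulate(lab[lab > 0L])
    mask <- lab == which.max(areas)
  }
  binary_silhouette(ifelse(mask, 0L, 1L),
                    case_id = sprintf("case_%03d", case_index), session = "AM")
}

render_scalloped_lobes <- function(params) {
  nl <- params$n_lobes
  phis <- seq(0, 2 * pi, length.out = 257L)[-257L]
  # lobe centres along a gently arched horizontal axis, spaced so that
  # neighbouring lobes always overlap (spacing < sum of min radii)
  r0 <- stats::runif(nl, 0.55, 1.0)
  squash <- stats::runif(nl, 0.55, 0.95)
  freq <- sample(4:9, nl, replace = TRUE)
  phase <- stats::runif(nl, 0, 2 * pi)
  amp <- params$scallop_amp * stats::runif(nl, 0.7, 1.3)
  cx <- numeric(nl)
  if (nl > 1L) {
    for (i in 2:nl) {
      cx[i] <- cx[i - 1L] + stats::runif(1, 0.7, 0.95) *
        (r0[i - 1L] + r0[i]) * 0.5
    }
  }
  cx <- cx - mean(cx)
  cy <- stats::runif(nl, -0.15, 0.15)
  scale_lr <- ifelse(cx < 0, params$asymmetry, 1)
  xs <- NULL; ys <- NULL; polys <- vector("list", nl)
  for (i in seq_len(nl)) {
    r <- r0[i] * (1 + amp[i] * sin(freq[i] * phis + phase[i])) * scale_lr[i]
    x <- cx[i] + r * cos(phis)
    y <- cy[i] + squash[i] * r * sin(phis)
    polys[[i]] <- list(x = x, y = y)
    xs <- c(xs, x); ys <- c(ys, y)
  }
  fitted <- fit_to_canvas(xs, ys)
  mask <- matrix(FALSE, 100L, 200L)
  off <- 0L
  for (i in seq_len(nl)) {
    n <- length(polys[[i]]$x)
    px <- fitted$x[(off + 1L):(off + n)]
    py <- fitted$y[(off + 1L):(off + n)]
    off <- off + n
    mask <- mask | rasterize_polygon(px, py, 100L, 200L)
  }
  mask
}

render_simple_rectangle <- function() {
  w <- stats::runif(1, 110, 170)
  h <- stats::runif(1, 40, 70)
  x0 <- (200 - w) / 2 + stats::runif(1, -5, 5)
  y0 <- (100 - h) / 2 + stats::runif(1, -3, 3)
  mask <- matrix(FALSE, 100L, 200L)
  cols <- max(1L, ceiling(x0)):min(200L, floor(x0 + w))
  rows <- max(1L, ceiling(y0)):min(100L, floor(y0 + h))
  mask[rows, cols] <- TRUE
  # clip the four corner pixels for a slightly rounded outline
  r1 <- rows[1L]; r2 <- rows[length(rows)]
  c1 <- cols[1L]; c2 <- cols[length(cols)]
  mask[c(r1, r2), c(c1, c2)] <- FALSE
  mask
}

#' Perturb a silhouette into its paired postmortem rendering
#'
#' Applies, in order: rotation about the foreground centroid drawn uniformly
#' from `[-perturb_rot_deg, +perturb_rot_deg]`, a per-axis translation drawn
#' uniformly from `[-perturb_shift_px, +perturb_shift_px]` (sub-pixel,
#' resampled nearest-neighbour), and a morphological erosion or dilation with
#' integer radius drawn uniformly from `{0, ..., perturb_morph_px}`. If the
#' perturbed foreground touches the canvas border or vanishes, the draw is
#' retried (up to 10 times) before erroring. Deterministic given
#' `(params$seed, pair_seed)`.
#'
#' @param img a [binary_silhouette()].
#' @param params a [synth_params()] object.
#' @param pair_seed integer stream selector for the perturbation draws.
#' @return a [binary_silhouette()] with session `"PM"`.
#' @export
perturb_shape <- function(img, params, pair_seed = 0L) {
  stopifnot(inherits(params, "synth_params"))
  validate_silhouette(img)
  mask <- sil_mask(img)
  seed <- derive_seed(params$seed, pair_seed, stream = 1L)
  out <- NULL
  withr::with_seed(seed, {
    for (attempt in 1:10) {
      ang <- stats::runif(1, -params$perturb_rot_deg, params$perturb_rot_deg)
      dx <- stats::runif(1, -params$perturb_shift_px, params$perturb_shift_px)
      dy <- stats::runif(1, -params$perturb_shift_px, params$perturb_shift_px)
      radius <- sample.int(params$perturb_morph_px + 1L, 1L) - 1L
      grow <- stats::runif(1) < 0.5
      cand <- transform_mask(mask, ang, dx, dy)
      if (radius > 0L) {
        cand <- if (grow) dilate_mask(cand, radius) else erode_mask(cand, radius)
      }
      ok <- any(cand) && !any(cand[1L, ]) && !any(cand[100L, ]) &&
        !any(cand[, 1L]) && !any(cand[, 200L])
      if (ok) { out <- cand; break }
    }
  })
  if (is.null(out)) stop("perturbation repeatedly pushed the foreground off-canvas")
  binary_silhouette(ifelse(out, 0L, 1L),
                    case_id = attr(img, "case_id"), session = "PM")
}

# Rigid transform of a logical mask: rotate by `ang` degrees about the
# foreground centroid, then translate by (dx, dy); nearest-neighbour
# resampling via inverse mapping, outside pixels background.
transform_mask <- function(mask, ang, dx, dy) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  cy <- mean((idx - 1L) %% nr + 1L)
  cx <- mean((idx - 1L) %/% nr + 1L)
  th <- ang * pi / 180
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr), nr, nc)
  # inverse map: undo translation, then rotate by -theta about the centroid
  xr <- X - dx - cx; yr <- Y - dy - cy
  xs <- round(cos(th) * xr + sin(th) * yr + cx)
  ys <- round(-sin(th) * xr + cos(th) * yr + cy)
  valid <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
  out <- matrix(FALSE, nr, nc)
  out[valid] <- mask[cbind(ys[valid], xs[valid])]
  out
}

#' Covariate proportions for synthetic cohorts
#'
#' Defaults follow the study design the generator emulates: 135/180 males,
#' 125/180 scan intervals under 30 days, 81/180 ages under 60 years. Exact
#' counts are assigned (`round(n * frac)`) and then shuffled by the cohort
#' seed, so an n = 180 cohort has exactly 135 male rows.
#'
#' @param male_frac,interval_lt30_frac,age_lt60_frac subgroup proportions.
#' @return a `cohort_covariates` list.
#' @export
cohort_covariates <- function(male_frac = 135 / 180,
                              interval_lt30_frac = 125 / 180,
                              age_lt60_frac = 81 / 180) {
  structure(list(male_frac = male_frac,
                 interval_lt30_frac = interval_lt30_frac,
                 age_lt60_frac = age_lt60_frac),
            class = "cohort_covariates")
}

#' Generate a synthetic AM/PM cohort
#'
#' For each case produces an antemortem silhouette and its paired postmortem
#' perturbation, plus a manifest of case covariates (sex, age in years, AM-PM
#' scan interval in days) with the stated subgroup proportions. The whole
#' cohort is a pure function of `(params, n_cases, covariates)`.
#'
#' @param n_cases number of cases (>= 2).
#' @param params a [synth_params()] object.
#' @param covariates a [cohort_covariates()] specification.
#' @param dir optional output directory; when given, silhouettes are written
#'   as PNG and the manifest as `manifest.csv`, and `am_path`/`pm_path`
#'   columns point at the files.
#' @return a `sinus_cohort` list with elements `manifest` (data frame with
#'   columns case_id, am_path, pm_path, sex, age_years, interval_days),
#'   `am` and `pm` (lists of silhouettes), and `params`.
#' @export
generate_cohort <- function(n_cases, params = synth_params(),
                            covariates = cohort_covariates(), dir = NULL) {
  if (n_cases < 2L) stop("n_cases must be >= 2")
  n <- as.integer(n_cases)
  am <- vector("list", n); pm <- vector("list", n)
  for (i in seq_len(n)) {
    am[[i]] <- generate_shape(params, case_index = i - 1L)
    pm[[i]] <- perturb_shape(am[[i]], params, pair_seed = i - 1L)
  }
  n_male <- as.integer(round(n * covariates$male_frac))
  n_short <- as.integer(round(n * covariates$interval_lt30_frac))
  n_young <- as.integer(round(n * covariates$age_lt60_frac))
  cov_seed <- derive_seed(params$seed, n, stream = 2L)
  manifest <- withr::with_seed(cov_seed, {
    sex <- sample(c(rep("M", n_male), rep("F", n - n_male)))
    young <- sample(c(rep(TRUE, n_young), rep(FALSE, n - n_young)))
    age <- ifelse(young,
                  round(stats::runif(n, 19, 59.49)),
                  round(stats::runif(n, 59.51, 98)))
    short <- sample(c(rep(TRUE, n_short), rep(FALSE, n - n_short)))
    interval <- ifelse(short,
                       round(stats::runif(n, 3, 29.49)),
                       pmin(1920, 30 + round(stats::rexp(n, 1 / 230))))
    data.frame(case_id = sprintf("case_%03d", seq_len(n) - 1L),
               am_path = NA_character_, pm_path = NA_character_,
               sex = sex, age_years = as.integer(age),
               interval_days = as.integer(interval),
               stringsAsFactors = FALSE)
  })
  cohort <- structure(list(manifest = manifest, am = am, pm = pm,
                           params = params),
                      class = "sinus_cohort")
  if (!is.null(dir)) cohort <- write_cohort(cohort, dir)
  cohort
}

#' Write a cohort's images and manifest to disk
#'
#' @param cohort a `sinus_cohort`.
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"pgm"`.
#' @return the cohort with manifest paths filled in.
#' @export
write_cohort <- function(cohort, dir, format = "png") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    ap <- file.path(dir, sprintf("%s_AM.%s", man$case_id[i], format))
    pp <- file.path(dir, sprintf("%s_PM.%s", man$case_id[i], format))
    write_silhouette(cohort$am[[i]], ap)
    write_silhouette(cohort$pm[[i]], pp)
    man$am_path[i] <- ap; man$pm_path[i] <- pp
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  cohort$manifest <- man
  cohort
}

#' @export
print.sinus_cohort <- function(x, ...) {
  cat(sprintf("sinus_cohort: %d cases (%d male, %d female), seed %d\n",
              nrow(x$manifest), sum(x$manifest$sex == "M"),
              sum(x$manifest$sex == "F"), x$params$seed))
  invisible(x)
}
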