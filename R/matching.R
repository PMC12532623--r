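# Brute-force Hamming matching and the mean-distance similarity score: for
# every descriptor of the antemortem image the nearest postmortem descriptor
# is found by exhaustive search, and the similarity score is the arithmetic
# mean of the matched Hamming distances. Lower is more similar; the score of
# an image with itself is 0.

#' Hamming distance between two binary descriptors
#'
#' @param d1,d2 raw vectors of equal length (same method).
#' @param nbits number of meaningful bits (trailing padding bits are zero on
#'   both sides, so they never contribute); defaults to `8 * length(d1)`.
#' @return integer count of differing bits.
#' @export
hamming <- function(d1, d2, nbits = 8L * length(d1)) {
  if (!is.raw(d1) || !is.raw(d2)) stop("descriptors must be raw vectors")
  if (length(d1) != length(d2)) stop("descriptor lengths differ")
  sum(as.integer(rawToBits(xor_raw(d1, d2))))
}

xor_raw <- function(a, b) {
  packBits(xor(rawToBits(a), rawToBits(b)))
}

#' Brute-force descriptor matching
#'
#' Every query descriptor is paired with the target descriptor of minimal
#' Hamming distance (ties resolved to the lowest target index). All query
#' descriptors are matched; there is no ratio test and no cross-checking,
#' because the similarity score is defined over all matches.
#'
#' @param query,target `sinus_features` objects (same method), or raw
#'   descriptor matrices (one descriptor per column).
#' @return a `match_set` data frame with columns `query`, `target`,
#'   `distance`, plus attributes `method` and `nbits`.
#' @export
brute_force_match <- function(query, target) {
  qm <- as_descriptor_matrix(query); tm <- as_descriptor_matrix(target)
  if (!is.null(attr(qm, "method")) && !is.null(attr(tm, "method")) &&
      !identical(attr(qm, "method"), attr(tm, "method")))
    stop("cannot match descriptors of different methods")
  if (ncol(qm) == 0L || ncol(tm) == 0L)
    stop_insufficient_features(attr(qm, "method") %||% "unknown", "empty descriptor set")
  res <- bf_match_cpp(qm, tm)
  structure(data.frame(query = seq_len(ncol(qm)), target = res$target,
                       distance = res$distance),
            method = attr(qm, "method"), nbits = attr(qm, "nbits"),
            class = c("match_set", "data.frame"))
}

as_descriptor_matrix <- function(x) {
  if (inherits(x, "sinus_features")) {
    structure(x$descriptors, method = x$method, nbits = x$nbits)
  } else if (is.raw(x) && is.matrix(x)) {
    x
  } else {
    stop("expected sinus_features or a raw descriptor matrix")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Similarity score between an AM and a PM image
#'
#' Extracts features from both images with the chosen method, matches the
#' antemortem descriptors against the postmortem ones by brute force
#' (query = AM), and returns the mean matched Hamming distance. 0 means the
#' images are identical in feature space; lower is more similar. If either
#' image yields no usable keypoints the error condition
#' `sinusid_insufficient_features` is signalled (cohort code records it as
#' missing, never as 0).
#'
#' @param image_am,image_pm silhouettes or grayscale matrices.
#' @param method `"akaze"` or `"orb"`.
#' @param params method parameter object; defaults per method.
#' @param symmetric also match PM against AM and average the two directions
#'   (off by default; the score is defined as AM to PM).
#' @return a `sinus_similarity` list: `value`, `n_matches`, `method`,
#'   `direction`.
#' @export
similarity_score <- function(image_am, image_pm, method = c("akaze", "orb"),
                             params = NULL, symmetric = FALSE) {
  method <- match.arg(method)
  fa <- extract_features(image_am, method, params)
  fp <- extract_features(image_pm, method, params)
  similarity_from_features(fa, fp, symmetric = symmetric)
}

#' Similarity score from precomputed features
#'
#' Same statistic as [similarity_score()] but starting from already-extracted
#' feature sets; used by cohort scoring to avoid re-extracting images.
#'
#' @param features_am,features_pm `sinus_features` objects (same method).
#' @param symmetric average both matching directions.
#' @return a `sinus_similarity` object.
#' @export
similarity_from_features <- function(features_am, features_pm, symmetric = FALSE) {
  m <- brute_force_match(features_am, features_pm)
  value <- mean(m$distance)
  n <- nrow(m)
  if (symmetric) {
    m2 <- brute_force_match(features_pm, features_am)
    value <- (value + mean(m2$distance)) / 2
    n <- n + nrow(m2)
  }
  structure(list(value = value, n_matches = n,
                 method = attr(m, "method"),
                 direction = if (symmetric) "symmetric" else "AM->PM"),
            class = "sinus_similarity")
}

extract_features <- function(image, method, params = NULL) {
  switch(method,
         akaze = akaze_extract(image, params %||% akaze_params()),
         orb = orb_extract(image, params %||% orb_params()),
         stop("unknown method: ", method))
}

#' Dump keypoints and descriptors as CSV
#'
#' One row per keypoint with columns x, y, octave, angle_rad, response and
#' the descriptor bits hex-encoded.
#'
#' @param features a `sinus_features` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "sinus_features"))
  kp <- features$keypoints
  hex <- apply(features$descriptors, 2L, function(d) paste(format(d), collapse = ""))
  utils::write.csv(data.frame(x = kp$x, y = kp$y, octave = kp$octave,
                              angle_rad = kp$angle, response = kp$response,
                              descriptor_hex = hex),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.sinus_similarity <- function(x, ...) {
  cat(sprintf("similarity (%s, %s): %.3f bits over %d matches\n",
              toupper(x$method), x$direction, x$value, x$n_matches))
  invisible(x)
}
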