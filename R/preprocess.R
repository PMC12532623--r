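# From a single axial CT slice in Hounsfield units to the normalized 200x100
# silhouette: threshold at 200 HU, isolate the enclosed air cavity inside a
# region of interest, and fit it to the canonical canvas.
#
# ROI convention (used everywhere): 0-based, half-open pixel bounds
# [x0, x1) x [y0, y1) with the origin at the top-left of the slice.

#' Threshold a Hounsfield-unit slice into a bone map
#'
#' Pixels at or above the threshold (bone) become white (1); pixels below it
#' (air, soft tissue) become black (0). The default of 200 HU separates bone
#' from the air-filled sinus cavity.
#'
#' @param slice integer/numeric matrix of Hounsfield values (>= 16x16).
#' @param threshold_hu threshold in HU; default 200.
#' @return integer 0/1 matrix of the same dimensions.
#' @export
threshold_hu <- function(slice, threshold_hu = 200L) {
  if (!is.matrix(slice) || length(slice) == 0L) stop("slice must be a non-empty matrix")
  if (nrow(slice) < 16L || ncol(slice) < 16L) stop("slice must be at least 16x16")
  out <- matrix(0L, nrow(slice), ncol(slice))
  out[slice >= threshold_hu] <- 1L
  out
}

#' Region of interest
#'
#' @param x0,y0,x1,y1 0-based half-open pixel bounds; `x` runs along columns,
#'   `y` along rows, origin top-left.
#' @return an `roi` object.
#' @export
roi <- function(x0, y0, x1, y1) {
  r <- list(x0 = as.integer(x0), y0 = as.integer(y0),
            x1 = as.integer(x1), y1 = as.integer(y1))
  if (r$x0 >= r$x1 || r$y0 >= r$y1) stop("ROI must satisfy x0 < x1 and y0 < y1")
  if (r$x0 < 0L || r$y0 < 0L) stop("ROI bounds must be non-negative")
  class(r) <- "roi"
  r
}

#' Extract the sinus cavity from a thresholded bone map
#'
#' Within the ROI, the sinus is the largest 4-connected black (sub-threshold)
#' component that is fully enclosed by bone, i.e. does not touch the ROI
#' border. That component is kept black; everything else in the ROI becomes
#' white. Replaces the manual editing step with an explicit, testable rule.
#'
#' @param bone_map 0/1 matrix from [threshold_hu()].
#' @param region an [roi()] enclosing the sinus and its bony margin.
#' @return 0/1 matrix of the ROI's dimensions (sinus black on white).
#' @export
extract_sinus_silhouette <- function(bone_map, region) {
  stopifnot(inherits(region, "roi"))
  if (region$x1 > ncol(bone_map) || region$y1 > nrow(bone_map))
    stop("ROI exceeds slice bounds")
  sub <- bone_map[(region$y0 + 1L):region$y1, (region$x0 + 1L):region$x1,
                  drop = FALSE]
  lab <- label_components(sub == 0L)
  k <- max(lab)
  if (k == 0L) stop("no sinus found: no sub-threshold pixels inside ROI")
  border_labels <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  keep <- setdiff(seq_len(k), border_labels)
  if (length(keep) == 0L)
    stop("no sinus found: every dark component touches the ROI border")
  areas <- tabulate(lab, nbins = k)[keep]
  best <- keep[which.max(areas)]
  out <- matrix(1L, nrow(sub), ncol(sub))
  out[lab == best] <- 0L
  out
}

#' Normalize a silhouette onto the canonical 200x100 canvas
#'
#' Crops to the foreground (black) bounding box plus a fixed 4-pixel white
#' margin, rescales preserving aspect ratio to fit 200x100, centres the
#' result on a white canvas, and re-binarizes at 0.5 after bilinear
#' interpolation.
#'
#' @param silhouette 0/1 matrix with at least one black pixel.
#' @param case_id,session metadata for the returned [binary_silhouette()].
#' @return a [binary_silhouette()].
#' @export
normalize_canvas <- function(silhouette, case_id = NA_character_,
                             session = NA_character_) {
  fg <- which(silhouette == 0L, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("empty foreground: nothing to normalize")
  margin <- 4L
  rmin <- min(fg[, 1L]); rmax <- max(fg[, 1L])
  cmin <- min(fg[, 2L]); cmax <- max(fg[, 2L])
  # white-padded crop: foreground bounding box plus a full 4-pixel margin on
  # every side, even where the box sits at the input edge
  crop <- matrix(1, rmax - rmin + 1L + 2L * margin, cmax - cmin + 1L + 2L * margin)
  crop[margin + seq_len(rmax - rmin + 1L), margin + seq_len(cmax - cmin + 1L)] <-
    silhouette[rmin:rmax, cmin:cmax, drop = FALSE]
  # the foreground is scaled to fit inside the margin-reserved area, so the
  # output always keeps the full 4-pixel border and a second pass is the
  # identity up to re-binarization
  s <- min((200 - 2 * margin) / (ncol(crop) - 2 * margin),
           (100 - 2 * margin) / (nrow(crop) - 2 * margin))
  nh <- max(1L, round(nrow(crop) * s)); nw <- max(1L, round(ncol(crop) * s))
  nh <- min(nh, 100L); nw <- min(nw, 200L)
  scaled <- resize_bilinear(crop, nh, nw)
  canvas <- matrix(1L, 100L, 200L)
  ro <- floor((100L - nh) / 2L); co <- floor((200L - nw) / 2L)
  canvas[(ro + 1L):(ro + nh), (co + 1L):(co + nw)] <-
    ifelse(scaled >= 0.5, 1L, 0L)
  binary_silhouette(canvas, case_id = case_id, session = session)
}

#' Read a Hounsfield-unit raster
#'
#' Two dialects: a headerless CSV of integer HU values, or a 16-bit grayscale
#' PNG storing `HU + 1024` (so air at -1000 HU is stored as 24).
#'
#' @param path file ending in `.csv` or `.png`.
#' @return integer matrix of Hounsfield values.
#' @export
read_hu_slice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  } else if (ext == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    matrix(as.integer(round(v * 65535)) - 1024L, nrow(v), ncol(v))
  } else {
    stop("unsupported HU raster format: .", ext)
  }
}

#' Write a Hounsfield-unit raster as CSV
#'
#' @param slice integer matrix of HU values.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_hu_csv <- function(slice, path) {
  utils::write.table(slice, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a Hounsfield-unit raster as 16-bit grayscale PNG
#'
#' Stores `HU + 1024` as 16-bit samples (air at -1000 HU becomes 24), the
#' dialect [read_hu_slice()] expects. Uses a minimal self-contained encoder
#' (uncompressed deflate blocks) because 16-bit PNG output is not otherwise
#' available here; any standards-compliant reader, including
#' [png::readPNG()], decodes it.
#'
#' @param slice integer matrix of HU values (>= -1024, <= 64511).
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_hu_png16 <- function(slice, path) {
  v <- slice + 1024L
  if (any(v < 0L) || any(v > 65535L)) stop("HU values out of 16-bit range")
  nr <- nrow(v); nc <- ncol(v)
  rows <- lapply(seq_len(nr), function(y) {
    s <- as.integer(v[y, ])
    c(as.raw(0L), as.raw(as.vector(rbind(s %/% 256L, s %% 256L))))
  })
  data <- unlist(rows)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)), con)
  ihdr <- c(int_be(nc), int_be(nr), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  write_png_chunk(con, "IHDR", ihdr)
  write_png_chunk(con, "IDAT", zlib_stored(data))
  write_png_chunk(con, "IEND", raw(0))
  invisible(path)
}

int_be <- function(x, n = 4L) {
  x <- as.double(x)
  if (x < 0) x <- x + 2^32
  as.raw(rev((x %/% 256^(seq_len(n) - 1)) %% 256))
}

write_png_chunk <- function(con, type, data) {
  tb <- charToRaw(type)
  writeBin(int_be(length(data)), con)
  writeBin(c(tb, data), con)
  writeBin(int_be(crc32(c(tb, data))), con)
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256L)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) bitwXor(-306674912L, bitwShiftR(c, 1L))
          else bitwShiftR(c, 1L)
        }
        t[n + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

adler32 <- function(bytes) {
  a <- 1; s <- 0
  b <- as.integer(bytes)
  # process in chunks so the partial sums stay well inside double precision
  for (start in seq(1L, length(b), by = 4096L)) {
    chunk <- as.double(b[start:min(start + 4095L, length(b))])
    cs <- cumsum(chunk)
    s <- (s + length(chunk) * a + sum(cs)) %% 65521
    a <- (a + cs[length(cs)]) %% 65521
  }
  s * 65536 + a
}

zlib_stored <- function(data) {
  n <- length(data)
  out <- list(as.raw(c(0x78, 0x01)))
  starts <- seq(1L, max(n, 1L), by = 65535L)
  for (i in seq_along(starts)) {
    s <- starts[i]
    e <- min(s + 65534L, n)
    len <- e - s + 1L
    final <- if (i == length(starts)) 0x01 else 0x00
    out[[length(out) + 1L]] <- c(as.raw(final),
                                 as.raw(c(len %% 256L, len %/% 256L)),
                                 as.raw(c(255L - len %% 256L, 255L - len %/% 256L)),
                                 data[s:e])
  }
  out[[length(out) + 1L]] <- int_be(adler32(data))
  unlist(out)
}
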