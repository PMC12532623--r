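#' Binary sinus silhouette
#'
#' The canonical container consumed by every comparison stage: a 200 wide by
#' 100 high integer matrix with value 0 where the sinus cavity is (black) and
#' 1 for background (white). Origin is the top-left corner, x runs rightward
#' along columns, y downward along rows.
#'
#' @param pixels integer matrix of 0/1 values, 100 rows by 200 columns.
#' @param case_id character case identifier.
#' @param session `"AM"` (antemortem) or `"PM"` (postmortem).
#' @return an object of class `binary_silhouette`.
#' @export
binary_silhouette <- function(pixels, case_id = NA_character_, session = NA_character_) {
  pixels <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  obj <- structure(pixels,
                   case_id = as.character(case_id),
                   session = as.character(session),
                   class = c("binary_silhouette", "matrix", "array"))
  validate_silhouette(obj)
  obj
}

#' Validate a binary silhouette
#'
#' Checks the container invariants: exactly 200x100 pixels, values restricted
#' to {0, 1}, and both a black (sinus) and a white (background) pixel present.
#'
#' @param x object to check.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_silhouette <- function(x) {
  if (!is.matrix(x)) stop("silhouette must be a matrix")
  if (nrow(x) != 100L || ncol(x) != 200L)
    stop("silhouette must be 200 (wide) x 100 (high) pixels, got ",
         ncol(x), " x ", nrow(x))
  ux <- unique(as.vector(x))
  if (!all(ux %in% c(0L, 1L))) stop("silhouette pixels must be 0 or 1")
  if (!any(x == 0L) || !any(x == 1L))
    stop("silhouette must contain at least one sinus (0) and one background (1) pixel")
  invisible(x)
}

#' @export
print.binary_silhouette <- function(x, ...) {
  cat(sprintf("binary_silhouette %dx%d  case_id=%s  session=%s  foreground=%d px\n",
              ncol(x), nrow(x), attr(x, "case_id"), attr(x, "session"),
              sum(x == 0L)))
  invisible(x)
}

# foreground (sinus) mask: TRUE where black
sil_mask <- function(x) x == 0L

# silhouette as grayscale in [0,1] for feature extraction (sinus = 0)
sil_gray <- function(x) {
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  m
}

#' Write a silhouette image to disk
#'
#' 8-bit grayscale output with the sinus at intensity 0 and background 255.
#' Format is chosen from the file extension: `.png` (via the png package) or
#' `.pgm` (plain-text P2, useful where a text fixture is needed).
#'
#' @param x a `binary_silhouette` (or any 0/1 matrix).
#' @param path output file path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_silhouette <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  if (ext == "png") {
    png::writePNG(m, target = path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
    apply_rows <- apply(m * 255, 1, paste, collapse = " ")
    writeLines(apply_rows, con)
  } else {
    stop("unsupported silhouette format: .", ext)
  }
  invisible(path)
}

#' Read a silhouette image from disk
#'
#' @param path `.png` or `.pgm` file written by [write_silhouette()].
#' @param case_id,session metadata attached to the returned object.
#' @return a `binary_silhouette`.
#' @export
read_silhouette <- function(path, case_id = NA_character_, session = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
  } else if (ext == "pgm") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    tok <- scan(text = paste(lines[-1L], collapse = " "), quiet = TRUE)
    nc <- tok[1L]; nr <- tok[2L]; maxv <- tok[3L]
    m <- matrix(tok[-(1:3)], nrow = nr, ncol = nc, byrow = TRUE) / maxv
  } else {
    stop("unsupported silhouette format: .", ext)
  }
  binary_silhouette(ifelse(m >= 0.5, 1L, 0L), case_id = case_id, session = session)
}
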