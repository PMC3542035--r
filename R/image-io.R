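#' @useDynLib thyrotex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rgamma runif sd qnorm pnorm setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

round_half_up <- function(x) floor(x + 0.5)

#' Validate a grayscale image matrix
#'
#' Images are plain integer matrices with values in 0..255; rows index the
#' image row coordinate m, columns the column coordinate n.
#'
#' @param img object to check.
#' @param what name used in error messages.
#' @return the image, invisibly, as an integer matrix.
#' @keywords internal
as_gray_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(what, " must have positive extent", call. = FALSE)
  if (anyNA(img)) stop(what, " contains missing pixels", call. = FALSE)
  if (any(img < 0) || any(img > 255))
    stop(what, " has pixels outside [0, 255]", call. = FALSE)
  if (any(img != floor(img)))
    stop(what, " has non-integer gray levels", call. = FALSE)
  storage.mode(img) <- "integer"
  img
}

#' Load a grayscale image
#'
#' Reads an 8-bit single-channel image from PNG, PGM (ASCII `P2` or binary
#' `P5`) or headerless CSV. RGB PNG input is converted to gray by the Rec.
#' 601 luma weighting (0.299 R + 0.587 G + 0.114 B) and quantized. PGM files
#' with `maxval` other than 255 are rescaled to 0..255 by min-max. DICOM is
#' not supported in this build (no reader is available offline); such files
#' are rejected with an explicit error.
#'
#' @param path path to a `.png`, `.pgm` or `.csv` file.
#' @return an integer matrix of gray levels in 0..255.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom"))
    stop("DICOM input is not supported in this build; convert to PNG or PGM")
  img <- switch(ext,
    png = {
      a <- png::readPNG(path)
      g <- if (length(dim(a)) == 3L) {
        # luma conversion; an alpha channel, if present, is ignored
        0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
      } else a
      matrix(round_half_up(g * 255), nrow(g), ncol(g))
    },
    pgm = read_pgm(path),
    csv = as.matrix(read.csv(path, header = FALSE)),
    stop("unsupported image format '", ext, "' (expected png, pgm or csv): ",
         path)
  )
  dimnames(img) <- NULL
  as_gray_image(img, paste0("image '", path, "'"))
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (P2/P5): ", path)
  # header tokens may be interleaved with '#' comments and any whitespace
  tok <- character(0)
  while (length(tok) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || !grepl("[0-9]", ch)) break
        num <- paste0(num, ch)
      }
      tok <- c(tok, num)
    }
  }
  width <- as.integer(tok[1L]); height <- as.integer(tok[2L])
  maxval <- as.integer(tok[3L])
  n <- width * height
  vals <- if (magic == "P5") {
    if (maxval > 255) stop("16-bit PGM not supported: ", path)
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PGM pixel data: ", path)
  img <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  if (maxval != 255L) {
    rng <- range(img)
    img <- if (rng[1L] == rng[2L]) matrix(0L, height, width)
           else round_half_up((img - rng[1L]) / (rng[2L] - rng[1L]) * 255)
  }
  img
}

#' Write a grayscale image as ASCII PGM
#'
#' @param img integer gray-level matrix (0..255).
#' @param path destination `.pgm` path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  img <- as_gray_image(img)
  lines <- c("P2", paste(ncol(img), nrow(img)), "255",
             apply(img, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write a grayscale image as 8-bit PNG
#'
#' @inheritParams write_pgm
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  img <- as_gray_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
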