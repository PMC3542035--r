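#' Rectangular region of interest
#'
#' ROIs are 1-based, inclusive: rows `top .. top + height - 1`, columns
#' `left .. left + width - 1`. The texture features are undefined for regions
#' smaller than 10x10 pixels, so that is the default minimum size; the
#' classification-robustness protocol relaxes it to 5x5.
#'
#' @param top,left 1-based row/column of the top-left corner.
#' @param height,width extent in pixels.
#' @param min_size smallest admissible side length.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(top, left, height, width, min_size = 10L) {
  vals <- c(top = top, left = left, height = height, width = width)
  if (anyNA(vals) || any(vals != floor(vals)))
    stop("roi fields must be integers")
  if (top < 1L || left < 1L) stop("roi corner must be inside the image (>= 1)")
  if (height < min_size || width < min_size)
    stop("ROI cannot be smaller than ", min_size, "x", min_size, " pixels")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi %dx%d at (%d,%d)>\n", x$height, x$width, x$top, x$left))
  invisible(x)
}

roi_inside <- function(roi, extent) {
  roi$top >= 1L && roi$left >= 1L &&
    roi$top + roi$height - 1L <= extent[1L] &&
    roi$left + roi$width - 1L <= extent[2L]
}

#' ROI perturbation
#'
#' Describes the affine ROI perturbations of the robustness protocol: shifts
#' `dm` (rows) and `dn` (columns) bounded by +/-20 px, symmetric size changes
#' `dM`/`dN`, and an in-plane rotation `phi` in degrees (0..180).
#'
#' @param dm,dn row/column shift in pixels, each in -20..20.
#' @param dM,dN height/width change in pixels.
#' @param phi rotation angle in degrees, in 0..180.
#' @return an object of class `affine_perturbation`.
#' @export
affine_perturbation <- function(dm = 0L, dn = 0L, dM = 0L, dN = 0L, phi = 0) {
  vals <- c(dm = dm, dn = dn, dM = dM, dN = dN)
  if (anyNA(vals) || any(vals != floor(vals)))
    stop("shift and size changes must be integers")
  if (abs(dm) > 20L || abs(dn) > 20L)
    stop("ROI shift outside the +/-20 pixel protocol range")
  if (is.na(phi) || phi < 0 || phi > 180)
    stop("rotation angle must lie in [0, 180] degrees")
  structure(list(dm = as.integer(dm), dn = as.integer(dn),
                 dM = as.integer(dM), dN = as.integer(dN), phi = phi),
            class = "affine_perturbation")
}

#' 3x3 median prefilter
#'
#' Each output pixel is the median of its 3x3 neighborhood; image borders are
#' handled by edge replication so the output extent equals the input extent.
#' Applied to the full B-mode frame before ROI extraction.
#'
#' @param image integer gray-level matrix.
#' @return filtered image, same extent.
#' @export
median_filter3 <- function(image) {
  image <- as_gray_image(image)
  median_filter3_cpp(image)
}

#' Extract an ROI sub-image
#'
#' @param image host image matrix.
#' @param roi a [roi_spec()].
#' @param min_size smallest admissible ROI side.
#' @return the cropped sub-image.
#' @export
extract_roi <- function(image, roi, min_size = 10L) {
  image <- as_gray_image(image)
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$height < min_size || roi$width < min_size)
    stop("ROI cannot be smaller than ", min_size, "x", min_size, " pixels")
  if (!roi_inside(roi, dim(image)))
    stop("ROI exceeds the limits of the image")
  image[roi$top:(roi$top + roi$height - 1L),
        roi$left:(roi$left + roi$width - 1L), drop = FALSE]
}

#' Apply a shift/resize perturbation to an ROI
#'
#' Shifts move the corner by (`dm`, `dn`). Size changes are applied
#' symmetrically about the ROI center; when the change is odd the extra pixel
#' goes to the bottom/right. Rotation is not applied here — rotated content is
#' resampled by [rotate_roi_content()].
#'
#' @param roi base [roi_spec()].
#' @param pert an [affine_perturbation()].
#' @param image_extent `c(rows, cols)` of the host image.
#' @param min_size smallest admissible perturbed side.
#' @return the perturbed [roi_spec()].
#' @export
perturb_roi <- function(roi, pert, image_extent, min_size = 10L) {
  stopifnot(inherits(roi, "roi_spec"), inherits(pert, "affine_perturbation"))
  height <- roi$height + pert$dM
  width <- roi$width + pert$dN
  if (height < min_size || width < min_size)
    stop("perturbed ROI smaller than ", min_size, "x", min_size, " pixels")
  top <- roi$top + pert$dm - trunc(pert$dM / 2)
  left <- roi$left + pert$dn - trunc(pert$dN / 2)
  out <- roi_spec(top, left, height, width, min_size = min_size)
  if (!roi_inside(out, image_extent))
    stop("moved or enlarged ROI may not exceed the limits of the image")
  out
}

#' Resample rotated ROI content
#'
#' Rotates the sampling grid by `phi` degrees about the ROI center and
#' resamples the *host* image bilinearly, so the corners of the rotated
#' window are filled with real neighboring tissue rather than synthetic fill.
#' Results are rounded half-up to integer gray levels. `phi = 0` reproduces
#' [extract_roi()] exactly.
#'
#' @param image host image matrix.
#' @param roi a [roi_spec()].
#' @param phi rotation angle in degrees (0..180).
#' @return an ROI-sized image matrix.
#' @export
rotate_roi_content <- function(image, roi, phi) {
  image <- as_gray_image(image)
  stopifnot(inherits(roi, "roi_spec"))
  if (is.na(phi) || phi < 0 || phi > 180)
    stop("rotation angle must lie in [0, 180] degrees")
  if (!roi_inside(roi, dim(image)))
    stop("ROI exceeds the limits of the image")
  if (phi == 0) return(extract_roi(image, roi, min_size = 1L))
  cr <- roi$top + (roi$height - 1) / 2
  cc <- roi$left + (roi$width - 1) / 2
  grid <- expand.grid(r = roi$top:(roi$top + roi$height - 1L),
                      c = roi$left:(roi$left + roi$width - 1L))
  th <- phi * pi / 180
  dr <- grid$r - cr; dc <- grid$c - cc
  src_r <- cr + cos(th) * dr - sin(th) * dc
  src_c <- cc + sin(th) * dr + cos(th) * dc
  eps <- 1e-9  # tolerate float fuzz at exact pixel-centre angles
  if (any(src_r < 1 - eps | src_c < 1 - eps |
          src_r > nrow(image) + eps | src_c > ncol(image) + eps))
    stop("rotated sampling window exceeds the limits of the image")
  vals <- bilinear_sample_cpp(image,
                              pmin(pmax(src_r, 1), nrow(image)) - 1,
                              pmin(pmax(src_c, 1), ncol(image)) - 1)
  matrix(vals, roi$height, roi$width)
}
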