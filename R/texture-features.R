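#' Gray-level histogram of an ROI
#'
#' Counts pixels per gray level i = 0..255. All histogram-based features
#' (w2 in particular) operate on these counts.
#'
#' @param ls ROI image matrix.
#' @return integer vector of length 256; element `i + 1` counts level `i`.
#' @export
compute_histogram <- function(ls) {
  ls <- as_gray_image(ls, "ROI")
  tabulate(as.vector(ls) + 1L, nbins = 256L)
}

#' Smoothness feature w1
#'
#' `w1 = 1 - 1/(1 + sigma^2)` where `sigma` is the population standard
#' deviation of the gray levels normalized to `[0, 1]` (divided by 255). A
#' flat region scores 0; w1 grows toward 1 with texture variance. Typical
#' thyroid speckle gives values of order 1e-3 to 1e-2.
#'
#' @param ls ROI image matrix.
#' @return smoothness in `[0, 1)`.
#' @export
feature_smoothness <- function(ls) {
  ls <- as_gray_image(ls, "ROI")
  x <- as.vector(ls) / 255
  v <- mean((x - mean(x))^2)  # population variance
  1 - 1 / (1 + v)
}

#' Noise-thresholded minimum brightness w2
#'
#' The lowest gray level whose pixel count strictly exceeds 20% of the modal
#' count. Bins at or below the threshold are treated as noise and removed
#' before taking the minimum; the modal bin always survives, so the result is
#' always defined.
#'
#' @param ls ROI image matrix.
#' @param noise_threshold fraction of the modal count below which a gray
#'   level is discarded as noise (default 0.2).
#' @return a gray level in 0..255.
#' @export
feature_min_brightness <- function(ls, noise_threshold = 0.2) {
  counts <- compute_histogram(ls)
  surviving <- which(counts > noise_threshold * max(counts))
  surviving[1L] - 1L  # bins are 1-based, gray levels 0-based
}

#' Quadtree decomposition of an ROI
#'
#' The ROI is padded by edge replication to the smallest enclosing
#' power-of-two square P x P, then recursively split: a block is divided into
#' four equal quadrants iff its gray-level range (max - min) exceeds
#' `split_fraction * 255` (default 10%, i.e. 25.5 levels). Recursion stops at
#' 1x1 blocks.
#'
#' @param ls ROI image matrix (at least 10x10).
#' @param split_fraction homogeneity threshold as a fraction of full range.
#' @return a list with `blocks` (data.frame of 1-based `top`, `left`, `size`)
#'   and `padded_extent` (P).
#' @export
quadtree_decompose <- function(ls, split_fraction = 0.10) {
  ls <- as_gray_image(ls, "ROI")
  if (nrow(ls) < 10L || ncol(ls) < 10L)
    stop("ROI cannot be smaller than 10x10 pixels")
  padded <- pad_pow2_square(ls)
  b <- quadtree_blocks_cpp(padded, split_fraction * 255)
  blocks <- data.frame(top = b[, 1L] + 1L, left = b[, 2L] + 1L,
                       size = b[, 3L])
  list(blocks = blocks, padded_extent = nrow(padded))
}

# edge-replicate to the smallest power-of-two square covering both extents
pad_pow2_square <- function(img) {
  p <- 2L^ceiling(log2(max(dim(img))))
  img[pmin(seq_len(p), nrow(img)), pmin(seq_len(p), ncol(img)), drop = FALSE]
}

#' Percentage of 8x8 quadtree blocks, w3
#'
#' `w3 = 100 * n8 * 64 / P^2` where `n8` is the number of final 8x8 blocks in
#' the decomposition of [quadtree_decompose()] and `P^2` the padded area, so
#' the feature is the fraction of the analyzed square tiled by 8x8 blocks.
#'
#' @inheritParams quadtree_decompose
#' @return a percentage in `[0, 100]`.
#' @export
feature_quadtree8 <- function(ls, split_fraction = 0.10) {
  qt <- quadtree_decompose(ls, split_fraction)
  n8 <- sum(qt$blocks$size == 8L)
  100 * n8 * 64 / qt$padded_extent^2
}

#' Full texture feature vector
#'
#' Computes the triple `(w1, w2, w3)` — smoothness, noise-thresholded
#' minimum brightness, and the 8x8 quadtree-block percentage — for one ROI.
#'
#' @param ls ROI image matrix.
#' @return named numeric vector `c(w1, w2, w3)`.
#' @export
extract_features <- function(ls) {
  c(w1 = feature_smoothness(ls),
    w2 = as.numeric(feature_min_brightness(ls)),
    w3 = feature_quadtree8(ls))
}

# preprocess one view (median filter on the full frame, then crop) and
# return its features
view_features <- function(image, roi, min_size = 10L) {
  extract_features(extract_roi(median_filter3(image), roi,
                               min_size = min_size))
}
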