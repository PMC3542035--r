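#' Synthetic texture parameters
#'
#' Parameters of the synthetic B-mode-like texture generator. The model is a
#' base echogenicity level carrying unit-mean multiplicative speckle, plus
#' randomly placed hyper/hypoechogenic patches emulating tissue
#' heterogeneity, low-pass filtered to mimic the finite beam resolution.
#'
#' @param mean_level base gray level in 0..255.
#' @param speckle_scale dispersion (coefficient of variation) of the
#'   multiplicative speckle field; 0 disables speckle.
#' @param blob_density heterogeneous patches per 1000 px^2; 0 disables them.
#' @param blob_contrast gray-level magnitude of a patch offset.
#' @param smooth_sigma Gaussian smoothing width in pixels; 0 disables it.
#' @return an object of class `texture_params`.
#' @export
texture_params <- function(mean_level, speckle_scale = 0, blob_density = 0,
                           blob_contrast = 0, smooth_sigma = 0) {
  if (is.na(mean_level) || mean_level < 0 || mean_level > 255)
    stop("mean_level must lie in [0, 255]")
  for (f in c(speckle_scale, blob_density, blob_contrast, smooth_sigma))
    if (is.na(f) || f < 0) stop("texture parameters must be non-negative")
  structure(list(mean_level = mean_level, speckle_scale = speckle_scale,
                 blob_density = blob_density, blob_contrast = blob_contrast,
                 smooth_sigma = smooth_sigma),
            class = "texture_params")
}

# run code with a local, restored RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# separable Gaussian convolution with edge replication
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    padded <- m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), ,
                drop = FALSE]
    out <- stats::filter(padded, k, sides = 2)
    out[(r + 1L):(r + nrow(m)), , drop = FALSE]
  }
  t(blur1(t(blur1(img))))
}

#' Generate one synthetic speckle texture
#'
#' Deterministic for fixed `(params, extent, seed)`. Construction: base level
#' `mean_level` multiplied by a unit-mean gamma speckle field with
#' coefficient of variation `speckle_scale` (shape `1/speckle_scale^2`),
#' plus `blob_density` randomly placed disk patches of offset
#' `+/- blob_contrast`, then Gaussian smoothing, then clipping to
#' `[0, 255]` and half-up quantization.
#'
#' @param params a [texture_params()].
#' @param extent `c(rows, cols)` of the output image.
#' @param seed integer RNG seed.
#' @return an integer gray-level matrix.
#' @export
generate_texture <- function(params, extent, seed) {
  stopifnot(inherits(params, "texture_params"))
  extent <- as.integer(extent)
  if (length(extent) != 2L || any(is.na(extent)) || any(extent < 1L))
    stop("extent must be two positive integers")
  M <- extent[1L]; N <- extent[2L]
  with_local_seed(seed, {
    img <- matrix(params$mean_level, M, N)
    if (params$speckle_scale > 0) {
      shape <- 1 / params$speckle_scale^2
      img <- img * matrix(rgamma(M * N, shape = shape, rate = shape), M, N)
    }
    if (params$blob_density > 0) {
      n_blobs <- round_half_up(params$blob_density * M * N / 1000)
      for (b in seq_len(n_blobs)) {
        cr <- runif(1, 1, M); cc <- runif(1, 1, N)
        rad <- runif(1, 2, 6)
        sign <- if (runif(1) < 0.5) -1 else 1
        rows <- max(1L, floor(cr - rad)):min(M, ceiling(cr + rad))
        cols <- max(1L, floor(cc - rad)):min(N, ceiling(cc + rad))
        d2 <- outer((rows - cr)^2, (cols - cc)^2, `+`)
        img[rows, cols] <- img[rows, cols] +
          sign * params$blob_contrast * (d2 <= rad^2)
      }
    }
    img <- gaussian_smooth(img, params$smooth_sigma)
    matrix(as.integer(round_half_up(pmin(pmax(img, 0), 255))), M, N)
  })
}

#' Default texture parameters per diagnostic class
#'
#' Fixed, documented defaults emulating the sonographic contrast between
#' classes: the diseased thyroid is hypoechogenic (lower `mean_level`) and
#' more heterogeneous (higher `blob_density` and speckle dispersion) than
#' healthy parenchyma. Magnitudes are chosen so that ROI features land in
#' realistic ranges (w1 about 0.001-0.01, w2 about 30-60, w3 about 15-35).
#'
#' @param label `"healthy"` or `"patient"`.
#' @return a [texture_params()].
#' @export
default_class_params <- function(label) {
  switch(match.arg(label, c("healthy", "patient")),
    healthy = texture_params(mean_level = 72, speckle_scale = 0.40,
                             blob_density = 0.5, blob_contrast = 22,
                             smooth_sigma = 0.8),
    patient = texture_params(mean_level = 50, speckle_scale = 0.40,
                             blob_density = 2.5, blob_contrast = 30,
                             smooth_sigma = 0.8))
}

view_tags <- c("LO", "RO", "LD", "RD")

#' Synthetic cohort configuration
#'
#' @param n_healthy,n_patient subjects per class (each >= 1).
#' @param image_extent `c(rows, cols)` of each synthetic frame.
#' @param roi_extent `c(rows, cols)` of the centered analysis ROI; the ROI
#'   must keep a margin of at least 20 px to every image edge so the whole
#'   shift/resize protocol stays legal.
#' @param seed master RNG seed; every view seed derives from it.
#' @param class_params named list with `healthy` and `patient`
#'   [texture_params()]; defaults from [default_class_params()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_healthy, n_patient, image_extent = c(128L, 128L),
                          roi_extent = c(50L, 50L), seed = 1L,
                          class_params = list(
                            healthy = default_class_params("healthy"),
                            patient = default_class_params("patient"))) {
  stopifnot(n_healthy >= 1L, n_patient >= 1L)
  image_extent <- as.integer(image_extent)
  roi_extent <- as.integer(roi_extent)
  roi <- roi_spec(top = (image_extent[1L] - roi_extent[1L]) %/% 2L + 1L,
                  left = (image_extent[2L] - roi_extent[2L]) %/% 2L + 1L,
                  height = roi_extent[1L], width = roi_extent[2L])
  margins <- c(roi$top - 1L, roi$left - 1L,
               image_extent[1L] - (roi$top + roi$height - 1L),
               image_extent[2L] - (roi$left + roi$width - 1L))
  if (any(margins < 20L))
    stop("ROI must keep a >= 20 px margin inside the image on every side")
  stopifnot(is.list(class_params),
            inherits(class_params$healthy, "texture_params"),
            inherits(class_params$patient, "texture_params"))
  structure(list(n_healthy = as.integer(n_healthy),
                 n_patient = as.integer(n_patient),
                 image_extent = image_extent, roi_extent = roi_extent,
                 roi = roi, seed = as.integer(seed),
                 class_params = class_params),
            class = "cohort_config")
}

# deterministic per-view seed fan-out, kept inside 32-bit integer range
derive_seed <- function(seed, subject_index, view_index) {
  as.integer((as.double(seed) * 48271 + subject_index * 4099 +
                view_index * 331) %% 2147483647)
}

#' Generate a synthetic multi-view cohort
#'
#' Produces one subject record per subject: a label, and four views (LO, RO,
#' LD, RD — left/right lobe in transverse/longitudinal section), each an
#' independently drawn texture image with the centered analysis ROI. The
#' whole cohort is a pure function of the configuration.
#'
#' @param config a [cohort_config()].
#' @return a list of subject records (class `thyroid_cohort`), each with
#'   `subject_id`, `label` and `views` (named list of `list(image, roi)`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- rep(c("healthy", "patient"),
                c(config$n_healthy, config$n_patient))
  cohort <- lapply(seq_along(labels), function(i) {
    label <- labels[i]
    params <- config$class_params[[label]]
    views <- lapply(seq_along(view_tags), function(v) {
      img <- generate_texture(params, config$image_extent,
                              derive_seed(config$seed, i, v))
      list(image = img, roi = config$roi)
    })
    names(views) <- view_tags
    list(subject_id = sprintf("S%04d", i), label = label, views = views)
  })
  structure(cohort, class = "thyroid_cohort", config = config)
}

#' Feature table for a cohort
#'
#' Runs the preprocessing chain (3x3 median filter on the full frame, ROI
#' crop) and feature extraction for every view of every subject.
#'
#' @param cohort a `thyroid_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @return data.frame with columns `subject_id`, `view`, `label`, `w1`,
#'   `w2`, `w3`.
#' @export
extract_cohort_features <- function(cohort) {
  rows <- lapply(cohort, function(rec) {
    feats <- lapply(rec$views, function(v) view_features(v$image, v$roi))
    data.frame(subject_id = rec$subject_id, view = names(rec$views),
               label = rec$label, do.call(rbind, feats),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Serialize a cohort to disk
#'
#' Writes one 8-bit PNG per view plus `manifest.csv` (subject_id, label,
#' view, image_path, roi_row, roi_col, roi_height, roi_width) and the
#' configuration as `config.json`.
#'
#' @param cohort a `thyroid_cohort`.
#' @param dir destination directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (rec in cohort) {
    for (tag in names(rec$views)) {
      v <- rec$views[[tag]]
      rel <- file.path("images", sprintf("%s_%s.png", rec$subject_id, tag))
      write_gray_png(v$image, file.path(dir, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rec$subject_id, label = rec$label, view = tag,
        image_path = rel, roi_row = v$roi$top, roi_col = v$roi$left,
        roi_height = v$roi$height, roi_width = v$roi$width)
    }
  }
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  config <- attr(cohort, "config")
  if (!is.null(config)) {
    cfg <- list(n_healthy = config$n_healthy, n_patient = config$n_patient,
                image_extent = config$image_extent,
                roi_extent = config$roi_extent, seed = config$seed,
                class_params = lapply(config$class_params, unclass))
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a serialized cohort
#'
#' Reads a directory written by [write_cohort()] (or any directory with a
#' compatible `manifest.csv` pointing at PNG/PGM images).
#'
#' @param dir cohort directory.
#' @return a `thyroid_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  needed <- c("subject_id", "label", "view", "image_path", "roi_row",
              "roi_col", "roi_height", "roi_width")
  if (!all(needed %in% names(manifest)))
    stop("manifest.csv is missing columns: ",
         paste(setdiff(needed, names(manifest)), collapse = ", "))
  cohort <- lapply(split(manifest, manifest$subject_id), function(mf) {
    views <- lapply(seq_len(nrow(mf)), function(k) {
      list(image = load_image(file.path(dir, mf$image_path[k])),
           roi = roi_spec(mf$roi_row[k], mf$roi_col[k],
                          mf$roi_height[k], mf$roi_width[k]))
    })
    names(views) <- mf$view
    list(subject_id = mf$subject_id[1L], label = mf$label[1L], views = views)
  })
  # restore generation order
  cohort <- cohort[unique(manifest$subject_id)]
  names(cohort) <- NULL
  structure(cohort, class = "thyroid_cohort")
}
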