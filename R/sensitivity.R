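#' Perturbation grids for the robustness protocol
#'
#' `shift_grid()` enumerates ROI shifts (`dm`, `dn`) in rows/columns,
#' default -20..20 px; `size_grid()` enumerates size changes (`dM`, `dN`),
#' default -20..20 px relative to the base ROI; `rotation_grid()` enumerates
#' angles, default 0..180 degrees by 1. The zero/identity cell must be part
#' of every grid — it anchors the exact fixed-point checks.
#'
#' @param dm_values,dn_values integer shift offsets, each within -20..20.
#' @return an object of class `shift_grid`, `size_grid` or `rotation_grid`.
#' @export
shift_grid <- function(dm_values = -20:20, dn_values = -20:20) {
  stopifnot(all(abs(dm_values) <= 20), all(abs(dn_values) <= 20),
            0 %in% dm_values, 0 %in% dn_values)
  structure(list(dm_values = as.integer(dm_values),
                 dn_values = as.integer(dn_values)),
            class = c("size_shift_grid", "shift_grid"))
}

#' @rdname shift_grid
#' @param dM_values,dN_values integer size changes.
#' @export
size_grid <- function(dM_values = -20:20, dN_values = -20:20) {
  stopifnot(0 %in% dM_values, 0 %in% dN_values)
  structure(list(dM_values = as.integer(dM_values),
                 dN_values = as.integer(dN_values)),
            class = c("size_shift_grid", "size_grid"))
}

#' @rdname shift_grid
#' @param angles rotation angles in degrees, within 0..180.
#' @export
rotation_grid <- function(angles = 0:180) {
  stopifnot(all(angles >= 0), all(angles <= 180), 0 %in% angles)
  structure(list(angles = angles), class = "rotation_grid")
}

grid_cells <- function(grid) {
  if (inherits(grid, "shift_grid"))
    expand.grid(dm = grid$dm_values, dn = grid$dn_values,
                dM = 0L, dN = 0L, phi = 0)
  else if (inherits(grid, "size_grid"))
    expand.grid(dm = 0L, dn = 0L, dM = grid$dM_values, dN = grid$dN_values,
                phi = 0)
  else if (inherits(grid, "rotation_grid"))
    data.frame(dm = 0L, dn = 0L, dM = 0L, dN = 0L, phi = grid$angles)
  else stop("unknown grid type")
}

# features of one perturbed cell on a pre-filtered host; NULL when the cell
# is illegal for this ROI
cell_features <- function(filtered, base_roi, cell, min_size = 10L) {
  roi <- tryCatch(
    perturb_roi(base_roi,
                affine_perturbation(cell$dm, cell$dn, cell$dM, cell$dN),
                dim(filtered), min_size = min_size),
    error = function(e) NULL)
  if (is.null(roi)) return(NULL)
  ls <- if (cell$phi == 0) extract_roi(filtered, roi, min_size = min_size)
        else tryCatch(rotate_roi_content(filtered, roi, cell$phi),
                      error = function(e) NULL)
  if (is.null(ls)) return(NULL)
  extract_features(ls)
}

#' Feature percentage-error surface under ROI perturbation
#'
#' For every grid cell the ROI is perturbed, the features recomputed on the
#' median-filtered host, and the relative change reported as
#' `100 * (w_perturbed - w_base) / w_base` per feature. Cells whose perturbed
#' ROI violates the image or size constraints are kept in the output but
#' flagged invalid (`valid = FALSE`, value `NA`). When a base feature is 0
#' (possible for w1 and w3 on degenerate textures) the percentage error is
#' undefined and reported as `NaN`, never silently 0.
#'
#' @param image host image (unfiltered; the 3x3 median prefilter is applied
#'   here).
#' @param base_roi the reference [roi_spec()] marked by the expert.
#' @param grid a [shift_grid()], [size_grid()] or [rotation_grid()].
#' @return long-format data.frame with the cell coordinates (`dm`, `dn`,
#'   `dM`, `dN`, `phi`), `feature`, `value` (error %) and `valid`; base
#'   features are attached as attribute `"base"`.
#' @export
feature_error_surface <- function(image, base_roi, grid) {
  filtered <- median_filter3(image)
  base <- extract_features(extract_roi(filtered, base_roi))
  cells <- grid_cells(grid)
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    cell <- cells[k, ]
    feats <- cell_features(filtered, base_roi, cell)
    if (is.null(feats))
      return(data.frame(cell, feature = names(base), value = NA_real_,
                        valid = FALSE, row.names = NULL))
    err <- ifelse(base == 0, NaN, 100 * (feats - base) / base)
    data.frame(cell, feature = names(base), value = as.numeric(err),
               valid = TRUE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  out
}

#' Classification-metric surface under ROI perturbation
#'
#' Trains one discriminant model on the *unperturbed* learning partition,
#' then, for each grid cell, perturbs every test-partition ROI identically,
#' recomputes its features and re-evaluates TPR/SPC/ACC. This frames the
#' perturbation as a measurement error at diagnosis time; `retrain = TRUE`
#' refits the model on equally perturbed training features instead. The
#' zero cell reproduces the unperturbed baseline metrics exactly. Cells
#' illegal for any test subject are masked (`valid = FALSE`).
#'
#' @param cohort a `thyroid_cohort`.
#' @param grid a [shift_grid()] or [size_grid()] ([rotation_grid()] is
#'   accepted but excluded from the default protocol, rotation having a
#'   negligible effect on the classification metrics).
#' @param variant discriminant variant to train.
#' @param seed integer seed for the cohort split.
#' @param retrain refit the model per cell on perturbed training features?
#' @return data.frame with cell coordinates, `TPR`, `SPC`, `ACC` and
#'   `valid`; baseline metrics attached as attribute `"base"`.
#' @export
classification_sensitivity_surface <- function(cohort, grid,
                                               variant = "linear", seed = 1L,
                                               retrain = FALSE) {
  stopifnot(inherits(cohort, "thyroid_cohort"))
  # pre-filter every view once; the per-cell loop only re-crops
  views <- list()
  for (rec in cohort)
    for (tag in names(rec$views)) {
      v <- rec$views[[tag]]
      views[[length(views) + 1L]] <- list(
        subject_id = rec$subject_id, label = rec$label, view = tag,
        filtered = median_filter3(v$image), roi = v$roi)
    }
  base_feats <- do.call(rbind, lapply(views, function(v)
    data.frame(subject_id = v$subject_id, view = v$view, label = v$label,
               t(extract_features(extract_roi(v$filtered, v$roi))))))
  parts <- split_cohort(base_feats, seed)
  model <- fit_discriminant(parts$train, variant)
  base_metrics <- evaluate(model, parts$test)
  is_test <- vapply(views, function(v)
    v$subject_id %in% parts$test$subject_id, logical(1L))
  test_views <- views[is_test]
  train_views <- views[!is_test &
                         vapply(views, function(v)
                           v$subject_id %in% parts$train$subject_id,
                           logical(1L))]
  cells <- grid_cells(grid)
  perturbed_frame <- function(view_list, cell) {
    feats <- lapply(view_list, function(v)
      cell_features(v$filtered, v$roi, cell))
    if (any(vapply(feats, is.null, logical(1L)))) return(NULL)
    do.call(rbind, lapply(seq_along(view_list), function(i)
      data.frame(subject_id = view_list[[i]]$subject_id,
                 view = view_list[[i]]$view,
                 label = view_list[[i]]$label, t(feats[[i]]))))
  }
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    cell <- cells[k, ]
    test_df <- perturbed_frame(test_views, cell)
    cell_model <- if (!retrain) model else {
      train_df <- perturbed_frame(train_views, cell)
      if (is.null(train_df)) NULL else fit_discriminant(train_df, variant)
    }
    if (is.null(test_df) || is.null(cell_model))
      return(data.frame(cell, TPR = NA_real_, SPC = NA_real_,
                        ACC = NA_real_, valid = FALSE, row.names = NULL))
    m <- evaluate(cell_model, test_df)
    data.frame(cell, TPR = m$TPR, SPC = m$SPC, ACC = m$ACC, valid = TRUE,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "base") <- base_metrics
  out
}

#' Per-angle rotation sensitivity of the features
#'
#' Rotates the ROI content about its center through each angle (default 0 to
#' 180 degrees by 1, bilinear interpolation) and reports the percentage error
#' of each feature against the unrotated reference.
#'
#' @param image host image (unfiltered).
#' @param base_roi a [roi_spec()].
#' @param angles rotation angles in degrees.
#' @return long-format data.frame as in [feature_error_surface()].
#' @export
rotation_sensitivity_report <- function(image, base_roi, angles = 0:180) {
  grid <- rotation_grid(angles)
  filtered <- median_filter3(image)
  bad <- angles[vapply(angles, function(a)
    is.null(tryCatch(rotate_roi_content(filtered, base_roi, a),
                     error = function(e) NULL)), logical(1L))]
  if (length(bad) > 0L)
    stop("rotated window exceeds the image at angles: ",
         paste(bad, collapse = ", "))
  feature_error_surface(image, base_roi, grid)
}

#' Write a sensitivity surface as CSV
#'
#' @param surface a data.frame from [feature_error_surface()] or
#'   [classification_sensitivity_surface()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  write.csv(surface, path, row.names = FALSE)
  invisible(path)
}
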