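#' Read a diffusion-weighted series from NIfTI + bval files
#'
#' Reads a 4D NIfTI magnitude volume and an FSL-style whitespace-separated
#' b-value text file. The b-value count must match the 4th dimension. If
#' the b-values are unsorted, volumes are reordered consistently with a
#' warning.
#'
#' @param volume_path Path to a `.nii`/`.nii.gz` 4D volume.
#' @param bval_path Path to a text file of b-values.
#' @return A [dwi_series()].
#' @export
read_dwi <- function(volume_path, bval_path) {
  vol <- as.array(RNifti::readNifti(volume_path))
  if (length(dim(vol)) == 3L) dim(vol) <- c(dim(vol), 1L)
  bvals <- scan(bval_path, quiet = TRUE)
  if (length(bvals) != dim(vol)[4L]) {
    stop("b-value count (", length(bvals), ") does not match the 4th ",
         "volume dimension (", dim(vol)[4L], ")", call. = FALSE)
  }
  if (any(bvals <= 0)) stop("b-values must be positive", call. = FALSE)
  if (is.unsorted(bvals, strictly = TRUE)) {
    warning("b-values are not strictly increasing; reordering volumes",
            call. = FALSE)
    o <- order(bvals)
    bvals <- bvals[o]
    vol <- vol[, , , o, drop = FALSE]
  }
  dwi_series(vol, bvals)
}

#' Write a diffusion-weighted series as NIfTI + bval files
#'
#' @param series A [dwi_series()].
#' @param volume_path,bval_path Output paths.
#' @return Invisibly, `volume_path`.
#' @export
write_dwi <- function(series, volume_path, bval_path) {
  RNifti::writeNifti(series$data, volume_path)
  writeLines(paste(unclass(series$bvalues), collapse = " "), bval_path)
  invisible(volume_path)
}

#' Read a noise-only volume
#'
#' @param path NIfTI path.
#' @return Numeric array.
#' @export
read_noise_volume <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Write fitted parameter maps and a JSON fit report
#'
#' Writes NIfTI maps (`s0`, `d_app` in 1e-3 mm^2/s, `k_app`, integer
#' `status` codes, `rss`) plus `fit_report.json` holding voxel counts by
#' status and the fit configuration.
#'
#' @param maps A `"dki_maps"` object from [fit_dki_volume()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_parameter_maps <- function(maps, dir, prefix = "dki") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    s0 = file.path(dir, paste0(prefix, "_s0.nii.gz")),
    d_app = file.path(dir, paste0(prefix, "_d_app.nii.gz")),
    k_app = file.path(dir, paste0(prefix, "_k_app.nii.gz")),
    status = file.path(dir, paste0(prefix, "_status.nii.gz")),
    rss = file.path(dir, paste0(prefix, "_rss.nii.gz")),
    report = file.path(dir, paste0(prefix, "_fit_report.json"))
  )
  RNifti::writeNifti(maps$s0, paths[["s0"]])
  RNifti::writeNifti(maps$d_app * 1e3, paths[["d_app"]])
  RNifti::writeNifti(maps$k_app, paths[["k_app"]])
  RNifti::writeNifti(maps$status, paths[["status"]])
  RNifti::writeNifti(maps$rss, paths[["rss"]])
  report <- c(as.list(glance(maps)),
              list(status_codes = as.list(dki_status_codes),
                   d_app_units = "1e-3 mm^2/s",
                   config = maps$config[c("lower", "upper", "max_iterations",
                                          "tolerance", "mask_threshold",
                                          "noise")]))
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read/write an RGB histology image (PNG or TIFF)
#'
#' The format is chosen by file extension (`.png` vs `.tif`/`.tiff`).
#'
#' @param path Image path.
#' @return `read_histology_image()`: an `h x w x 3` array in `[0, 1]`.
#' @export
read_histology_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rlang::check_installed("tiff", reason = "to read TIFF images")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_histology_image
#' @param image RGB array in `[0, 1]`.
#' @export
write_histology_image <- function(image, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rlang::check_installed("tiff", reason = "to write TIFF images")
    tiff::writeTIFF(image, path)
  } else {
    png::writePNG(image, path)
  }
  invisible(path)
}

#' Read/write ROI polygons as JSON
#'
#' The JSON format is a list of objects `{"label": str,
#' "vertices": [[x, y], ...]}` in 0-based pixel coordinates.
#'
#' @param path JSON path.
#' @return A named list of vertex matrices.
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  out <- lapply(raw, function(r) {
    v <- r$vertices
    if (is.list(v) && !is.matrix(v)) v <- do.call(rbind, v)
    matrix(as.numeric(v), ncol = 2L)
  })
  names(out) <- vapply(raw, function(r) as.character(r$label), character(1))
  out
}

#' @rdname read_roi_json
#' @param rois Named list of two-column vertex matrices.
#' @export
write_roi_json <- function(rois, path) {
  obj <- lapply(seq_along(rois), function(i) {
    list(label = names(rois)[i],
         vertices = lapply(seq_len(nrow(rois[[i]])),
                           function(j) as.numeric(rois[[i]][j, ])))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write a cohort table CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal; columns exactly
#' `patient_id, roi_id, tissue, gs_group, median_d_app, median_k_app,
#' cellularity, fsm, luminal, area_mm2`.
#'
#' @param path CSV path.
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_cohort_table(tab)
  tab
}

#' @rdname read_cohort_csv
#' @param table Cohort tibble/data frame.
#' @export
write_cohort_csv <- function(table, path) {
  check_cohort_table(table)
  utils::write.csv(table[, cohort_schema], path, row.names = FALSE)
  invisible(path)
}

#' Write a study-analysis results CSV
#'
#' @param analysis Result of [run_study_analyses()].
#' @param path CSV path.
#' @export
write_analysis_csv <- function(analysis, path) {
  utils::write.csv(analysis, path, row.names = FALSE)
  invisible(path)
}
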