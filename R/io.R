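#' Read a diffusion-weighted series from NIfTI + bval/bvec sidecars
#'
#' Expects a 4-D (single repetition) or 5-D NIfTI volume ordered
#' (row, col, slice, channel, repetition) with channel 1 the b0 reference,
#' and FSL-style text sidecars: `bval` one whitespace-separated row of
#' b-values, `bvec` three rows (x, y, z) of direction components for the
#' diffusion-encoded channels. Direction vectors within 1% of unit norm are
#' normalized; larger deviations raise a format error.
#'
#' @param paths list with elements `dwi`, `bval`, `bvec`.
#' @return A [dwi_series()].
#' @export
read_dwi <- function(paths) {
  for (p in c("dwi", "bval", "bvec"))
    if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
      stop("input error: missing file for '", p, "': ",
           if (is.null(paths[[p]])) "<unset>" else paths[[p]], call. = FALSE)
  img <- RNifti::readNifti(paths$dwi)
  arr <- as.array(img)
  if (length(dim(arr)) == 4) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 5)
    stop("format error: expected a 4-D or 5-D volume, found ",
         length(dim(img)), " dimensions", call. = FALSE)
  bval <- scan(paths$bval, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(paths$bvec))
  if (nrow(bvec) != 3)
    stop("format error: bvec must have 3 rows", call. = FALSE)
  nch <- dim(arr)[4]
  if (length(bval) != nch || ncol(bvec) != nch)
    stop("format error: expected ", nch, " bval/bvec entries, found ",
         length(bval), "/", ncol(bvec), call. = FALSE)
  dw <- which(bval > 0)
  if (length(dw) < 6)
    stop("invalid scheme: fewer than 6 diffusion-encoded channels", call. = FALSE)
  if (!identical(dw, 2:nch) || bval[1] != 0)
    stop("format error: channel 1 must be b = 0 and channels 2.. diffusion-encoded",
         call. = FALSE)
  b <- unique(bval[dw])
  if (length(b) != 1)
    stop("format error: a single non-zero b-value is expected", call. = FALSE)
  scheme <- gradient_scheme(t(bvec[, dw, drop = FALSE]), b_value = b)
  pix <- RNifti::pixdim(img)
  dwi_series(arr, scheme, pixel_spacing = pix[1],
             slice_positions = cumsum(c(0, rep(pix[3], dim(arr)[3] - 1))))
}

#' Write a diffusion-weighted series as NIfTI + bval/bvec
#'
#' @param series a [dwi_series()].
#' @param dir output directory (created if needed).
#' @param prefix file name stem.
#' @return Invisibly, the list of written paths (`dwi`, `bval`, `bvec`).
#' @export
write_dwi <- function(series, dir, prefix = "dwi") {
  stopifnot(inherits(series, "dwi_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$intensities)
  img <- RNifti::asNifti(series$intensities)
  dz <- if (length(series$slice_positions) > 1)
    diff(series$slice_positions)[1] else 1
  # trailing singleton dimensions may be dropped by the NIfTI container
  nd <- length(dim(img))
  RNifti::pixdim(img) <- c(series$pixel_spacing, series$pixel_spacing, dz,
                           rep(1, max(nd - 3, 0)))
  dwi_path <- file.path(dir, paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(img, dwi_path)
  bval <- c(0, rep(series$scheme$b_value, nrow(series$scheme$directions)))
  bval_path <- file.path(dir, paste0(prefix, ".bval"))
  writeLines(paste(bval, collapse = " "), bval_path)
  bvec <- cbind(0, t(series$scheme$directions))
  bvec_path <- file.path(dir, paste0(prefix, ".bvec"))
  writeLines(apply(bvec, 1, paste, collapse = " "), bvec_path)
  invisible(list(dwi = dwi_path, bval = bval_path, bvec = bvec_path))
}

#' Read LV geometry from a NIfTI label mask plus JSON metadata
#'
#' The label image uses 1 = LV cavity, 2 = myocardium (anything else is
#' background); the JSON carries `rv_azimuth` (degrees) and optionally
#' `long_axis` (3-vector) and `pixel_spacing`.
#'
#' @param mask_path NIfTI label image path.
#' @param json_path JSON metadata path.
#' @return An [lv_geometry()].
#' @export
read_geometry <- function(mask_path, json_path) {
  for (p in c(mask_path, json_path))
    if (is.null(p) || !file.exists(p))
      stop("input error: missing geometry file: ",
           if (is.null(p)) "<unset>" else p, call. = FALSE)
  lab <- as.array(RNifti::readNifti(mask_path))
  if (length(dim(lab)) == 2) lab <- array(lab, c(dim(lab), 1L))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pix <- RNifti::pixdim(RNifti::readNifti(mask_path))[1]
  lv_geometry(
    myo_mask = lab == 2, cavity_mask = lab == 1,
    rv_azimuth = if (!is.null(meta$rv_azimuth)) meta$rv_azimuth else 180,
    pixel_spacing = if (!is.null(meta$pixel_spacing)) meta$pixel_spacing else pix,
    long_axis = if (!is.null(meta$long_axis)) unlist(meta$long_axis) else c(0, 0, 1)
  )
}

scalar_map_to_nifti <- function(map) {
  v <- map$values
  v[!map$mask] <- NA_real_
  RNifti::asNifti(v)
}

#' Write study outputs (maps, labels, tables, run report) to a directory
#'
#' Persists FA/MD/HA maps and region labels as NIfTI, regional means and the
#' preprocessing reports as CSV, the per-voxel eigensystem (eigenvalues and
#' eigenvectors) as CSV for external glyph rendering, and a machine-readable
#' JSON run report with masking / rejection / repair counts.
#'
#' @param study a `cdti_study` from [run_single_study()].
#' @param dir output directory.
#' @param eigensystem_csv also export the per-voxel eigensystem table.
#' @return Invisibly, the vector of written paths.
#' @export
write_maps <- function(study, dir, eigensystem_csv = FALSE) {
  stopifnot(inherits(study, "cdti_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (m in c("fa", "md", "ha")) {
    p <- file.path(dir, paste0(m, ".nii.gz"))
    RNifti::writeNifti(scalar_map_to_nifti(study[[m]]), p)
    paths <- c(paths, p)
  }
  lab <- study$labels
  for (nm in c("slice", "wall", "layer")) {
    p <- file.path(dir, paste0("labels_", nm, ".nii.gz"))
    arr <- lab[[nm]]
    arr[is.na(arr)] <- 0L
    RNifti::writeNifti(RNifti::asNifti(arr), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "region_means.csv")
  readr::write_csv(study$region_means, p)
  paths <- c(paths, p)
  for (nm in c("rejection", "registration")) {
    if (!is.null(study$report[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(study$report[[nm]], p)
      paths <- c(paths, p)
    }
  }
  if (eigensystem_csv) {
    idx <- which(study$eigen$mask, arr.ind = TRUE)
    lin <- which(study$eigen$mask)
    tbl <- tibble::tibble(row = idx[, 1], col = idx[, 2], slice = idx[, 3])
    for (k in 1:3) tbl[[paste0("lambda", k)]] <- study$eigen$values[, , , k][lin]
    for (k in 1:3) for (c3 in 1:3)
      tbl[[paste0("e", k, c("x", "y", "z")[c3])]] <-
        study$eigen$vectors[, , , c3, k][lin]
    p <- file.path(dir, "eigensystem.csv")
    readr::write_csv(tbl, p)
    paths <- c(paths, p)
  }
  report <- list(
    n_masked_out = study$report$n_masked_out,
    n_repaired = study$report$n_repaired,
    n_rejected = if (!is.null(study$report$rejection))
      sum(!study$report$rejection$accepted) else NA
  )
  p <- file.path(dir, "run_report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
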