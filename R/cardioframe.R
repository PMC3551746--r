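#' Left-ventricular geometry model
#'
#' Per-slice endocardial cavity and myocardial masks, LV centroid, the
#' azimuth of the right ventricle (used to anchor wall segments), the
#' long-axis direction (apex -> base, +z for short-axis stacks) and,
#' optionally, a transmural depth map.
#'
#' @param myo_mask logical array (row, col, slice): myocardium.
#' @param cavity_mask logical array: LV cavity (inside the endocardial
#'   border).
#' @param centroid n_slices x 2 matrix of (row, col) centroids in pixel
#'   coordinates; computed from the masks when omitted.
#' @param rv_azimuth septum direction from the centroid, degrees
#'   counterclockwise from +x (+x = increasing column).
#' @param pixel_spacing mm per pixel in-plane.
#' @param long_axis unit 3-vector, apex to base; default +z.
#' @param depth optional transmural depth map (see [transmural_depth()]).
#' @return An object of class `lv_geometry`.
#' @export
lv_geometry <- function(myo_mask, cavity_mask, centroid = NULL,
                        rv_azimuth = 180, pixel_spacing = 1,
                        long_axis = c(0, 0, 1), depth = NULL) {
  stopifnot(is.logical(myo_mask), is.logical(cavity_mask),
            all(dim(myo_mask) == dim(cavity_mask)))
  ns <- dim(myo_mask)[3]
  for (s in seq_len(ns))
    if (!any(myo_mask[, , s]))
      stop("geometry error: empty myocardial mask in slice ", s, call. = FALSE)
  if (is.null(centroid)) {
    centroid <- t(vapply(seq_len(ns), function(s) {
      idx <- which(myo_mask[, , s] | cavity_mask[, , s], arr.ind = TRUE)
      c(mean(idx[, 1]), mean(idx[, 2]))
    }, numeric(2)))
  }
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  structure(list(myo_mask = myo_mask, cavity_mask = cavity_mask,
                 centroid = centroid, rv_azimuth = rv_azimuth,
                 pixel_spacing = pixel_spacing, long_axis = long_axis,
                 depth = depth),
            class = "lv_geometry")
}

#' Transmural depth map
#'
#' Normalized wall position, 0 at the endocardial border to 1 at the
#' epicardial border, computed from Euclidean distance transforms:
#' `d = de / (de + dp)` where `de` is the distance to the cavity and `dp`
#' the distance to the background outside the epicardium. Pixel-centre
#' distance transforms never reach 0 on the border, so both distances are
#' measured to the mask boundary by subtracting half a pixel
#' (`d = (de - 1/2) / (de + dp - 1)`, clipped to `[0, 1]`), which keeps the
#' estimate unbiased at the few-pixel wall thicknesses of 2.7 mm cardiac
#' acquisitions.
#'
#' @param geometry an [lv_geometry()].
#' @return The geometry with its `depth` array (NA outside the myocardium)
#'   replaced by the distance-transform estimate.
#' @export
transmural_depth <- function(geometry) {
  stopifnot(inherits(geometry, "lv_geometry"))
  dm <- dim(geometry$myo_mask)
  depth <- array(NA_real_, dm)
  for (s in seq_len(dm[3])) {
    myo <- geometry$myo_mask[, , s]
    cav <- geometry$cavity_mask[, , s]
    outside <- !(myo | cav)
    if (!any(myo))
      stop("geometry error: empty myocardium", call. = FALSE)
    de <- EBImage::distmap(matrix(as.numeric(!cav), dm[1], dm[2]))
    dp <- EBImage::distmap(matrix(as.numeric(!outside), dm[1], dm[2]))
    d <- (de - 0.5) / (de + dp - 1)
    d <- pmin(pmax(d, 0), 1)
    dslice <- array(NA_real_, dm[1:2])
    dslice[myo] <- d[myo]
    depth[, , s] <- dslice
  }
  geometry$depth <- depth
  geometry
}

#' Local cardiac coordinate frame at a voxel
#'
#' Right-handed orthonormal frame: radial `r` is the in-plane unit vector
#' from the slice centroid to the voxel, longitudinal `l` is the long-axis
#' direction (apex -> base), and circumferential `c = l x r`, so that zero
#' helix angle is circumferential and positive angles tilt toward the base.
#'
#' @param geometry an [lv_geometry()].
#' @param voxel integer vector (row, col, slice).
#' @return List with unit vectors `circumferential`, `longitudinal`,
#'   `radial`.
#' @export
local_frame <- function(geometry, voxel) {
  stopifnot(inherits(geometry, "lv_geometry"), length(voxel) == 3)
  ctr <- geometry$centroid[voxel[3], ]
  x <- voxel[2] - ctr[2]          # +x with increasing column
  y <- ctr[1] - voxel[1]          # +y with decreasing row
  rr <- sqrt(x^2 + y^2)
  if (rr < .Machine$double.eps)
    stop("undefined radial direction: voxel at the slice centroid", call. = FALSE)
  rhat <- c(x / rr, y / rr, 0)
  lhat <- geometry$long_axis
  chat <- c(lhat[2] * rhat[3] - lhat[3] * rhat[2],
            lhat[3] * rhat[1] - lhat[1] * rhat[3],
            lhat[1] * rhat[2] - lhat[2] * rhat[1])
  list(circumferential = chat, longitudinal = lhat, radial = rhat)
}

# vectorized frames for all masked voxels of the geometry; returns matrices
# (nvox x 3) keyed by the linear voxel index
frames_for_mask <- function(geometry) {
  dm <- dim(geometry$myo_mask)
  idx <- which(geometry$myo_mask, arr.ind = TRUE)
  ctr <- geometry$centroid[idx[, 3], , drop = FALSE]
  x <- idx[, 2] - ctr[, 2]
  y <- ctr[, 1] - idx[, 1]
  rr <- sqrt(x^2 + y^2)
  ok <- rr > .Machine$double.eps
  rhat <- cbind(x / rr, y / rr, 0)
  lhat <- matrix(geometry$long_axis, nrow(idx), 3, byrow = TRUE)
  chat <- cbind(lhat[, 2] * rhat[, 3] - lhat[, 3] * rhat[, 2],
                lhat[, 3] * rhat[, 1] - lhat[, 1] * rhat[, 3],
                lhat[, 1] * rhat[, 2] - lhat[, 2] * rhat[, 1])
  list(idx = idx, lin = which(geometry$myo_mask), ok = ok,
       rhat = rhat, lhat = lhat, chat = chat)
}

#' Helix-angle map with the Streeter sign convention
#'
#' For each myocardial voxel the principal eigenvector e1 (mean intravoxel
#' myocyte orientation) is projected onto the plane tangential to the local
#' endocardium (spanned by the circumferential and longitudinal directions,
#' normal to the radial); the helix angle is the angle between that
#' projection and the short-axis plane:
#' `HA = atan2(v . l, v . c)` in degrees. The sign of the projection is
#' flipped so `v . c >= 0`, which removes the +-e1 ambiguity and confines HA
#' to `[-90, +90]` — positive for right-handed (endocardial) helices,
#' negative for left-handed (epicardial) ones, 0 circumferential; a purely
#' longitudinal projection maps to +90. Voxels with a vanishing projection
#' or degenerate leading eigenvalues (lambda1 - lambda2 < 1e-12) are masked
#' as unreliable.
#'
#' @param eig a repaired `eigen_field`.
#' @param geometry an [lv_geometry()] with the same array dimensions.
#' @return A `scalar_map` (kind `"HA"`, degrees) over the intersection of
#'   the eigensystem mask and the myocardium.
#' @export
helix_angle_map <- function(eig, geometry) {
  stopifnot(inherits(eig, "eigen_field"), inherits(geometry, "lv_geometry"))
  dm <- dim(eig$values)[1:3]
  if (!all(dm == dim(geometry$myo_mask)))
    stop("dimension error: eigensystem and geometry shapes differ", call. = FALSE)
  fr <- frames_for_mask(geometry)
  keep <- fr$ok & eig$mask[fr$lin]
  ha <- array(NA_real_, dm)
  mask <- array(FALSE, dm)
  if (any(keep)) {
    lin <- fr$lin[keep]
    e1 <- sapply(1:3, function(c3) eig$vectors[, , , c3, 1][lin])
    if (length(lin) == 1) e1 <- matrix(e1, 1)
    rhat <- fr$rhat[keep, , drop = FALSE]
    chat <- fr$chat[keep, , drop = FALSE]
    lhat <- fr$lhat[keep, , drop = FALSE]
    er <- rowSums(e1 * rhat)
    v <- e1 - er * rhat
    vc <- rowSums(v * chat)
    vl <- rowSums(v * lhat)
    flip <- vc < 0
    vc[flip] <- -vc[flip]; vl[flip] <- -vl[flip]
    vnorm <- sqrt(vc^2 + vl^2)
    l1 <- slice4(eig$values, 1)[lin]; l2 <- slice4(eig$values, 2)[lin]
    reliable <- vnorm >= 1e-9 & (l1 - l2) >= 1e-12
    ang <- atan2(vl, vc) * 180 / pi
    ang[abs(vc) < 1e-15 & vl != 0] <- 90
    ha[lin[reliable]] <- ang[reliable]
    mask[lin[reliable]] <- TRUE
  }
  new_scalar_map(ha, mask, "HA", "degrees", geometry$pixel_spacing)
}

#' Transmural layer labels
#'
#' Divides the wall into three equal-thickness layers by transmural depth:
#' endocardial `d < 1/3`, mesocardial `1/3 <= d < 2/3`, epicardial
#' `d >= 2/3` (half-open boundaries).
#'
#' @param geometry an [lv_geometry()] whose `depth` is set (see
#'   [transmural_depth()]).
#' @return Integer array with levels 1 = endocardial, 2 = mesocardial,
#'   3 = epicardial (NA outside the myocardium), with a `levels` attribute.
#' @export
assign_layers <- function(geometry) {
  stopifnot(inherits(geometry, "lv_geometry"))
  if (is.null(geometry$depth))
    stop("geometry has no depth map; run transmural_depth() first", call. = FALSE)
  d <- geometry$depth
  lab <- array(NA_integer_, dim(d))
  lab[!is.na(d) & d < 1 / 3] <- 1L
  lab[!is.na(d) & d >= 1 / 3 & d < 2 / 3] <- 2L
  lab[!is.na(d) & d >= 2 / 3] <- 3L
  attr(lab, "levels") <- c("endocardial", "mesocardial", "epicardial")
  lab
}

#' Left-ventricular wall labels
#'
#' Four 90-degree sectors anchored to the right-ventricular azimuth:
#' septal is the sector within +-45 degrees of `rv_azimuth`, anterior the
#' next sector counterclockwise (viewed from the base), lateral opposite
#' the septum, inferior the remainder.
#'
#' @param geometry an [lv_geometry()] with `rv_azimuth` set.
#' @return Integer array with levels 1 = anterior, 2 = septal,
#'   3 = inferior, 4 = lateral (NA outside the myocardium), with a `levels`
#'   attribute.
#' @export
assign_walls <- function(geometry) {
  stopifnot(inherits(geometry, "lv_geometry"))
  dm <- dim(geometry$myo_mask)
  lab <- array(NA_integer_, dm)
  idx <- which(geometry$myo_mask, arr.ind = TRUE)
  ctr <- geometry$centroid[idx[, 3], , drop = FALSE]
  x <- idx[, 2] - ctr[, 2]
  y <- ctr[, 1] - idx[, 1]
  az <- atan2(y, x) * 180 / pi
  # sectors counted math-counterclockwise from the septal sector edge; the
  # long axis points out of the image toward the base, so counterclockwise
  # viewed FROM the base runs clockwise here: the anterior sector is at
  # rv_azimuth - 90 in image coordinates
  rel <- (az - geometry$rv_azimuth + 45) %% 360
  sector <- floor(rel / 90)                        # 0 septal, then inferior, lateral, anterior
  wall <- c(2L, 3L, 4L, 1L)[sector + 1L]
  lab[which(geometry$myo_mask)] <- wall
  attr(lab, "levels") <- c("anterior", "septal", "inferior", "lateral")
  lab
}

#' Slice, wall and layer labels for every myocardial voxel
#'
#' Combines [assign_layers()] and [assign_walls()] with slice naming
#' (basal / mid / apical for the conventional 3-slice stack, `slice_k`
#' otherwise) into a single label set partitioning the myocardium.
#'
#' @param geometry an [lv_geometry()]; depth is computed if missing.
#' @return An object of class `region_labels`: list of `slice`, `wall`,
#'   `layer` integer arrays plus level names and the myocardial mask.
#' @export
region_labels <- function(geometry) {
  stopifnot(inherits(geometry, "lv_geometry"))
  if (is.null(geometry$depth)) geometry <- transmural_depth(geometry)
  dm <- dim(geometry$myo_mask)
  ns <- dm[3]
  slice_levels <- if (ns == 3) c("basal", "mid", "apical")
                  else paste0("slice_", seq_len(ns))
  slice <- array(rep(seq_len(ns), each = dm[1] * dm[2]), dm)
  slice[!geometry$myo_mask] <- NA_integer_
  layer <- assign_layers(geometry)
  layer[!geometry$myo_mask] <- NA_integer_
  structure(list(slice = slice, wall = assign_walls(geometry), layer = layer,
                 slice_levels = slice_levels,
                 wall_levels = attr(assign_walls(geometry), "levels"),
                 layer_levels = c("endocardial", "mesocardial", "epicardial"),
                 mask = geometry$myo_mask),
            class = "region_labels")
}
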