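#' Configuration for the synthetic left-ventricle phantom
#'
#' Defines an annular short-axis LV phantom with a linear transmural
#' helix-angle ramp, homogeneous FA and MD inside the myocardium, Rician
#' noise, inter-repetition breath-hold translations and occasional corrupted
#' frames. The defaults reproduce the acquisition that the pipeline targets:
#' 3 short-axis slices at 2.7 mm in-plane resolution, b = 350 s/mm^2 with six
#' encoding directions, about 10 repetitions per image, global myocardial
#' FA 0.613 and MD 0.750e-3 mm^2/s, and a helix-angle ramp from +38.9 deg at
#' the endocardium (right-handed) to -34.3 deg at the epicardium
#' (left-handed).
#'
#' `noise_sigma = 50` with `s0 = 1000` corresponds to a b0 SNR of 20.
#'
#' @param grid_size voxels per in-plane edge.
#' @param n_slices number of short-axis slices (basal -> apical).
#' @param pixel_spacing in-plane voxel size, mm.
#' @param endo_radius,epi_radius endocardial / epicardial radius, mm.
#' @param ha_endo,ha_epi helix angle at the endocardial / epicardial border,
#'   degrees (Streeter convention: positive right-handed endocardial,
#'   negative left-handed epicardial).
#' @param target_fa myocardial fractional anisotropy, in `[0, 1)`.
#' @param target_md myocardial mean diffusivity, mm^2/s.
#' @param s0 b0 signal level, arbitrary units.
#' @param noise_sigma Rician noise parameter, same units as `s0`.
#' @param n_repetitions repetitions per slice/direction before averaging.
#' @param shift_sd SD of the per-repetition breath-hold translation, pixels
#'   (rounded to integers).
#' @param corrupt_prob probability that any one frame carries a signal-loss
#'   band artefact.
#' @param rv_azimuth azimuth of the septum (direction of the right ventricle
#'   from the LV centroid), degrees counterclockwise from +x.
#' @param seed integer seed; all phantom randomness is derived from it.
#' @return A `phantom_config` list.
#' @examples
#' cfg <- phantom_config(grid_size = 32, noise_sigma = 0, shift_sd = 0,
#'                       corrupt_prob = 0, n_repetitions = 1)
#' truth <- build_truth(cfg)
#' @export
phantom_config <- function(grid_size = 48,
                           n_slices = 3,
                           pixel_spacing = 2.7,
                           endo_radius = 12,
                           epi_radius = 25,
                           ha_endo = 38.9,
                           ha_epi = -34.3,
                           target_fa = 0.613,
                           target_md = 0.750e-3,
                           s0 = 1000,
                           noise_sigma = 50,
                           n_repetitions = 10,
                           shift_sd = 1,
                           corrupt_prob = 0.05,
                           rv_azimuth = 180,
                           seed = 1L) {
  if (!(endo_radius > 0 && epi_radius > endo_radius))
    stop("invalid parameter: need 0 < endo_radius < epi_radius", call. = FALSE)
  if (!(target_fa >= 0 && target_fa < 1))
    stop("invalid parameter: target_fa must lie in [0, 1)", call. = FALSE)
  if (target_md <= 0)
    stop("invalid parameter: target_md must be positive", call. = FALSE)
  if (n_repetitions < 1)
    stop("invalid parameter: n_repetitions >= 1 required", call. = FALSE)
  if (corrupt_prob < 0 || corrupt_prob > 1)
    stop("invalid parameter: corrupt_prob must lie in [0, 1]", call. = FALSE)
  if (noise_sigma < 0)
    stop("invalid parameter: noise_sigma must be non-negative", call. = FALSE)
  if (shift_sd < 0)
    stop("invalid parameter: shift_sd must be non-negative", call. = FALSE)
  structure(
    list(grid_size = as.integer(grid_size), n_slices = as.integer(n_slices),
         pixel_spacing = pixel_spacing, endo_radius = endo_radius,
         epi_radius = epi_radius, ha_endo = ha_endo, ha_epi = ha_epi,
         target_fa = target_fa, target_md = target_md, s0 = s0,
         noise_sigma = noise_sigma, n_repetitions = as.integer(n_repetitions),
         shift_sd = shift_sd, corrupt_prob = corrupt_prob,
         rv_azimuth = rv_azimuth, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Axially symmetric eigenvalues from FA and MD
#'
#' Inverts the FA/MD definitions for a prolate, axially symmetric tensor
#' (lambda2 = lambda3). With a = FA / sqrt(3 - 2 FA^2):
#' lambda1 = MD (1 + 2a), lambda2 = lambda3 = MD (1 - a). Substituting back
#' into the FA and MD formulas reproduces the inputs exactly.
#'
#' @param fa fractional anisotropy in `[0, 1)`.
#' @param md mean diffusivity, mm^2/s (positive).
#' @return Numeric vector `c(lambda1, lambda2, lambda3)` in mm^2/s,
#'   `lambda1 >= lambda2 = lambda3 >= 0`.
#' @examples
#' eigenvalues_from_fa_md(0.613, 0.750e-3)
#' @export
eigenvalues_from_fa_md <- function(fa, md) {
  if (!is.numeric(fa) || length(fa) != 1 || fa < 0 || fa >= 1)
    stop("invalid parameter: fa must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(md) || length(md) != 1 || md <= 0)
    stop("invalid parameter: md must be positive", call. = FALSE)
  a <- fa / sqrt(3 - 2 * fa^2)
  c(md * (1 + 2 * a), md * (1 - a), md * (1 - a))
}

# in-plane voxel-centre coordinates (mm) relative to the grid centre;
# +x to the right (increasing column), +y up (decreasing row), so that with
# the long axis +z (apex -> base, out of the short-axis plane) the frame is
# right-handed
grid_coords <- function(grid_size, pixel_spacing) {
  centre <- (grid_size + 1) / 2
  col <- matrix(rep(seq_len(grid_size), each = grid_size), grid_size)
  row <- matrix(rep(seq_len(grid_size), times = grid_size), grid_size)
  list(x = (col - centre) * pixel_spacing,
       y = (centre - row) * pixel_spacing,
       centre = c(centre, centre))
}

#' Build the ground-truth tensor field and geometry of the phantom
#'
#' Each myocardial voxel receives a tensor `R diag(l1, l2, l3) R'` whose
#' principal eigenvector e1 lies in the local endocardial tangent plane
#' (spanned by the circumferential and longitudinal directions) at the
#' prescribed helix angle; the tertiary eigenvector is radial and e2
#' completes a right-handed frame (sheet-normal convention). The helix angle
#' ramps linearly with transmural depth from `ha_endo` to `ha_epi`. The LV
#' cavity is filled with isotropic "blood" diffusivity (2.5e-3 mm^2/s) so b0
#' images have realistic bright-cavity contrast.
#'
#' @param config a [phantom_config()].
#' @return A `phantom_truth` list: 6-component `tensor` array
#'   (row, col, slice, Dxx..Dyz) over the signal support, unit `e1` field,
#'   `ha`, `fa`, `md` truth maps (NA outside the myocardium), and the
#'   [lv_geometry] model.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$grid_size
  ns <- config$n_slices
  co <- grid_coords(n, config$pixel_spacing)
  r <- sqrt(co$x^2 + co$y^2)
  myo2d <- r >= config$endo_radius & r <= config$epi_radius
  cav2d <- r < config$endo_radius
  if (!any(myo2d))
    stop("geometry error: empty myocardial mask", call. = FALSE)

  lam <- if (config$target_fa == 0) {
    rep(config$target_md, 3)
  } else {
    eigenvalues_from_fa_md(config$target_fa, config$target_md)
  }

  depth2d <- (r - config$endo_radius) / (config$epi_radius - config$endo_radius)
  ha2d <- config$ha_endo + depth2d * (config$ha_epi - config$ha_endo)

  idx <- which(myo2d)
  rx <- co$x[idx] / r[idx]; ry <- co$y[idx] / r[idx]
  # rhat = (rx, ry, 0); lhat = (0,0,1); chat = lhat x rhat = (-ry, rx, 0)
  ha <- ha2d[idx] * pi / 180
  e1 <- cbind(-ry * cos(ha), rx * cos(ha), sin(ha))
  e3 <- cbind(rx, ry, 0)
  # e2 = e3 x e1
  e2 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])
  outer6 <- function(v) cbind(v[, 1]^2, v[, 2]^2, v[, 3]^2,
                              v[, 1] * v[, 2], v[, 1] * v[, 3], v[, 2] * v[, 3])
  D6 <- lam[1] * outer6(e1) + lam[2] * outer6(e2) + lam[3] * outer6(e3)

  blood_md <- 2.5e-3
  tensor2d <- matrix(NA_real_, n * n, 6)
  tensor2d[idx, ] <- D6
  cavidx <- which(cav2d)
  tensor2d[cavidx, ] <- matrix(rep(c(blood_md, blood_md, blood_md, 0, 0, 0),
                                   each = length(cavidx)), length(cavidx))

  rep_slices <- function(m2d, extra = NULL) {
    a <- array(m2d, dim = c(n, n, ns, length(extra)))
    if (is.null(extra)) array(m2d, dim = c(n, n, ns)) else a
  }
  tensor <- array(NA_real_, c(n, n, ns, 6))
  e1f <- array(NA_real_, c(n, n, ns, 3))
  for (s in seq_len(ns)) {
    tensor[, , s, ] <- tensor2d
    tmp <- matrix(NA_real_, n * n, 3)
    tmp[idx, ] <- e1
    e1f[, , s, ] <- tmp
  }
  mk <- function(v2d) {
    out <- matrix(NA_real_, n, n)
    out[idx] <- v2d[idx]
    array(out, c(n, n, ns))
  }
  geometry <- lv_geometry(
    myo_mask = rep_slices(myo2d),
    cavity_mask = rep_slices(cav2d),
    centroid = matrix(rep(co$centre, ns), ns, 2, byrow = TRUE),
    rv_azimuth = config$rv_azimuth,
    pixel_spacing = config$pixel_spacing,
    depth = mk(depth2d)
  )
  structure(
    list(tensor = tensor, e1 = e1f,
         ha = mk(ha2d),
         fa = mk(matrix(config$target_fa, n, n)),
         md = mk(matrix(config$target_md, n, n)),
         geometry = geometry, config = config),
    class = "phantom_truth"
  )
}

#' Add Rician noise to a magnitude image
#'
#' Replaces each intensity x by `|(x + n1) + i n2|` with independent
#' `n1, n2 ~ Normal(0, sigma)` — the noise model of magnitude MR data. For
#' x = 0 the output is Rayleigh with mean `sigma * sqrt(pi/2)`; for
#' `x >> sigma` the mean tends to `sqrt(x^2 + sigma^2)`, the bias that makes
#' low-SNR diffusion estimates optimistic.
#'
#' @param x numeric array of intensities.
#' @param sigma noise parameter (same units as `x`), non-negative.
#' @param seed optional integer seed for reproducibility.
#' @return Array of the same shape, all values non-negative.
#' @export
add_rician_noise <- function(x, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("invalid parameter: sigma must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(x)
  n1 <- stats::rnorm(length(x), 0, sigma)
  n2 <- stats::rnorm(length(x), 0, sigma)
  out <- sqrt((as.vector(x) + n1)^2 + n2^2)
  array(out, dim = if (is.null(dim(x))) length(x) else dim(x))
}

# integer translation with zero fill; dy > 0 moves content toward larger row
translate_image <- function(img, dy, dx) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  src_r <- seq_len(n) - dy; src_c <- seq_len(m) - dx
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= m
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Simulate a diffusion-weighted acquisition of the phantom
#'
#' Forward model: per voxel and direction, `S_i = S0 exp(-b g' D g)`
#' (Stejskal-Tanner attenuation of the ground-truth tensor), channel 0 being
#' the b = 0 reference. Each repetition receives an independent
#' integer-rounded translation ~ Normal(0, shift_sd) emulating breath-hold
#' position changes; each frame is, with probability `corrupt_prob`, struck
#' by a signal-dropout band (a zeroed run of rows); Rician noise with
#' parameter `noise_sigma` is applied last. Everything is deterministic
#' given `config$seed`.
#'
#' @param truth a [build_truth()] result.
#' @param scheme a [gradient_scheme()]; defaults to the six dual-gradient
#'   directions at the config's b-value of 350 s/mm^2.
#' @param config the [phantom_config()] used for `truth`.
#' @return A [dwi_series] whose `meta` records the applied per-repetition
#'   shifts and the corrupted-frame flags.
#' @export
simulate_dwi <- function(truth, scheme = gradient_scheme(default_directions()),
                         config = truth$config) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(scheme, "gradient_scheme"))
  n <- config$grid_size; ns <- config$n_slices
  ndir <- nrow(scheme$directions); nch <- ndir + 1L
  nrep <- config$n_repetitions

  support <- !is.na(truth$tensor[, , , 1, drop = FALSE])[, , , 1]
  D6 <- matrix(0, n * n * ns, 6)
  for (k in 1:6) {
    comp <- truth$tensor[, , , k]
    comp[!support] <- 0
    D6[, k] <- as.vector(comp)
  }
  atten <- exp(-scheme$b_value * tensor_quadform(D6, scheme$directions))

  clean <- array(0, c(n, n, ns, nch))
  s0map <- array(ifelse(support, config$s0, 0), c(n, n, ns))
  clean[, , , 1] <- s0map
  for (i in seq_len(ndir))
    clean[, , , i + 1L] <- s0map * array(atten[, i], c(n, n, ns))

  set.seed(config$seed)
  shifts <- matrix(round(stats::rnorm(2L * nrep, 0, config$shift_sd)), nrep, 2)
  colnames(shifts) <- c("dy", "dx")
  corrupt <- array(stats::runif(ns * nch * nrep) < config$corrupt_prob,
                   c(ns, nch, nrep))
  band_h <- max(2L, n %/% 4L)
  band_start <- array(sample.int(n - band_h + 1L, ns * nch * nrep, replace = TRUE),
                      c(ns, nch, nrep))

  intens <- array(0, c(n, n, ns, nch, nrep))
  for (r in seq_len(nrep)) {
    for (s in seq_len(ns)) {
      for (ch in seq_len(nch)) {
        img <- translate_image(clean[, , s, ch], shifts[r, 1], shifts[r, 2])
        if (corrupt[s, ch, r]) {
          b0row <- band_start[s, ch, r]
          img[b0row:(b0row + band_h - 1L), ] <- 0
        }
        intens[, , s, ch, r] <- img
      }
    }
  }
  if (config$noise_sigma > 0)
    intens <- array(add_rician_noise(intens, config$noise_sigma),
                    dim(intens))

  meta <- list(
    shifts = tibble::tibble(repetition = seq_len(nrep),
                            dy = shifts[, 1], dx = shifts[, 2]),
    corrupted = tidyr::expand_grid(slice = seq_len(ns),
                                   channel = seq_len(nch),
                                   repetition = seq_len(nrep)) |>
      dplyr::mutate(corrupted = as.vector(corrupt[cbind(.data$slice,
                                                        .data$channel,
                                                        .data$repetition)]))
  )
  dwi_series(intens, scheme, pixel_spacing = config$pixel_spacing,
             slice_positions = seq(0, by = 12, length.out = ns),
             meta = meta)
}
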