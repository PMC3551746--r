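# drop-safe extraction of component k from a (r, c, s, k) array
slice4 <- function(a, k) array(a[, , , k, drop = FALSE], dim(a)[1:3])

#' Log-linear diffusion tensor fit
#'
#' Estimates the rank-2 symmetric diffusion tensor per voxel from the
#' averaged b0 + diffusion-weighted images by solving
#' `-ln(S_i / S0) = b g_i' D g_i` through the 6-column design matrix
#' `(gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)`. With exactly six
#' directions the system is exactly determined; with more it is solved in
#' the least-squares sense. Signals are clipped below at `1e-6 * S0` before
#' the log, and voxels with `S0 < s0_floor` are masked out.
#'
#' @param averaged a [dwi_series()] with a single repetition (see
#'   [average_repetitions()]).
#' @param scheme gradient scheme; defaults to the one carried by `averaged`.
#' @param s0_floor minimum b0 intensity for a voxel to be fitted; default
#'   5% of the robust (99th percentile) S0 maximum.
#' @return A `tensor_field`: list with `D` array (row, col, slice, 6
#'   components Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), logical `mask`,
#'   and per-voxel RMS fit `residual` (dimensionless; 0 to machine precision
#'   for noiseless 6-direction data).
#' @export
fit_tensor_loglinear <- function(averaged, scheme = averaged$scheme,
                                 s0_floor = NULL) {
  stopifnot(inherits(averaged, "dwi_series"))
  d <- dim(averaged$intensities)
  if (d[5] != 1)
    stop("averaged series must have exactly 1 repetition", call. = FALSE)
  A <- dti_design_matrix(scheme)
  if (qr(A)$rank < 6)
    stop("invalid scheme: rank-deficient design matrix", call. = FALSE)
  s0 <- array(averaged$intensities[, , , 1, 1], d[1:3])
  if (is.null(s0_floor)) {
    s0_floor <- 0.05 * stats::quantile(s0, 0.99, names = FALSE)
    if (!is.finite(s0_floor) || s0_floor <= 0) s0_floor <- .Machine$double.eps
  }
  if (s0_floor <= 0)
    stop("invalid parameter: s0_floor must be positive", call. = FALSE)
  mask <- s0 >= s0_floor & is.finite(s0)
  idx <- which(mask)
  ndir <- nrow(scheme$directions)

  Y <- matrix(0, ndir, length(idx))
  for (i in seq_len(ndir)) {
    si <- array(averaged$intensities[, , , i + 1L, 1], d[1:3])[idx]
    si <- pmax(si, 1e-6 * s0[idx])
    Y[i, ] <- -log(si / s0[idx])
  }
  qrA <- qr(A)
  coef <- qr.coef(qrA, Y)              # 6 x nvox
  res <- sqrt(colMeans((A %*% coef - Y)^2))

  Darr <- array(NA_real_, c(d[1:3], 6))
  resid <- array(NA_real_, d[1:3])
  for (k in 1:6) {
    tmp <- array(NA_real_, d[1:3]); tmp[idx] <- coef[k, ]
    Darr[, , , k] <- tmp
  }
  resid[idx] <- res
  structure(list(D = Darr, mask = mask, residual = resid,
                 pixel_spacing = averaged$pixel_spacing),
            class = "tensor_field")
}

#' Per-voxel eigensystem of a tensor field
#'
#' Symmetric eigendecomposition of every masked voxel's tensor. Eigenvalues
#' are sorted descending; each eigenvector's sign is fixed deterministically
#' (its largest-magnitude component is made positive) so repeated runs and
#' degenerate inputs give stable output. Voxels with non-finite tensor
#' components are removed from the mask with a warning.
#'
#' @param field a `tensor_field` from [fit_tensor_loglinear()].
#' @return An `eigen_field`: `values` array (row, col, slice, 3),
#'   `vectors` array (row, col, slice, 3 components, 3 ranks), `mask`, and
#'   a `repaired` logical array (all FALSE here; see
#'   [repair_negative_eigenvalues()]).
#' @export
eigendecompose <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  dm <- dim(field$D)[1:3]
  mask <- field$mask
  idx <- which(mask)
  D6 <- sapply(1:6, function(k) slice4(field$D, k)[idx])
  if (length(idx) == 1) D6 <- matrix(D6, 1)
  bad <- !apply(is.finite(D6), 1, all)
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with non-finite tensor components masked out")
    mask[idx[bad]] <- FALSE
    idx <- idx[!bad]; D6 <- D6[!bad, , drop = FALSE]
  }
  values <- array(NA_real_, c(dm, 3))
  vectors <- array(NA_real_, c(dm, 3, 3))
  vals <- matrix(NA_real_, length(idx), 3)
  vecs <- array(NA_real_, c(length(idx), 3, 3))
  for (i in seq_along(idx)) {
    M <- matrix(c(D6[i, 1], D6[i, 4], D6[i, 5],
                  D6[i, 4], D6[i, 2], D6[i, 6],
                  D6[i, 5], D6[i, 6], D6[i, 3]), 3, 3)
    e <- eigen(M, symmetric = TRUE)     # values already decreasing
    for (k in 1:3) {
      v <- e$vectors[, k]
      j <- which.max(abs(v))
      if (v[j] < 0) v <- -v
      vecs[i, , k] <- v
    }
    vals[i, ] <- e$values
  }
  for (k in 1:3) {
    tmp <- array(NA_real_, dm); tmp[idx] <- vals[, k]; values[, , , k] <- tmp
    for (c3 in 1:3) {
      tmp <- array(NA_real_, dm); tmp[idx] <- vecs[, c3, k]
      vectors[, , , c3, k] <- tmp
    }
  }
  structure(list(values = values, vectors = vectors, mask = mask,
                 repaired = array(FALSE, c(dm, 3)),
                 pixel_spacing = field$pixel_spacing),
            class = "eigen_field")
}

#' Repair negative eigenvalues from neighbouring voxels
#'
#' Noise, high local anisotropy, misregistration or artefacts can drive a
#' small fraction of measured eigenvalues negative, violating positive
#' definiteness. In a single pass, each negative eigenvalue of rank k is
#' replaced by the mean of the rank-k eigenvalues over the in-plane
#' 8-connected masked neighbours whose own rank-k eigenvalue is
#' non-negative (cross-slice neighbours are excluded: the slice gap makes
#' them poor surrogates). A voxel with no such neighbour gets 0.
#' Non-negative eigenvalues and all eigenvectors are untouched.
#'
#' @param eig an `eigen_field`.
#' @return The `eigen_field` with all eigenvalues non-negative and
#'   `repaired` flags set where a value was replaced; the number of repaired
#'   values is stored in `attr(, "n_repaired")`.
#' @export
repair_negative_eigenvalues <- function(eig) {
  stopifnot(inherits(eig, "eigen_field"))
  dm <- dim(eig$values)[1:3]
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  n_rep <- 0L
  for (k in 1:3) {
    vk <- slice4(eig$values, k)
    neg <- which(eig$mask & !is.na(vk) & vk < 0, arr.ind = TRUE)
    if (nrow(neg) == 0) next
    for (i in seq_len(nrow(neg))) {
      r <- neg[i, 1]; c <- neg[i, 2]; s <- neg[i, 3]
      nb <- c()
      for (j in seq_len(nrow(offs))) {
        rr <- r + offs$dr[j]; cc <- c + offs$dc[j]
        if (rr < 1 || cc < 1 || rr > dm[1] || cc > dm[2]) next
        if (!eig$mask[rr, cc, s]) next
        v <- vk[rr, cc, s]
        if (!is.na(v) && v >= 0) nb <- c(nb, v)
      }
      eig$values[r, c, s, k] <- if (length(nb)) mean(nb) else 0
      eig$repaired[r, c, s, k] <- TRUE
      n_rep <- n_rep + 1L
    }
  }
  attr(eig, "n_repaired") <- n_rep
  eig
}

new_scalar_map <- function(values, mask, kind, units, pixel_spacing = NULL) {
  structure(list(values = values, mask = mask, kind = kind, units = units,
                 pixel_spacing = pixel_spacing),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<scalar_map:%s> %d voxels, mean %.4g %s\n",
              x$kind, sum(x$mask), mean(v, na.rm = TRUE), x$units))
  invisible(x)
}

#' Mean diffusivity map
#'
#' MD is the first moment of the diffusion tensor — the average diffusivity
#' `(lambda1 + lambda2 + lambda3) / 3`, equal to trace(D)/3 and therefore
#' rotation invariant.
#'
#' @param eig a repaired `eigen_field`.
#' @return A `scalar_map` (kind `"MD"`, units mm^2/s).
#' @export
compute_md <- function(eig) {
  stopifnot(inherits(eig, "eigen_field"))
  md <- (slice4(eig$values, 1) + slice4(eig$values, 2) + slice4(eig$values, 3)) / 3
  new_scalar_map(md, eig$mask, "MD", "mm^2/s", eig$pixel_spacing)
}

#' Fractional anisotropy map
#'
#' FA indexes the deviation of diffusion from isotropy:
#' `FA = sqrt(3/2) * sqrt(sum((lambda_k - mean)^2)) / sqrt(sum(lambda_k^2))`,
#' 0 for isotropic diffusion, 1 in the one-dimensional limit. The value is
#' clipped to `[0, 1]` against floating-point overshoot and set to 0 by
#' convention when all eigenvalues vanish.
#'
#' @param eig a repaired `eigen_field`.
#' @return A `scalar_map` (kind `"FA"`, dimensionless).
#' @export
compute_fa <- function(eig) {
  stopifnot(inherits(eig, "eigen_field"))
  l1 <- slice4(eig$values, 1); l2 <- slice4(eig$values, 2)
  l3 <- slice4(eig$values, 3)
  lb <- (l1 + l2 + l3) / 3
  num <- (l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[den == 0] <- 0
  fa <- pmin(pmax(fa, 0), 1)
  new_scalar_map(array(fa, dim(l1)), eig$mask, "FA", "dimensionless",
                 eig$pixel_spacing)
}
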