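#' Diffusion gradient scheme
#'
#' A gradient scheme couples the diffusion sensitization (b-value, s/mm^2)
#' with the set of unit encoding direction vectors. The scheme defines the
#' design matrix of the log-linear tensor fit, so at least six directions
#' spanning a rank-6 design are required.
#'
#' Directions whose norm deviates from 1 by less than 1% are renormalized
#' (with a warning when the deviation exceeds 1e-6); larger deviations are a
#' format error.
#'
#' @param directions numeric matrix, one row per encoding direction (3 columns).
#' @param b_value diffusion sensitization in s/mm^2 (default 350, the value
#'   typical of breath-hold stimulated-echo cardiac protocols).
#' @return An object of class `gradient_scheme`: a list with elements
#'   `b_value` and `directions` (n x 3 matrix of unit rows).
#' @examples
#' sch <- gradient_scheme(default_directions())
#' dti_design_matrix(sch)
#' @export
gradient_scheme <- function(directions, b_value = 350) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3)
    stop("directions must be an n x 3 matrix", call. = FALSE)
  if (nrow(directions) < 6)
    stop("invalid scheme: at least 6 encoding directions are required, got ",
         nrow(directions), call. = FALSE)
  if (!is.numeric(b_value) || length(b_value) != 1 || b_value <= 0)
    stop("b_value must be a single positive number", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 0.01))
    stop("format error: encoding direction norm deviates from unit by more than 1%",
         call. = FALSE)
  if (any(abs(nrm - 1) > 1e-6))
    warning("non-unit encoding directions normalized (deviation <= 1%)")
  directions <- directions / nrm
  scheme <- structure(
    list(b_value = b_value, directions = directions),
    class = "gradient_scheme"
  )
  if (qr(dti_design_matrix(scheme))$rank < 6)
    stop("invalid scheme: tensor design matrix is rank-deficient", call. = FALSE)
  scheme
}

#' Default six-direction encoding set
#'
#' The classic dual-gradient set (+-1,+-1,0 permutations, normalized), which
#' yields a well-conditioned rank-6 design. Protocol papers rarely print
#' their direction tables; this set is the conventional minimal choice and
#' can be replaced by any scheme read from bval/bvec sidecars.
#'
#' @return 6 x 3 matrix of unit direction vectors.
#' @export
default_directions <- function() {
  d <- rbind(
    c(1,  1, 0), c(1, -1, 0),
    c(1,  0, 1), c(1,  0, -1),
    c(0,  1, 1), c(0,  1, -1)
  )
  d / sqrt(2)
}

#' Tensor-fit design matrix
#'
#' Row i is b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz) for direction
#' g_i, so that `design %*% d = b * g' D g` with
#' `d = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#'
#' @param scheme a [gradient_scheme()].
#' @return n x 6 numeric matrix.
#' @export
dti_design_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  g <- scheme$directions
  scheme$b_value * cbind(
    g[, 1]^2, g[, 2]^2, g[, 3]^2,
    2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3]
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("<gradient_scheme> b =", x$b_value, "s/mm^2,",
      nrow(x$directions), "directions\n")
  invisible(x)
}

# quadratic form g' D g for a 6-component tensor row vector, vectorized over
# voxels: D is nvox x 6, returns nvox x ndir matrix of g' D g
tensor_quadform <- function(D6, directions) {
  g <- directions
  A <- cbind(
    g[, 1]^2, g[, 2]^2, g[, 3]^2,
    2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3]
  )
  D6 %*% t(A)
}
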