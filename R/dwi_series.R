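#' Diffusion-weighted image series
#'
#' Container for a multi-slice, multi-direction, multi-repetition magnitude
#' image stack. Intensities are a 5-D array indexed
#' (row, col, slice, channel, repetition); channel 1 is the b = 0 reference
#' and channels 2..(n+1) follow the order of the gradient scheme's
#' directions. An `accepted` logical array (slice, channel, repetition)
#' tracks which frames survive artefact rejection; all frames start
#' accepted.
#'
#' @param intensities non-negative 5-D numeric array (or 4-D, promoted to a
#'   single repetition).
#' @param scheme a [gradient_scheme()]; channel count must equal
#'   1 + number of directions.
#' @param pixel_spacing in-plane voxel size, mm.
#' @param slice_positions slice locations along the long axis, mm.
#' @param accepted optional logical array (slice, channel, repetition).
#' @param meta optional list of provenance tables (phantom shifts,
#'   corrupted-frame flags, ...).
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(intensities, scheme, pixel_spacing,
                       slice_positions = NULL, accepted = NULL, meta = list()) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  d <- dim(intensities)
  if (length(d) == 4) {
    intensities <- array(intensities, c(d, 1L))
    d <- dim(intensities)
  }
  if (length(d) != 5)
    stop("intensities must be a 5-D array (row, col, slice, channel, repetition)",
         call. = FALSE)
  if (d[4] != nrow(scheme$directions) + 1L)
    stop("format error: expected ", nrow(scheme$directions) + 1L,
         " channels (b0 + directions), found ", d[4], call. = FALSE)
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative", call. = FALSE)
  if (is.null(slice_positions)) slice_positions <- seq_len(d[3])
  if (is.null(accepted)) accepted <- array(TRUE, d[3:5])
  structure(
    list(intensities = intensities, scheme = scheme,
         pixel_spacing = pixel_spacing, slice_positions = slice_positions,
         accepted = accepted, meta = meta),
    class = "dwi_series"
  )
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<dwi_series> %d x %d pixels, %d slice(s), %d channel(s), %d repetition(s); %d/%d frames accepted\n",
    d[1], d[2], d[3], d[4], d[5], sum(x$accepted), length(x$accepted)))
  invisible(x)
}

#' @export
dim.dwi_series <- function(x) dim(x$intensities)
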