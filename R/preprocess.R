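# normalized cross-correlation (Pearson over pixels); 0 when either image is
# constant, unless both are constant and equal (then 1)
ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) {
    if (sa == 0 && sb == 0 && isTRUE(all.equal(a, b))) return(1)
    return(0)
  }
  stats::cor(a, b)
}

# exhaustive integer-shift NCC search: for each frame of a (nrow, ncol, nframe)
# stack, the translation (dy, dx) within `radius` maximizing the Pearson
# correlation with `ref` over the overlap region (the score at radius 0 is the
# plain NCC). Constant frames score 0.
search_translation <- function(frames, ref, radius) {
  d <- dim(frames)
  nf <- d[3]
  best <- rep(-Inf, nf); best_dy <- integer(nf); best_dx <- integer(nf)
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      # NCC(translate(frame, dy, dx), ref) over the overlap equals
      # cor(frame[src], ref[dst])
      dst_r <- max(1, 1 + dy):min(d[1], d[1] + dy)
      dst_c <- max(1, 1 + dx):min(d[2], d[2] + dx)
      src_r <- dst_r - dy; src_c <- dst_c - dx
      refv <- as.vector(ref[dst_r, dst_c])
      if (stats::sd(refv) == 0) next
      m <- matrix(frames[src_r, src_c, , drop = FALSE],
                  length(src_r) * length(src_c), nf)
      np <- nrow(m)
      cs <- colSums(m)
      num <- colSums(m * refv) - cs * mean(refv)
      den <- sqrt(pmax(colSums(m^2) - cs^2 / np, 0)) *
        sqrt(sum((refv - mean(refv))^2))
      sc <- ifelse(den > 0, num / den, -Inf)
      upd <- sc > best + 1e-12
      best[upd] <- sc[upd]; best_dy[upd] <- dy; best_dx[upd] <- dx
    }
  }
  best[!is.finite(best)] <- 0
  tibble::tibble(score = best, dy = best_dy, dx = best_dx)
}

#' Reject artefact-corrupted repetitions
#'
#' Automated stand-in for visual frame review: each repetition of every
#' (slice, channel) group is scored against the pixelwise median image of
#' its group by normalized cross-correlation, and frames scoring below the
#' threshold are dropped (marked not accepted). Because rejection runs
#' before co-registration, the score is taken as the maximum NCC over small
#' integer translations (`align_radius`); breath-hold position changes then
#' leave intact frames near 1 while signal-loss bands and gross artefacts,
#' which no translation can explain, score low.
#'
#' @param series a [dwi_series()].
#' @param threshold NCC acceptance threshold in (-1, 1]; default 0.9.
#' @param align_radius shift tolerance of the score, pixels.
#' @return A list with elements `series` (accepted flags updated) and
#'   `report`, a tibble with one row per (slice, channel, repetition) giving
#'   the similarity score and the decision.
#' @seealso [register_translation()], [average_repetitions()]
#' @export
reject_corrupted <- function(series, threshold = 0.9, align_radius = 3) {
  stopifnot(inherits(series, "dwi_series"))
  if (!(threshold > -1 && threshold <= 1))
    stop("invalid parameter: threshold must lie in (-1, 1]", call. = FALSE)
  d <- dim(series$intensities)
  ns <- d[3]; nch <- d[4]
  rows <- vector("list", ns * nch)
  accepted <- series$accepted
  k <- 0L
  for (s in seq_len(ns)) {
    for (ch in seq_len(nch)) {
      reps <- which(series$accepted[s, ch, ])
      if (length(reps) == 0)
        stop(sprintf("unusable data: no accepted repetitions for slice %d, channel %d",
                     s, ch), call. = FALSE)
      block <- array(series$intensities[, , s, ch, reps], c(d[1], d[2], length(reps)))
      med <- apply(block, c(1, 2), stats::median)
      score <- search_translation(block, med, align_radius)$score
      keep <- score >= threshold
      if (!any(keep))
        stop(sprintf("unusable data: all repetitions rejected for slice %d, channel %d",
                     s, ch), call. = FALSE)
      accepted[s, ch, reps] <- keep
      k <- k + 1L
      rows[[k]] <- tibble::tibble(slice = s, channel = ch, repetition = reps,
                                  score = score, threshold = threshold,
                                  accepted = keep)
    }
  }
  series$accepted <- accepted
  list(series = series, report = dplyr::bind_rows(rows))
}

#' Co-register repetitions by translation-only cross-correlation
#'
#' Rigid co-registration restricted to integer-pixel translations (no
#' rotation). The reference for each slice is the pixelwise median of its
#' accepted b0 repetitions; every accepted frame is shifted by the integer
#' translation (within `search_radius`) that maximizes the normalized
#' cross-correlation with the reference over the overlap region.
#' Out-of-frame pixels are zero-filled.
#'
#' @param series a [dwi_series()], typically after [reject_corrupted()].
#' @param search_radius maximum |shift| searched per axis, pixels.
#' @return A list with `series` (frames shifted into alignment) and
#'   `result`, a tibble of applied (dy, dx) per frame.
#' @export
register_translation <- function(series, search_radius = 10) {
  stopifnot(inherits(series, "dwi_series"))
  d <- dim(series$intensities)
  if (search_radius < 0 || search_radius > min(d[1], d[2]) / 2)
    stop("invalid parameter: search_radius must lie in [0, grid/2]", call. = FALSE)
  search_radius <- as.integer(search_radius)
  ns <- d[3]
  out <- series$intensities
  rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    b0reps <- which(series$accepted[s, 1, ])
    refblock <- array(series$intensities[, , s, 1, b0reps],
                      c(d[1], d[2], length(b0reps)))
    ref <- apply(refblock, c(1, 2), stats::median)

    acc <- array(series$accepted[s, , , drop = FALSE], d[4:5])
    frames <- which(acc, arr.ind = TRUE)                       # channel, rep
    nf <- nrow(frames)
    fm <- array(0, c(d[1], d[2], nf))
    for (i in seq_len(nf))
      fm[, , i] <- series$intensities[, , s, frames[i, 1], frames[i, 2]]
    found <- search_translation(fm, ref, search_radius)
    for (i in seq_len(nf))
      out[, , s, frames[i, 1], frames[i, 2]] <-
        translate_image(fm[, , i], found$dy[i], found$dx[i])
    rows[[s]] <- tibble::tibble(slice = s, channel = frames[, 1],
                                repetition = frames[, 2],
                                dy = found$dy, dx = found$dx)
  }
  series$intensities <- out
  list(series = series, result = dplyr::bind_rows(rows))
}

#' Average repetitions per channel
#'
#' Pixelwise arithmetic mean over the accepted repetitions of each
#' (slice, channel), the final step of the reject / co-register / average
#' preprocessing chain. The result has a single repetition.
#'
#' @param series a [dwi_series()].
#' @return A [dwi_series] with repetition dimension 1.
#' @export
average_repetitions <- function(series) {
  stopifnot(inherits(series, "dwi_series"))
  d <- dim(series$intensities)
  out <- array(0, c(d[1], d[2], d[3], d[4], 1L))
  for (s in seq_len(d[3])) {
    for (ch in seq_len(d[4])) {
      reps <- which(series$accepted[s, ch, ])
      if (length(reps) == 0)
        stop(sprintf("unusable data: no accepted repetitions for slice %d, channel %d",
                     s, ch), call. = FALSE)
      block <- array(series$intensities[, , s, ch, reps],
                     c(d[1], d[2], length(reps)))
      out[, , s, ch, 1] <- matrix(rowMeans(matrix(block, d[1] * d[2])),
                                  d[1], d[2])
    }
  }
  dwi_series(out, series$scheme, series$pixel_spacing, series$slice_positions,
             meta = series$meta)
}
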