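#' Regional means of a scalar map
#'
#' Unweighted voxel means of a scalar map over myocardial regions: globally
#' (all segments, all slices), by slice, by LV wall and — for helix-angle
#' maps, which vary transmurally by design — by layer and layer-crossed
#' groupings. Empty regions are dropped with a warning.
#'
#' @param map a `scalar_map` (FA, MD or HA).
#' @param labels a [region_labels()] object sharing the map's grid.
#' @param groupings character vector out of `"global"`, `"slice"`,
#'   `"wall"`, `"layer"`, `"layer_slice"`, `"layer_wall"`. Defaults to the
#'   study's grouping for the map kind: global/slice/wall for FA and MD,
#'   layer plus layer-by-slice and layer-by-wall for HA.
#' @return A tibble with columns `metric`, `region_type`, `region`,
#'   `value` (regional mean) and `n_voxels`.
#' @export
region_means <- function(map, labels, groupings = NULL) {
  stopifnot(inherits(map, "scalar_map"), inherits(labels, "region_labels"))
  if (is.null(groupings)) {
    groupings <- if (identical(map$kind, "HA"))
      c("global", "layer", "layer_slice", "layer_wall")
    else c("global", "slice", "wall")
  }
  lin <- which(labels$mask & map$mask & !is.na(map$values))
  if (length(lin) == 0) stop("no valid voxels under the mask", call. = FALSE)
  df <- tibble::tibble(
    value = map$values[lin],
    slice = labels$slice_levels[labels$slice[lin]],
    wall = labels$wall_levels[labels$wall[lin]],
    layer = labels$layer_levels[labels$layer[lin]]
  )
  one <- function(g) {
    keys <- switch(g,
      global = character(0),
      slice = "slice",
      wall = "wall",
      layer = "layer",
      layer_slice = c("layer", "slice"),
      layer_wall = c("layer", "wall"),
      stop("unknown grouping: ", g, call. = FALSE))
    out <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(value = mean(.data$value), n_voxels = dplyr::n(),
                       .groups = "drop")
    region <- if (length(keys) == 0) "global"
              else do.call(paste, c(out[keys], sep = "/"))
    tibble::tibble(region_type = g, region = region,
                   value = out$value, n_voxels = out$n_voxels)
  }
  res <- purrr::map_dfr(groupings, one)
  dplyr::bind_cols(tibble::tibble(metric = map$kind), res)
}

#' Interstudy reproducibility statistics per region
#'
#' Pairs the per-subject regional means of an initial and a repeat study and
#' computes, per region: the pooled mean (mean of all values from both
#' scans), the mean difference (initial - repeat), the SD of the difference
#' (n - 1 denominator), the 95% Bland-Altman limits of agreement
#' (mean difference +- 1.96 SD) and the coefficient of variation
#' `CoV = 100 * SD_of_difference / pooled_mean` (%). The CoV is flagged as
#' not computable (NA) when the pooled mean is within `cov_tol` of zero —
#' as happens for mesocardial helix angles, where the mean approaches zero
#' while the orientation rotates through the wall.
#'
#' @param stats_initial,stats_repeat tibbles with columns `subject`,
#'   `region_type`, `region`, `value` (e.g. stacked [region_means()] rows
#'   per subject) covering the same subjects and regions.
#' @param cov_tol pooled-mean magnitude below which the CoV is flagged NA.
#' @return A tibble of class `repro_result` with one row per region:
#'   `region_type`, `region`, `n`, `mean_value`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `cov_pct`.
#' @export
paired_reproducibility <- function(stats_initial, stats_repeat, cov_tol = 1e-8) {
  need <- c("subject", "region_type", "region", "value")
  stopifnot(all(need %in% names(stats_initial)),
            all(need %in% names(stats_repeat)))
  a <- dplyr::select(stats_initial, dplyr::all_of(need))
  b <- dplyr::select(stats_repeat, dplyr::all_of(need))
  merged <- dplyr::inner_join(a, b, by = c("subject", "region_type", "region"),
                              suffix = c("_i", "_r"))
  if (nrow(merged) != nrow(a) || nrow(merged) != nrow(b))
    stop("pairing error: subjects/regions do not match between studies",
         call. = FALSE)
  out <- merged |>
    dplyr::group_by(.data$region_type, .data$region) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_value = mean(c(.data$value_i, .data$value_r)),
      mean_diff = mean(.data$value_i - .data$value_r),
      sd_diff = stats::sd(.data$value_i - .data$value_r),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      loa_low = .data$mean_diff - 1.96 * .data$sd_diff,
      loa_high = .data$mean_diff + 1.96 * .data$sd_diff,
      cov_pct = dplyr::if_else(abs(.data$mean_value) < cov_tol,
                               NA_real_,
                               100 * .data$sd_diff / .data$mean_value)
    )
  class(out) <- c("repro_result", class(out))
  out
}

#' Bland-Altman points for paired measurements
#'
#' Per subject: the point `((a + b)/2, a - b)`; the bias is the mean
#' difference and the 95% limits of agreement are `bias +- 1.96 SD` of the
#' differences.
#'
#' @param a,b equal-length numeric vectors of paired measurements
#'   (initial and repeat study values).
#' @return A tibble of class `ba_points` with columns `mean` and `diff` and
#'   attributes `bias`, `loa_low`, `loa_high`.
#' @export
bland_altman_points <- function(a, b) {
  if (length(a) != length(b))
    stop("pairing error: vectors of unequal length", call. = FALSE)
  if (length(a) < 2)
    stop("insufficient data: at least 2 pairs required", call. = FALSE)
  d <- a - b
  out <- tibble::tibble(mean = (a + b) / 2, diff = d)
  attr(out, "bias") <- mean(d)
  attr(out, "loa_low") <- mean(d) - 1.96 * stats::sd(d)
  attr(out, "loa_high") <- mean(d) + 1.96 * stats::sd(d)
  class(out) <- c("ba_points", class(out))
  out
}

#' Variance-ratio test comparing two coefficients of variation
#'
#' Compares the reproducibility of two metrics via the ratio of their
#' normalized difference variances:
#' `F = (SD_num / mean_num)^2 / (SD_den / mean_den)^2` on
#' `(n_num - 1, n_den - 1)` degrees of freedom, with a two-sided p-value
#' from the F distribution. Swapping numerator and denominator inverts F
#' and leaves p unchanged.
#'
#' @param diffs_num,diffs_den paired-difference vectors (length >= 2).
#' @param mean_num,mean_den the corresponding measurement means used to
#'   normalize (pooled means of the two scans).
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
variance_ratio_test <- function(diffs_num, diffs_den, mean_num, mean_den) {
  if (length(diffs_num) < 2 || length(diffs_den) < 2)
    stop("insufficient data: need >= 2 differences per group", call. = FALSE)
  v_num <- stats::var(diffs_num) / mean_num^2
  v_den <- stats::var(diffs_den) / mean_den^2
  if (v_den == 0)
    stop("degenerate test: zero denominator variance", call. = FALSE)
  f <- v_num / v_den
  df1 <- length(diffs_num) - 1L
  df2 <- length(diffs_den) - 1L
  p <- 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
  tibble::tibble(statistic = f, df1 = df1, df2 = df2, p_value = min(p, 1))
}

#' Simulate a paired interstudy phantom cohort
#'
#' Generates `n_subjects` phantoms and, for each, an "initial" and a
#' "repeat" scan: the two scans share the subject's geometry but draw
#' independent noise/shift/corruption realizations, and each scan's
#' myocardial FA and MD targets are perturbed by an independent global
#' offset with SD `between_scan_sd` (in the metric's native units),
#' emulating day-to-day physiological and calibration drift. Each scan is
#' run through the full post-processing pipeline and summarised with
#' [region_means()]. Deterministic given `seed`.
#'
#' @param config base [phantom_config()]; per-subject/scan seeds are derived
#'   from `seed`.
#' @param between_scan_sd named numeric vector with elements `fa`
#'   (dimensionless) and `md` (mm^2/s): SD of the per-scan global
#'   perturbation.
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer master seed.
#' @param ... options forwarded to [run_single_study()] (e.g.
#'   `search_radius`, `reject_threshold`).
#' @return A tibble with columns `subject`, `scan` (`"initial"` /
#'   `"repeat"`), `metric`, `region_type`, `region`, `value`, `n_voxels`.
#' @export
synthetic_paired_study <- function(config, between_scan_sd = c(fa = 0, md = 0),
                                   n_subjects = 10, seed = 1L, ...) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_subjects < 2)
    stop("insufficient data: n_subjects >= 2 required", call. = FALSE)
  sd_fa <- if ("fa" %in% names(between_scan_sd)) between_scan_sd[["fa"]] else 0
  sd_md <- if ("md" %in% names(between_scan_sd)) between_scan_sd[["md"]] else 0
  set.seed(seed)
  scan_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_subjects),
                       n_subjects, 2)
  d_fa <- matrix(stats::rnorm(2L * n_subjects, 0, sd_fa), n_subjects, 2)
  d_md <- matrix(stats::rnorm(2L * n_subjects, 0, sd_md), n_subjects, 2)
  rows <- vector("list", 2L * n_subjects)
  k <- 0L
  for (j in seq_len(n_subjects)) {
    for (sc in 1:2) {
      cfg <- config
      cfg$target_fa <- min(max(config$target_fa + d_fa[j, sc], 0), 0.999)
      cfg$target_md <- max(config$target_md + d_md[j, sc], 1e-6)
      cfg$seed <- scan_seeds[j, sc]
      study <- run_single_study(cfg, ...)
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(
        tibble::tibble(subject = j, scan = c("initial", "repeat")[sc]),
        study$region_means
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Reproducibility tables from a paired cohort
#'
#' Convenience wrapper applying [paired_reproducibility()] per metric to the
#' long cohort tibble produced by [synthetic_paired_study()].
#'
#' @param cohort tibble with columns `subject`, `scan`, `metric`,
#'   `region_type`, `region`, `value`.
#' @param cov_tol forwarded to [paired_reproducibility()].
#' @return A tibble of class `repro_result` with a leading `metric` column.
#' @export
cohort_reproducibility <- function(cohort, cov_tol = 1e-8) {
  metrics <- unique(cohort$metric)
  out <- purrr::map_dfr(metrics, function(m) {
    sub <- dplyr::filter(cohort, .data$metric == m)
    res <- paired_reproducibility(
      dplyr::filter(sub, .data$scan == "initial"),
      dplyr::filter(sub, .data$scan == "repeat"),
      cov_tol = cov_tol
    )
    dplyr::bind_cols(tibble::tibble(metric = m), res)
  })
  class(out) <- c("repro_result", class(out))
  out
}

#' Across-subject regional summary
#'
#' Mean, SD and subject count of the per-subject regional means, per scan
#' and region — the layout of single-study regional tables
#' (mean +- SD over subjects).
#'
#' @param cohort tibble with columns `subject`, `scan`, `metric`,
#'   `region_type`, `region`, `value`.
#' @return Tibble with `scan`, `metric`, `region_type`, `region`, `n`,
#'   `mean`, `sd`.
#' @export
across_subject_stats <- function(cohort) {
  cohort |>
    dplyr::group_by(.data$scan, .data$metric, .data$region_type, .data$region) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
}
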