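#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reproducibility result
#'
#' Returns the reproducibility table as a plain tibble, one row per region,
#' in the column layout of the standard reporting tables (mean value, mean
#' difference, SD of difference, 95% limits, CoV%).
#'
#' @param x a `repro_result` from [paired_reproducibility()] or
#'   [cohort_reproducibility()].
#' @param ... unused.
#' @export
tidy.repro_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "repro_result")
  tibble::as_tibble(out)
}

#' One-row summary of a reproducibility result
#'
#' @param x a `repro_result`.
#' @param ... unused.
#' @return Tibble with the number of regions, subject count, mean absolute
#'   bias, largest SD of difference and the range of computable CoVs.
#' @export
glance.repro_result <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    n_subjects = max(x$n),
    mean_abs_bias = mean(abs(x$mean_diff), na.rm = TRUE),
    max_sd_diff = max(x$sd_diff, na.rm = TRUE),
    min_cov_pct = suppressWarnings(min(x$cov_pct, na.rm = TRUE)),
    max_cov_pct = suppressWarnings(max(x$cov_pct, na.rm = TRUE))
  )
}

#' Tidy Bland-Altman points
#'
#' @param x a `ba_points` object from [bland_altman_points()].
#' @param ... unused.
#' @return Tibble of `mean`, `diff` points with `bias`, `loa_low`,
#'   `loa_high` repeated as columns.
#' @export
tidy.ba_points <- function(x, ...) {
  tibble::tibble(mean = x$mean, diff = x$diff,
                 bias = attr(x, "bias"),
                 loa_low = attr(x, "loa_low"),
                 loa_high = attr(x, "loa_high"))
}
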