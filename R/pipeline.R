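#' Run the full single-study post-processing pipeline
#'
#' Executes reject -> co-register -> average -> log-linear tensor fit ->
#' eigensystem -> negative-eigenvalue repair -> FA/MD maps -> helix-angle
#' map -> slice/wall/layer labels -> regional means, either on a synthetic
#' phantom configuration (the acquisition is simulated first) or on a list
#' of input files read with [read_dwi()] and [read_geometry()].
#'
#' @param x a [phantom_config()], or a list of paths with elements `dwi`,
#'   `bval`, `bvec`, `geometry` (NIfTI label image) and `geometry_json`.
#' @param reject_threshold NCC rejection threshold; `NULL` skips rejection.
#' @param search_radius registration search radius in pixels; `NULL` or 0
#'   skips registration.
#' @param s0_floor b0 masking floor forwarded to [fit_tensor_loglinear()].
#' @return An object of class `cdti_study`: list holding the averaged
#'   series, the tensor and eigen fields, `fa`/`md`/`ha` scalar maps,
#'   `labels`, a long `region_means` tibble over all three metrics, and a
#'   `report` list (rejection table, registration table, repaired-eigenvalue
#'   count, masked-voxel count).
#' @examples
#' cfg <- phantom_config(grid_size = 32, noise_sigma = 0, shift_sd = 0,
#'                       corrupt_prob = 0, n_repetitions = 1)
#' study <- run_single_study(cfg, search_radius = 0)
#' dplyr::filter(study$region_means, region_type == "global")
#' @export
run_single_study <- function(x, reject_threshold = 0.9, search_radius = 10,
                             s0_floor = NULL) {
  if (inherits(x, "phantom_config")) {
    truth <- build_truth(x)
    series <- simulate_dwi(truth, gradient_scheme(default_directions(),
                                                  b_value = 350), x)
    geometry <- truth$geometry
  } else if (is.list(x) && !is.null(x$dwi)) {
    series <- read_dwi(x)
    geometry <- read_geometry(x$geometry, x$geometry_json)
  } else {
    stop("input error: x must be a phantom_config or a list of input paths",
         call. = FALSE)
  }

  rejection <- NULL
  if (!is.null(reject_threshold)) {
    rej <- reject_corrupted(series, threshold = reject_threshold)
    series <- rej$series
    rejection <- rej$report
  }
  registration <- NULL
  if (!is.null(search_radius) && search_radius > 0) {
    reg <- register_translation(series, search_radius = search_radius)
    series <- reg$series
    registration <- reg$result
  }
  averaged <- average_repetitions(series)

  tf <- fit_tensor_loglinear(averaged, s0_floor = s0_floor)
  eig <- eigendecompose(tf) |> repair_negative_eigenvalues()
  fa <- compute_fa(eig)
  md <- compute_md(eig)

  geometry <- transmural_depth(geometry)
  ha <- helix_angle_map(eig, geometry)
  labels <- region_labels(geometry)

  rm_tbl <- dplyr::bind_rows(
    region_means(fa, labels),
    region_means(md, labels),
    region_means(ha, labels)
  )
  structure(
    list(averaged = averaged, tensor = tf, eigen = eig,
         fa = fa, md = md, ha = ha, labels = labels, geometry = geometry,
         region_means = rm_tbl,
         report = list(
           rejection = rejection,
           registration = registration,
           n_repaired = attr(eig, "n_repaired"),
           n_masked_out = sum(!tf$mask)
         )),
    class = "cdti_study"
  )
}

#' @export
print.cdti_study <- function(x, ...) {
  g <- dplyr::filter(x$region_means, .data$region_type == "global")
  cat("<cdti_study>\n")
  for (i in seq_len(nrow(g)))
    cat(sprintf("  global %s: %.4g (%d voxels)\n",
                g$metric[i], g$value[i], g$n_voxels[i]))
  invisible(x)
}

#' Run a paired interstudy reproducibility analysis
#'
#' Runs [run_single_study()] on matched initial and repeat study inputs for
#' one or more subjects, pairs the regional summaries, and returns the
#' interstudy reproducibility tables (mean value, mean difference, SD of
#' difference, 95% limits of agreement, CoV) per metric.
#'
#' SD-based quantities need at least 2 subjects; with a single pair they
#' are returned as NA with a warning.
#'
#' @param x_initial,x_repeat a single study input (see [run_single_study()])
#'   or a list of them, one per subject, in matching order.
#' @param ... options forwarded to [run_single_study()].
#' @return List with `table` (a `repro_result` tibble with `metric` column)
#'   and `cohort` (the long per-subject regional means).
#' @export
run_reproducibility <- function(x_initial, x_repeat, ...) {
  as_cohort_list <- function(x) {
    if (inherits(x, "phantom_config") || (is.list(x) && !is.null(x$dwi))) list(x)
    else x
  }
  li <- as_cohort_list(x_initial)
  lr <- as_cohort_list(x_repeat)
  if (length(li) != length(lr))
    stop("pairing error: unequal numbers of initial and repeat studies",
         call. = FALSE)
  if (length(li) < 2)
    warning("single subject pair: SD of difference, limits of agreement and CoV are undefined (NA)")
  rows <- vector("list", 2L * length(li))
  k <- 0L
  for (j in seq_along(li)) {
    for (sc in 1:2) {
      study <- run_single_study(if (sc == 1) li[[j]] else lr[[j]], ...)
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(
        tibble::tibble(subject = j, scan = c("initial", "repeat")[sc]),
        study$region_means
      )
    }
  }
  cohort <- dplyr::bind_rows(rows)
  list(table = cohort_reproducibility(cohort), cohort = cohort)
}
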