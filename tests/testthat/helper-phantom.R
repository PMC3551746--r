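# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small clean phantom: no noise, no shifts, no corruption, one repetition
clean_config <- function(grid_size = 32, ...) {
  phantom_config(grid_size = grid_size, noise_sigma = 0, shift_sd = 0,
                 corrupt_prob = 0, n_repetitions = 1, seed = 1L, ...)
}

clean_truth <- function() fixture("clean_truth", function() build_truth(clean_config()))

clean_series <- function() fixture("clean_series", function() {
  simulate_dwi(clean_truth(), config = clean_config())
})

clean_study <- function() fixture("clean_study", function() {
  run_single_study(clean_config(), search_radius = 0)
})

# independent 3x3 FA/MD evaluation, used as the formula oracle
fa_md_direct <- function(lambda) {
  md <- mean(lambda)
  fa <- sqrt(1.5) * sqrt(sum((lambda - md)^2)) / sqrt(sum(lambda^2))
  c(fa = fa, md = md)
}

# rotation matrix about an arbitrary axis
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

tensor6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

mat_to_tensor6 <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])

# single-voxel eigen field wrapper for unit tests of map formulas
eigen_field_from_values <- function(lambda_list) {
  nv <- length(lambda_list)
  values <- array(NA_real_, c(nv, 1, 1, 3))
  vectors <- array(NA_real_, c(nv, 1, 1, 3, 3))
  for (i in seq_len(nv)) {
    values[i, 1, 1, ] <- lambda_list[[i]]
    vectors[i, 1, 1, , ] <- diag(3)
  }
  structure(list(values = values, vectors = vectors,
                 mask = array(TRUE, c(nv, 1, 1)),
                 repaired = array(FALSE, c(nv, 1, 1, 3)),
                 pixel_spacing = 1),
            class = "eigen_field")
}
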