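# Shared fixtures: small grids and cohorts built in code.

conf_names <- paste0("conf_", sprintf("%02d", 1:10))
default_confounders <- c(conf_names, "sex")
default_continuous <- c(conf_names, "no2", "nox", "pm25")

small_grid <- function(n = 8, cell = 1000) {
  grid_spec(n_cols = n, n_rows = n, cell_size = cell)
}

# minimal snapped cohort with iid standard-normal covariates
tiny_cohort <- function(n, grid, seed = 1, n_conf = 2) {
  withr::with_seed(seed, {
    centres <- cell_centres(grid)
    cells <- sample.int(nrow(centres), n, replace = TRUE)
    covs <- matrix(rnorm(n * (n_conf + 2)), n)
    colnames(covs) <- c(paste0("z", seq_len(n_conf)), "cog", "pol")
    dplyr::bind_cols(
      tibble::tibble(id = sprintf("p%04d", seq_len(n)),
                     easting = centres$easting[cells],
                     northing = centres$northing[cells]),
      tibble::as_tibble(covs)
    )
  })
}

# residual stack of N independent fields smoothed to a known FWHM (cells),
# for smoothness-estimator checks; anisotropy supported
smoothed_residual_stack <- function(n, grid, fwhm_x, fwhm_y = fwhm_x,
                                    seed = 1) {
  op_r <- spatcog:::smoothing_operator(grid$n_rows,
                                       fwhm_y / sqrt(8 * log(2)))
  op_c <- spatcog:::smoothing_operator(grid$n_cols,
                                       fwhm_x / sqrt(8 * log(2)))
  withr::with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      z <- matrix(rnorm(op_r$n_in * op_c$n_in), op_r$n_in)
      field <- op_r$s %*% z %*% t(op_c$s)
      as.vector(t(field)) # linear cell order (row-major)
    }, numeric(n_cells(grid))))
  })
}
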