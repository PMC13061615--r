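# Robustness suite: kernel-size sweep, expanded and translated analysis
# windows, and the non-mover subcohort, each compared to the base analysis
# by mask overlap on the intersection of the windows.

#' Plan for the sensitivity suite
#'
#' Defaults follow the production analysis: kernel containment diameters
#' from 1.25 km to 10 km in 1.25 km steps, an expanded window adding a 5 km
#' buffer in each cardinal direction, a translation of 8 km north and east,
#' and the non-mover subcohort.
#'
#' @param kernel_sizes Ascending positive containment diameters, metres.
#' @param expand_buffer Buffer added on each side of the window, metres
#'   (must be a multiple of the cell size); `NULL` to skip.
#' @param translate Numeric `c(east, north)` shift in metres (multiples of
#'   the cell size); `NULL` to skip.
#' @param non_mover Include the non-mover subcohort variant? Default TRUE.
#' @return An object of class `sensitivity_plan`.
#' @export
sensitivity_plan <- function(kernel_sizes = seq(1250, 10000, by = 1250),
                             expand_buffer = 5000,
                             translate = c(8000, 8000),
                             non_mover = TRUE) {
  if (length(kernel_sizes) > 0) {
    if (any(kernel_sizes <= 0) || is.unsorted(kernel_sizes, strictly = TRUE)) {
      abort("`kernel_sizes` must be positive and strictly ascending.")
    }
  }
  structure(
    list(kernel_sizes = kernel_sizes, expand_buffer = expand_buffer,
         translate = translate, non_mover = non_mover),
    class = "sensitivity_plan"
  )
}

#' Restrict a cohort to participants who never moved
#'
#' @param data Cohort data frame with a logical `non_mover` column.
#' @return The filtered tibble; the reduction fraction is reported.
#' @export
non_mover_filter <- function(data) {
  if (!"non_mover" %in% names(data)) {
    abort("Column `non_mover` is absent from the cohort table.")
  }
  out <- as_tibble(data[as.logical(data$non_mover), , drop = FALSE])
  inform(sprintf("non_mover_filter: retained %d of %d participants (%.1f%% removed).",
                 nrow(out), nrow(data),
                 100 * (1 - nrow(out) / max(nrow(data), 1))))
  out
}

# Dice on the window intersection; empty-vs-empty counts as 1, empty-vs-
# nonempty as 0
mask_dice <- function(mask_a, grid_a, mask_b, grid_b) {
  ix <- grid_intersection(grid_a, grid_b)
  a <- mask_a[ix$cells_a]
  b <- mask_b[ix$cells_b]
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

shift_grid <- function(grid, de, dn) {
  grid_spec(grid$origin_easting + de, grid$origin_northing + dn,
            grid$cell_size, grid$n_cols, grid$n_rows)
}

expand_grid_window <- function(grid, buffer) {
  k <- round(buffer / grid$cell_size)
  grid_spec(grid$origin_easting - k * grid$cell_size,
            grid$origin_northing - k * grid$cell_size,
            grid$cell_size, grid$n_cols + 2L * k, grid$n_rows + 2L * k)
}

cohort_in_window <- function(data, grid) {
  hi_e <- grid$origin_easting + grid$n_cols * grid$cell_size
  hi_n <- grid$origin_northing + grid$n_rows * grid$cell_size
  keep <- data$easting >= grid$origin_easting & data$easting < hi_e &
    data$northing >= grid$origin_northing & data$northing < hi_n
  data[keep, , drop = FALSE]
}

#' Run the sensitivity suite
#'
#' Re-runs the full spatial analysis under each variant of the plan — one run
#' per kernel size, the expanded window, the translated window, and the
#' non-mover subcohort — and compares each variant's significance mask with
#' the base mask by the Dice coefficient on the intersection of the analysis
#' windows. A variant whose cohort is empty (or whose fit fails) is skipped
#' with a log entry rather than aborting the suite.
#'
#' @inheritParams fit_spatial_interaction
#' @param plan A [sensitivity_plan()].
#' @param keep_fits Keep each variant's full fit in an attribute? Default
#'   FALSE.
#' @return A tibble with one row per variant (including the base run):
#'   `variant`, `kernel_diameter`, `n`, `n_regions`, `n_sig_cells`,
#'   `dice_vs_base`, `status`. The base fit is attached as attribute
#'   `base_fit`.
#' @export
run_sensitivity_suite <- function(data, grid, cognition, pollution,
                                  confounders,
                                  kernel = kernel_spec(),
                                  alpha = 0.05,
                                  min_participants = 10,
                                  connectivity = 8,
                                  plan = sensitivity_plan(),
                                  keep_fits = FALSE) {
  stopifnot(inherits(plan, "sensitivity_plan"))
  fit_args <- function(d, g, k) {
    fit_spatial_interaction(d, g, cognition, pollution, confounders,
                            kernel = k, alpha = alpha,
                            min_participants = min_participants,
                            connectivity = connectivity)
  }
  base_fit <- fit_args(data, grid, kernel)

  variants <- list(list(id = "base", data = data, grid = grid,
                        kernel = kernel))
  for (sz in plan$kernel_sizes) {
    variants <- c(variants, list(list(
      id = sprintf("kernel_%gm", sz), data = data, grid = grid,
      kernel = kernel_spec(kernel$containment_fraction, sz)
    )))
  }
  if (!is.null(plan$expand_buffer)) {
    g2 <- expand_grid_window(grid, plan$expand_buffer)
    variants <- c(variants, list(list(
      id = "expanded_window", data = cohort_in_window(data, g2), grid = g2,
      kernel = kernel
    )))
  }
  if (!is.null(plan$translate)) {
    g3 <- shift_grid(grid, plan$translate[1], plan$translate[2])
    variants <- c(variants, list(list(
      id = "translated_window", data = cohort_in_window(data, g3), grid = g3,
      kernel = kernel
    )))
  }
  if (isTRUE(plan$non_mover)) {
    variants <- c(variants, list(list(
      id = "non_mover", data = non_mover_filter(data), grid = grid,
      kernel = kernel
    )))
  }

  fits <- list()
  rows <- purrr::map_dfr(variants, function(v) {
    if (nrow(v$data) == 0) {
      inform(sprintf("sensitivity: variant '%s' skipped (empty cohort).", v$id))
      return(tibble(variant = v$id,
                    kernel_diameter = v$kernel$containment_diameter,
                    n = 0L, n_regions = NA_integer_,
                    n_sig_cells = NA_integer_, dice_vs_base = NA_real_,
                    status = "skipped"))
    }
    fit <- if (v$id == "base") base_fit else {
      tryCatch(fit_args(v$data, v$grid, v$kernel), error = function(e) e)
    }
    if (inherits(fit, "error")) {
      inform(sprintf("sensitivity: variant '%s' skipped (%s).", v$id,
                     conditionMessage(fit)))
      return(tibble(variant = v$id,
                    kernel_diameter = v$kernel$containment_diameter,
                    n = nrow(v$data), n_regions = NA_integer_,
                    n_sig_cells = NA_integer_, dice_vs_base = NA_real_,
                    status = "skipped"))
    }
    if (keep_fits) fits[[v$id]] <<- fit
    tibble(
      variant = v$id,
      kernel_diameter = v$kernel$containment_diameter,
      n = nrow(v$data),
      n_regions = nrow(fit$regions),
      n_sig_cells = sum(fit$mask),
      dice_vs_base = mask_dice(fit$mask, v$grid, base_fit$mask, grid),
      status = "ok"
    )
  })
  attr(rows, "base_fit") <- base_fit
  if (keep_fits) attr(rows, "fits") <- fits
  rows
}
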