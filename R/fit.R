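#' Fit the spatial interaction model for one cognition-pollution pair
#'
#' The full spatial analysis for one model: builds the sample-concentration
#' response stack, the shared design with interaction terms, fits the
#' voxelwise OLS, forms t-maps for the cognition-by-pollution interaction and
#' the two individual effects, estimates residual smoothness, derives the
#' voxel-level family-wise error threshold, and extracts classified
#' significant regions.
#'
#' Variables are used as-is: run [preprocess_cohort()] first so that
#' continuous covariates are standardized and outcome times ORQ-normalized.
#'
#' @param data Prepared cohort data frame (snapped coordinates, standardized
#'   covariates).
#' @param grid A [grid_spec()].
#' @param cognition,pollution,confounders Column names defining the design.
#' @param kernel A [kernel_spec()]. Default: 95% containment in 5 km.
#' @param alpha Family-wise error level. Default 0.05 (two-tailed).
#' @param min_participants Region filter. Default 10.
#' @param connectivity Region adjacency, 4 or 8. Default 8.
#' @param smoothness `"residuals"` (estimate from the residual stack,
#'   default) or `"kernel"` (analytic value implied by the smoothing kernel).
#' @param threshold_method Passed to [fwe_threshold()].
#' @return An object of class `spatcog_fit`: coefficient maps for the three
#'   effects of interest, the interaction `stat_map`, smoothness, threshold,
#'   significance mask and region tibble, plus model metadata. Methods:
#'   [tidy.spatcog_fit()], [glance.spatcog_fit()], [autoplot.spatcog_fit()].
#' @examples
#' \donttest{
#' g <- grid_spec(n_cols = 12, n_rows = 12)
#' sim <- generate_cohort(g, n = 800, seed = 1)
#' coh <- preprocess_cohort(sim$cohort,
#'   continuous = c(paste0("conf_", sprintf("%02d", 1:10)),
#'                  "no2", "nox", "pm25"),
#'   cognition = c("reaction_time", "completion_time"))
#' fit <- fit_spatial_interaction(coh, g,
#'   cognition = "reaction_time", pollution = "no2",
#'   confounders = c(paste0("conf_", sprintf("%02d", 1:10)), "sex"))
#' glance(fit)
#' }
#' @export
fit_spatial_interaction <- function(data, grid, cognition, pollution,
                                    confounders,
                                    kernel = kernel_spec(),
                                    alpha = 0.05,
                                    min_participants = 10,
                                    connectivity = 8,
                                    smoothness = c("residuals", "kernel"),
                                    threshold_method = "min-of-both") {
  smoothness <- match.arg(smoothness)
  response <- build_response_stack(data, grid, kernel)
  design <- build_design(data, confounders, cognition, pollution)
  coeffs <- fit_voxelwise_glm(response, design)
  tmap <- contrast_tmap(coeffs, attr(design, "interaction"))
  smooth <- if (smoothness == "residuals") {
    estimate_smoothness(coeffs$residuals, grid, coeffs$df)
  } else {
    kernel_smoothness(kernel, grid, coeffs$df)
  }
  thr <- fwe_threshold(smooth, coeffs$df, alpha = alpha, two_tailed = TRUE,
                       method = threshold_method)
  mask <- threshold_map(tmap, thr)
  regions <- significant_regions(mask, coeffs, data, grid,
                                 min_participants = min_participants,
                                 connectivity = connectivity)
  da <- coeffs$design_attrs
  keep_maps <- coeffs$beta[c(da$interaction, da$cognition, da$pollution), ,
                           drop = FALSE]
  structure(
    list(
      grid = grid,
      kernel = kernel,
      cognition = cognition,
      pollution = pollution,
      confounders = confounders,
      n = nrow(data),
      p = ncol(design),
      df = coeffs$df,
      beta = coeffs$beta,
      effect_maps = keep_maps,
      sigma2 = coeffs$sigma2,
      tmap = tmap,
      smoothness = smooth,
      threshold = thr,
      mask = mask,
      regions = regions,
      min_participants = min_participants,
      connectivity = connectivity
    ),
    class = "spatcog_fit"
  )
}

#' @export
print.spatcog_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<spatcog_fit> %s x %s: n = %d, P = %d, df = %d\n",
           "  FWHM (%.2f, %.2f) cells, t* = %.3f (%s), ",
           "%d significant cell(s) in %d region(s)\n"),
    x$cognition, x$pollution, x$n, x$p, x$df,
    x$smoothness$fwhm_x, x$smoothness$fwhm_y,
    x$threshold$t_star, x$threshold$method,
    sum(x$mask), nrow(x$regions)
  ))
  if (nrow(x$regions) > 0) {
    print(x$regions[, c("region_id", "n_cells", "n_participants",
                        "classification")])
  }
  invisible(x)
}

#' Tidy method for a spatial interaction fit
#'
#' @param x A `spatcog_fit`.
#' @param ... Unused.
#' @return The region tibble: one row per retained significant region with
#'   counts, coefficient summaries and sign classification.
#' @export
tidy.spatcog_fit <- function(x, ...) {
  x$regions
}

#' Glance method for a spatial interaction fit
#'
#' @param x A `spatcog_fit`.
#' @param ... Unused.
#' @return A one-row tibble with model size, smoothness, resel counts, the
#'   family-wise threshold and region counts.
#' @export
glance.spatcog_fit <- function(x, ...) {
  tibble(
    cognition = x$cognition,
    pollution = x$pollution,
    n = x$n,
    p = x$p,
    df = x$df,
    fwhm_x = x$smoothness$fwhm_x,
    fwhm_y = x$smoothness$fwhm_y,
    resels_r2 = unname(x$smoothness$resels["r2"]),
    alpha = x$threshold$alpha,
    t_star = x$threshold$t_star,
    threshold_method = x$threshold$method,
    n_sig_cells = sum(x$mask),
    n_regions = nrow(x$regions)
  )
}
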