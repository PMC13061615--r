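# Voxel-level family-wise error correction via Gaussian random field theory.
#
# P(max |t| over the map exceeds u) is approximated by the expected Euler
# characteristic of the excursion set, a weighted sum of Euler characteristic
# densities of the t-field with weights given by the search region's resel
# counts. The smoothness (FWHM) entering the resel counts is estimated from
# the spatial roughness of the standardized model residuals, in the
# statistical parametric mapping tradition.

#' Estimate field smoothness from model residuals
#'
#' Normalizes the residual stack to unit sum of squares per cell, measures
#' the mean squared forward difference of the normalized residuals along each
#' grid axis (an estimate of the variance of the field's spatial derivative),
#' and converts to per-axis FWHM via `fwhm = sqrt(4 log 2 / lambda)` (cell
#' units). Resel counts for the full rectangular search region follow:
#' `R0 = 1`, `R1 = n_cols/fwhm_x + n_rows/fwhm_y`,
#' `R2 = n_cells/(fwhm_x * fwhm_y)`.
#'
#' @param residuals N x C residual matrix (e.g. from [fit_voxelwise_glm()]).
#' @param grid The [grid_spec()] the cells live on.
#' @param df Residual degrees of freedom of the model.
#' @return An object of class `smoothness_estimate`: `fwhm_x`, `fwhm_y`
#'   (cells), `resels` (named numeric `r0`, `r1`, `r2`), `n_cells`, `df`.
#' @export
estimate_smoothness <- function(residuals, grid, df) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(residuals) < 3) abort("Need at least 3 residual rows.")
  ss <- colSums(residuals^2)
  valid <- ss > 0
  if (!any(valid)) {
    abort("Constant residual field: zero roughness everywhere.")
  }
  rn <- residuals
  rn[, valid] <- sweep(residuals[, valid, drop = FALSE], 2,
                       sqrt(ss[valid]), "/")
  nc <- grid$n_cols
  nr <- grid$n_rows
  idx <- matrix(seq_len(nc * nr), nrow = nr, ncol = nc, byrow = TRUE)
  # forward differences along x (within rows) and y (within columns),
  # averaged over pairs where both cells carry residual variation (cells
  # beyond the kernel support are identically zero and carry no roughness
  # information)
  x_a <- as.vector(idx[, -nc])
  x_b <- as.vector(idx[, -1])
  y_a <- as.vector(idx[-nr, ])
  y_b <- as.vector(idx[-1, ])
  x_ok <- valid[x_a] & valid[x_b]
  y_ok <- valid[y_a] & valid[y_b]
  if (!any(x_ok) || !any(y_ok)) {
    abort("Too few varying cells to estimate smoothness.")
  }
  x_a <- x_a[x_ok]; x_b <- x_b[x_ok]
  y_a <- y_a[y_ok]; y_b <- y_b[y_ok]
  lambda_x <- mean(colSums((rn[, x_b, drop = FALSE] - rn[, x_a, drop = FALSE])^2))
  lambda_y <- mean(colSums((rn[, y_b, drop = FALSE] - rn[, y_a, drop = FALSE])^2))
  if (lambda_x <= 0 || lambda_y <= 0) {
    abort("Zero spatial roughness; smoothness cannot be estimated.")
  }
  fwhm_x <- sqrt(4 * log(2) / lambda_x)
  fwhm_y <- sqrt(4 * log(2) / lambda_y)
  new_smoothness(fwhm_x, fwhm_y, grid, df)
}

#' Analytic smoothness implied by the smoothing kernel
#'
#' Cross-check mode for [estimate_smoothness()]: when smoothing is imposed by
#' construction, the field FWHM equals `2.3548 sigma / cell_size` on both
#' axes.
#'
#' @param kernel A [kernel_spec()].
#' @inheritParams estimate_smoothness
#' @return A `smoothness_estimate`.
#' @export
kernel_smoothness <- function(kernel, grid, df) {
  stopifnot(inherits(kernel, "kernel_spec"), inherits(grid, "grid_spec"))
  fwhm <- sqrt(8 * log(2)) * kernel$sigma / grid$cell_size
  new_smoothness(fwhm, fwhm, grid, df)
}

new_smoothness <- function(fwhm_x, fwhm_y, grid, df) {
  nc <- grid$n_cols
  nr <- grid$n_rows
  structure(
    list(
      fwhm_x = fwhm_x,
      fwhm_y = fwhm_y,
      resels = c(r0 = 1,
                 r1 = nc / fwhm_x + nr / fwhm_y,
                 r2 = nc * nr / (fwhm_x * fwhm_y)),
      n_cells = nc * nr,
      df = df
    ),
    class = "smoothness_estimate"
  )
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf(
    "<smoothness_estimate> FWHM (%.2f, %.2f) cells; resels R0=%.3g R1=%.3g R2=%.3g\n",
    x$fwhm_x, x$fwhm_y, x$resels["r0"], x$resels["r1"], x$resels["r2"]
  ))
  invisible(x)
}

#' Euler characteristic densities of a t-field
#'
#' The d-dimensional EC densities of a Student-t random field in resel units:
#' order 0 is the upper-tail t probability; orders 1 and 2 are the standard
#' closed forms
#' \deqn{\rho_1(t) = \frac{\sqrt{4\log 2}}{2\pi}\,(1 + t^2/\nu)^{-(\nu-1)/2}}
#' \deqn{\rho_2(t) = \frac{4\log 2}{(2\pi)^{3/2}}
#'   \frac{\Gamma((\nu+1)/2)}{\sqrt{\nu/2}\,\Gamma(\nu/2)}\,
#'   t\,(1 + t^2/\nu)^{-(\nu-1)/2}}
#'
#' @param t Threshold value(s).
#' @param df Degrees of freedom (>= 1).
#' @param order EC density order, one of 0, 1, 2.
#' @return Numeric vector of density values.
#' @export
ec_density_t <- function(t, df, order) {
  if (df < 1) abort("`df` must be >= 1.")
  if (!order %in% c(0, 1, 2)) abort("`order` must be 0, 1 or 2.")
  base <- (1 + t^2 / df)^(-(df - 1) / 2)
  switch(as.character(order),
    "0" = pt(t, df, lower.tail = FALSE),
    "1" = sqrt(4 * log(2)) / (2 * pi) * base,
    "2" = (4 * log(2)) / (2 * pi)^1.5 *
      exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2) * t * base
  )
}

#' Expected Euler characteristic of the excursion set above t
#'
#' @param t Threshold value(s).
#' @param df Degrees of freedom.
#' @param resels Named resel counts `c(r0=, r1=, r2=)` (see
#'   [estimate_smoothness()]).
#' @return `sum_d R_d rho_d(t)`, the random-field approximation to
#'   `P(max t-field > t)` at high thresholds.
#' @export
expected_ec <- function(t, df, resels) {
  resels[["r0"]] * ec_density_t(t, df, 0) +
    resels[["r1"]] * ec_density_t(t, df, 1) +
    resels[["r2"]] * ec_density_t(t, df, 2)
}

#' Family-wise error threshold for a t-map
#'
#' Solves `E[EC](t) = alpha_tail` for t by bisection-based root finding
#' (tolerance 1e-8), where `alpha_tail = alpha/2` for a two-tailed test
#' applied to |t| by symmetry. The returned threshold is by default the
#' smaller of the random-field solution and the Bonferroni t-quantile over
#' the number of cells: Bonferroni protects against random-field blow-up at
#' low smoothness, and the random-field solution takes over once spatial
#' correlation makes Bonferroni needlessly strict.
#'
#' @param smooth A `smoothness_estimate`.
#' @param df Degrees of freedom.
#' @param alpha Family-wise error level, in (0, 1). Default 0.05.
#' @param two_tailed Apply the threshold to |t|? Default TRUE.
#' @param method `"min-of-both"` (default), `"rft"` or `"bonferroni"`.
#' @return An object of class `fwe_threshold`: `t_star`, `t_rft`, `t_bonf`,
#'   `method` (which rule produced `t_star`), `alpha`, `two_tailed`, `df`.
#' @export
fwe_threshold <- function(smooth, df, alpha = 0.05, two_tailed = TRUE,
                          method = c("min-of-both", "rft", "bonferroni")) {
  stopifnot(inherits(smooth, "smoothness_estimate"))
  method <- match.arg(method)
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  alpha_tail <- if (two_tailed) alpha / 2 else alpha
  f <- function(t) expected_ec(t, df, smooth$resels) - alpha_tail
  if (f(100) > 0) abort("No root in (0, 100): search region too large for this alpha.")
  t_rft <- if (f(1e-8) <= 0) 1e-8 else {
    uniroot(f, c(1e-8, 100), tol = 1e-8)$root
  }
  t_bonf <- qt(alpha_tail / smooth$n_cells, df, lower.tail = FALSE)
  t_star <- switch(method,
    "min-of-both" = min(t_rft, t_bonf),
    "rft" = t_rft,
    "bonferroni" = t_bonf
  )
  used <- switch(method,
    "min-of-both" = if (t_rft <= t_bonf) "rft" else "bonferroni",
    method
  )
  structure(
    list(alpha = alpha, two_tailed = two_tailed, t_star = t_star,
         t_rft = t_rft, t_bonf = t_bonf, method = used, df = df,
         smooth = smooth),
    class = "fwe_threshold"
  )
}

#' @export
print.fwe_threshold <- function(x, ...) {
  cat(sprintf(
    "<fwe_threshold> t* = %.4f (%s; rft %.4f, bonferroni %.4f), %s alpha = %g, df = %d\n",
    x$t_star, x$method, x$t_rft, x$t_bonf,
    if (x$two_tailed) "two-tailed" else "one-tailed", x$alpha, x$df
  ))
  invisible(x)
}

#' Threshold a t-map at the family-wise error level
#'
#' @param stat A [contrast_tmap()] result.
#' @param thr A [fwe_threshold()].
#' @return Logical vector, one entry per cell: `|t| >= t_star` (two-tailed)
#'   or `t >= t_star` (one-tailed). The boundary case `t == t_star` is
#'   included. Degenerate cells are always FALSE.
#' @export
threshold_map <- function(stat, thr) {
  stopifnot(inherits(stat, "stat_map"), inherits(thr, "fwe_threshold"))
  t <- if (thr$two_tailed) abs(stat$t) else stat$t
  mask <- t >= thr$t_star & !stat$degenerate
  mask
}
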