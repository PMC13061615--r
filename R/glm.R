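# Mass-univariate OLS: one regression per grid cell, shared design.
# The design is factorized once (QR); coefficients, residual variances and
# t-statistics at all cells follow from matrix operations against the stack.

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares of the local response on the global design at every
#' grid cell: `beta(v) = (X'X)^-1 X' y(v)` with residual variance
#' `sigma2(v) = RSS(v) / (N - P)`. The QR factorization of the shared design
#' is computed once and reused across cells.
#'
#' @param response A [build_response_stack()] result (N x C matrix).
#' @param design A [build_design()] matrix (N x P).
#' @return An object of class `coefficient_maps`: list with `beta` (P x C),
#'   `sigma2` (length C), `df` (N - P), `residuals` (N x C, kept for
#'   smoothness estimation), `xtx_inv`, `design_attrs`, `grid`.
#' @export
fit_voxelwise_glm <- function(response, design) {
  x <- unclass(design)
  y <- unclass(response)
  n <- nrow(x)
  p <- ncol(x)
  if (nrow(y) != n) abort("Response and design disagree on N.")
  if (n <= p) abort(sprintf("Need N > P (got N = %d, P = %d).", n, p))
  qr_x <- qr(x)
  if (qr_x$rank < p) abort("Design matrix is singular.")
  beta <- qr.coef(qr_x, y)
  resid <- qr.resid(qr_x, y)
  rss <- colSums(resid^2)
  r_inv <- backsolve(qr.R(qr_x), diag(p))
  xtx_inv <- tcrossprod(r_inv)
  # undo any QR pivoting so rows follow design column order
  piv <- qr_x$pivot
  xtx_inv[piv, piv] <- xtx_inv
  dimnames(xtx_inv) <- list(colnames(x), colnames(x))
  rownames(beta) <- colnames(x)
  structure(
    list(
      beta = beta,
      sigma2 = pmax(rss, 0) / (n - p),
      df = n - p,
      residuals = resid,
      xtx_inv = xtx_inv,
      design_attrs = attributes(design)[c("roles", "cognition", "pollution",
                                          "interaction")],
      grid = attr(response, "grid")
    ),
    class = "coefficient_maps"
  )
}

#' @export
print.coefficient_maps <- function(x, ...) {
  cat(sprintf("<coefficient_maps> %d coefficients x %d cells, df = %d\n",
              nrow(x$beta), ncol(x$beta), x$df))
  invisible(x)
}

#' t-statistic map for one design column
#'
#' `t(v) = beta_j(v) / sqrt(sigma2(v) * [(X'X)^-1]_jj)` at every cell. Cells
#' with zero residual variance are degenerate: their t is set to 0 and
#' flagged rather than returned as NaN/Inf.
#'
#' @param coeffs A [fit_voxelwise_glm()] result.
#' @param column Name of a non-intercept design column.
#' @return An object of class `stat_map`: list with `t` (length C), `df`,
#'   `column`, `degenerate` (logical per cell), `grid`.
#' @export
contrast_tmap <- function(coeffs, column) {
  stopifnot(inherits(coeffs, "coefficient_maps"))
  if (!column %in% rownames(coeffs$beta)) {
    abort(sprintf("Unknown design column '%s'.", column))
  }
  if (column == "(Intercept)") abort("Contrast on the intercept is not supported.")
  cjj <- coeffs$xtx_inv[column, column]
  se <- sqrt(coeffs$sigma2 * cjj)
  degenerate <- !(se > 0)
  t <- ifelse(degenerate, 0, coeffs$beta[column, ] / se)
  structure(
    list(t = as.numeric(t), df = coeffs$df, column = column,
         degenerate = degenerate, grid = coeffs$grid),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> '%s': %d cells, df = %d, range [%.3g, %.3g]\n",
              x$column, length(x$t), x$df, min(x$t), max(x$t)))
  invisible(x)
}

#' Tidy a t-statistic map into one row per cell
#'
#' @param x A `stat_map`.
#' @param ... Unused.
#' @return A tibble with cell coordinates, `t` and the `degenerate` flag.
#' @export
tidy.stat_map <- function(x, ...) {
  out <- map_tibble(x$t, x$grid, name = "t")
  out$degenerate <- x$degenerate
  out
}
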