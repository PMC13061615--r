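#' Build the shared design matrix with interaction terms
#'
#' Assembles the global predictor matrix of the mass-univariate model:
#' an intercept, the confounders, the exposure (pollution) covariate, the
#' cognition covariate, and one interaction column for the product of the
#' cognition covariate with every other non-intercept covariate (each
#' confounder, then the exposure). Variables are expected to arrive already
#' standardized or ORQ-normalized; interaction columns are raw elementwise
#' products of those columns and are deliberately not re-standardized, so
#' regional sign summaries read directly off the coefficients.
#'
#' @param data Prepared cohort data frame.
#' @param confounders Character vector of confounder column names.
#' @param cognition Name of the cognition column.
#' @param pollution Name of the exposure column.
#' @return A numeric N x P matrix of class `design_matrix` with attributes
#'   `roles` (named character: intercept/confounder/pollution/cognition/
#'   interaction), `cognition`, `pollution`, and `interaction` (the name of
#'   the cognition-by-pollution column).
#' @examples
#' d <- data.frame(a = rnorm(20), b = rnorm(20), cog = rnorm(20),
#'                 pol = rnorm(20))
#' dim(build_design(d, c("a", "b"), "cog", "pol")) # 20 x 8
#' @export
build_design <- function(data, confounders, cognition, pollution) {
  vars <- c(confounders, pollution, cognition)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("Columns not in `data`: ", toString(missing_vars)))
  }
  if (cognition %in% confounders || pollution %in% confounders ||
      cognition == pollution) {
    abort("`cognition`, `pollution` and `confounders` must name distinct columns.")
  }
  n <- nrow(data)
  base <- vapply(vars, function(v) as.numeric(data[[v]]), numeric(n))
  cog <- base[, cognition]
  partners <- c(confounders, pollution)
  inter <- base[, partners, drop = FALSE] * cog
  colnames(inter) <- paste0(cognition, ":", partners)
  x <- cbind(`(Intercept)` = rep(1, n), base, inter)

  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 toString(dropped)))
  }
  roles <- c("intercept",
             rep("confounder", length(confounders)),
             "pollution", "cognition",
             rep("interaction", ncol(inter)))
  names(roles) <- colnames(x)
  structure(x,
            roles = roles,
            cognition = cognition,
            pollution = pollution,
            interaction = paste0(cognition, ":", pollution),
            class = c("design_matrix", "matrix", "array"))
}
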