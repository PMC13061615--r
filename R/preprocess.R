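#' Remove rows with extreme or missing values
#'
#' Cohort exclusion step: drops participants whose value on any of the named
#' continuous variables lies strictly below the lower or strictly above the
#' upper percentile of that variable (percentiles computed once, on the input
#' table), and drops all rows with any missing value. Percentiles use linear
#' interpolation between order statistics (`stats::quantile()` type 7); the
#' convention is fixed for reproducibility.
#'
#' Re-running on its own output recomputes percentiles and may trim further;
#' only the single-pass contract is guaranteed.
#'
#' @param data A cohort data frame.
#' @param variables Character vector of continuous column names to trim on.
#' @param lower,upper Percentile bounds, defaults 1 and 99.
#' @return The filtered tibble, with attributes `n_removed_extreme` and
#'   `n_removed_missing` recording how many rows each rule removed.
#' @export
trim_extremes <- function(data, variables, lower = 1, upper = 99) {
  stopifnot(is.data.frame(data))
  if (!(lower >= 0 && lower < upper && upper <= 100)) {
    abort("Need 0 <= lower < upper <= 100.")
  }
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("Variables not in `data`: ", toString(missing_vars)))
  }
  complete <- complete.cases(data)
  keep <- complete
  for (v in variables) {
    x <- data[[v]]
    qs <- quantile(x, probs = c(lower, upper) / 100, na.rm = TRUE,
                   names = FALSE, type = 7)
    keep <- keep & !is.na(x) & x >= qs[1] & x <= qs[2]
  }
  n_missing <- sum(!complete)
  n_extreme <- sum(complete & !keep)
  out <- as_tibble(data[keep, , drop = FALSE])
  if (nrow(out) == 0) {
    abort("No rows left after trimming; bounds are over-aggressive for these data.")
  }
  inform(sprintf(
    "trim_extremes: removed %d row(s) with missing values and %d extreme row(s); %d retained.",
    n_missing, n_extreme, nrow(out)
  ))
  attr(out, "n_removed_missing") <- n_missing
  attr(out, "n_removed_extreme") <- n_extreme
  out
}

#' Standardize a numeric vector
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (denominator
#' n - 1).
#'
#' @param x Numeric vector, length >= 2.
#' @param name Optional variable name used in error messages.
#' @return The standardized vector.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2) abort(sprintf("`%s`: need at least 2 values.", name))
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("`%s` has zero variance and cannot be standardized.", name))
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Ordered quantile (rank-based inverse normal) normalization
#'
#' Maps values to standard-normal quantiles of their offset ranks,
#' `qnorm((rank - 0.5) / n)`, with average ranks for ties. Rank order is
#' preserved; an all-tied input maps to all zeros (the midrank quantile)
#' rather than failing. `NA`s are kept in place and excluded from `n`.
#'
#' @param x Numeric vector, length >= 2.
#' @return The normalized vector.
#' @examples
#' orq_normalize(c(3, 1, 2))
#' @export
orq_normalize <- function(x) {
  if (length(x) < 2) abort("Need at least 2 values.")
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) abort("Need at least 2 non-missing values.")
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / n)
  out
}

#' Prepare cohort variables for analysis
#'
#' The full variable-preparation step: trims extreme and missing rows on the
#' named continuous variables and the raw outcome times (binary covariates
#' are never trimmed), then standardizes the continuous covariates to
#' (mean 0, sd 1) and maps the outcome times through ordered quantile
#' normalization. Standardization is computed on the trimmed cohort.
#'
#' @param data Cohort data frame.
#' @param continuous Character vector of continuous covariate columns to trim
#'   and standardize (binaries should be left out).
#' @param cognition Character vector of outcome-time columns to trim and
#'   ORQ-normalize.
#' @param lower,upper Trimming percentiles, defaults 1 and 99.
#' @return The prepared tibble.
#' @export
preprocess_cohort <- function(data, continuous, cognition,
                              lower = 1, upper = 99) {
  out <- trim_extremes(data, c(continuous, cognition), lower, upper)
  for (v in continuous) out[[v]] <- standardize(out[[v]], name = v)
  for (v in cognition) out[[v]] <- orq_normalize(out[[v]])
  out
}
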