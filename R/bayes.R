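# Non-spatial comparator: Bayesian multiple regression with a ridge prior,
# fitted by Gibbs sampling (compiled core in src/gibbs_ridge.cpp). The
# summary table mirrors the conventional report format: posterior mean, sd,
# equal-tailed 95% CI, t statistic (mean/sd), rank of |t| within the model,
# effective sample size, model R-squared, and the two-tier sign flags.

#' Markov chain configuration for the ridge sampler
#'
#' Desk-scale defaults keep a validation run fast; `paper_chain_config()`
#' returns the heavyweight configuration (100,000 burn-in, 20,000 retained,
#' then a further 100,000 thinned by 5) used for production tables.
#'
#' @param n_samples Draws retained directly after burn-in.
#' @param n_burnin Initial draws discarded.
#' @param thinning_pool Additional draws of which every `thin_by`-th is
#'   retained. Default 0 (disabled).
#' @param thin_by Thinning factor for the pool. Default 5.
#' @param seed Optional integer seed.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_samples = 4000, n_burnin = 2000,
                         thinning_pool = 0, thin_by = 5, seed = NULL) {
  stopifnot(n_samples >= 1, n_burnin >= 0, thinning_pool >= 0, thin_by >= 1)
  structure(
    list(n_samples = as.integer(n_samples), n_burnin = as.integer(n_burnin),
         thinning_pool = as.integer(thinning_pool),
         thin_by = as.integer(thin_by), seed = seed),
    class = "chain_config"
  )
}

#' @rdname chain_config
#' @export
paper_chain_config <- function(seed = NULL) {
  chain_config(n_samples = 20000, n_burnin = 100000,
               thinning_pool = 100000, thin_by = 5, seed = seed)
}

#' Fit a Bayesian ridge regression by Gibbs sampling
#'
#' Fits `y = alpha + X beta + eps` with `eps ~ N(0, sigma2)`,
#' `beta | sigma2, tau2 ~ N(0, sigma2 tau2 I)`, a Jeffreys prior on `sigma2`
#' and a half-Cauchy prior on `tau` (inverse-gamma scale mixture), using full
#' conditional updates in the order (beta, sigma2, tau2, mixing variable).
#' The intercept is unpenalized. Predictors should arrive standardized or
#' ORQ-normalized.
#'
#' @param data Data frame.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns (no interactions).
#' @param config A [chain_config()].
#' @param tau2 `NULL` to sample the global shrinkage scale (default), or a
#'   fixed positive value (e.g. a very large one, in which case the posterior
#'   mean approaches OLS).
#' @return An object of class `spatcog_ridge`: `$summary` (the per-predictor
#'   tibble, see [rank_and_flags()]), `$r2`, `$draws` (list of retained
#'   draws), `$config`. Methods: `tidy()`, `glance()`, `autoplot()`.
#' @export
bayes_ridge <- function(data, response, predictors,
                        config = chain_config(), tau2 = NULL) {
  stopifnot(inherits(config, "chain_config"))
  missing_vars <- setdiff(c(response, predictors), names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("Columns not in `data`: ", toString(missing_vars)))
  }
  y <- as.numeric(data[[response]])
  x <- vapply(predictors, function(v) as.numeric(data[[v]]),
              numeric(nrow(data)))
  if (anyNA(y) || anyNA(x)) abort("Missing values in model variables.")
  if (nrow(x) <= ncol(x) + 1) abort("Need N > P.")
  draws <- with_seed_if(config$seed, {
    gibbs_ridge_cpp(y, x, config$n_burnin, config$n_samples,
                    config$thinning_pool, config$thin_by,
                    if (is.null(tau2)) -1 else tau2)
  })
  colnames(draws$beta) <- predictors

  summ <- purrr::map_dfr(predictors, function(v) {
    ch <- draws$beta[, v]
    q <- quantile(ch, c(0.025, 0.25, 0.75, 0.975), names = FALSE)
    tibble(
      term = v,
      mean = mean(ch),
      std = sd(ch),
      ci_lower = q[1], ci_upper = q[4],
      q25 = q[2], q75 = q[3],
      t_stat = mean(ch) / sd(ch),
      ess = effective_sample_size(ch)
    )
  })
  summ$ess_per_100 <- 100 * summ$ess / length(draws$alpha)
  summ <- rank_and_flags(summ)
  beta_mean <- colMeans(draws$beta)
  r2 <- model_r2(y, x, beta_mean, alpha = mean(draws$alpha))
  structure(
    list(summary = summ, r2 = r2, draws = draws, config = config,
         response = response, predictors = predictors, n = length(y)),
    class = "spatcog_ridge"
  )
}

#' @export
print.spatcog_ridge <- function(x, ...) {
  cat(sprintf("<spatcog_ridge> %s ~ %d predictors, n = %d, R^2 = %.3f\n",
              x$response, length(x$predictors), x$n, x$r2))
  print(x$summary[, c("term", "mean", "std", "ci_lower", "ci_upper",
                      "t_stat", "rank", "ess", "flag")])
  invisible(x)
}

#' Effective sample size of an MCMC chain
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by
#' Geyer's initial monotone positive sequence rule (consecutive lag pairs are
#' summed, the sum stops at the first non-positive pair and is made
#' non-increasing). The estimate is capped at the chain length.
#'
#' @param chain Numeric vector, length >= 10.
#' @return Effective number of independent draws.
#' @export
effective_sample_size <- function(chain) {
  n <- length(chain)
  if (n < 10) abort("Chain too short (need length >= 10).")
  if (var(chain) == 0) abort("Constant chain: zero variance.")
  rho <- as.vector(acf(chain, lag.max = min(n - 2, 2000),
                       plot = FALSE, demean = TRUE)$acf)
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}, starting at lag 0
  n_pairs <- floor(length(rho) / 2)
  gam <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  pos <- which(gam <= 0)
  if (length(pos) > 0) gam <- gam[seq_len(pos[1] - 1)]
  if (length(gam) > 1) gam <- cummin(gam)
  tau <- max(-1 + 2 * sum(gam), 1e-8)
  min(n, n / tau)
}

#' Rank predictors and assign sign flags
#'
#' Completes a posterior summary table: `rank` is the 1-based descending rank
#' of |t| among the model's (non-intercept) predictors, ties broken by row
#' order; `flag` is `"**"` when the equal-tailed 95% interval excludes zero,
#' `"*"` when only the interquartile range does, and `""` otherwise.
#'
#' @param summary A tibble with columns `term`, `t_stat`, `ci_lower`,
#'   `ci_upper`, `q25`, `q75`.
#' @return The tibble with `rank` and `flag` columns added or replaced.
#' @export
rank_and_flags <- function(summary) {
  summary$rank <- rank(-abs(summary$t_stat), ties.method = "first")
  summary$flag <- dplyr::case_when(
    summary$ci_lower > 0 | summary$ci_upper < 0 ~ "**",
    summary$q25 > 0 | summary$q75 < 0 ~ "*",
    TRUE ~ ""
  )
  summary
}

#' Model R-squared at the posterior mean coefficients
#'
#' @param y Response vector.
#' @param x Predictor matrix.
#' @param beta Posterior mean coefficients (per predictor).
#' @param alpha Posterior mean intercept.
#' @return `1 - RSS/TSS` with predictions at the posterior means.
#' @export
model_r2 <- function(y, x, beta, alpha = 0) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("Zero total sum of squares.")
  rss <- sum((y - alpha - as.vector(x %*% beta))^2)
  1 - rss / tss
}

#' Tidy method for a ridge fit
#'
#' @param x A `spatcog_ridge`.
#' @param ... Unused.
#' @return The per-predictor posterior summary tibble.
#' @export
tidy.spatcog_ridge <- function(x, ...) {
  x$summary
}

#' Glance method for a ridge fit
#'
#' @param x A `spatcog_ridge`.
#' @param ... Unused.
#' @return One-row tibble: `n`, number of predictors, retained draws, `r2`,
#'   and the count of `"**"`-flagged predictors.
#' @export
glance.spatcog_ridge <- function(x, ...) {
  tibble(
    n = x$n,
    p = length(x$predictors),
    n_draws = length(x$draws$alpha),
    r2 = x$r2,
    n_flag_strong = sum(x$summary$flag == "**"),
    n_flag_weak = sum(x$summary$flag == "*")
  )
}
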