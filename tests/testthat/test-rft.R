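test_that("EC densities obey symmetry, tails and the closed forms", {
  for (df in c(10, 100, 1976)) {
    expect_equal(ec_density_t(0, df, 0), 0.5)
  }
  for (ord in 0:2) {
    expect_lt(ec_density_t(50, 100, ord), 1e-8)
  }
  # frozen values of an independent transcription at t = 3, df = 100
  expect_equal(ec_density_t(3, 100, 0), 0.00170395767166042,
               tolerance = 1e-10)
  expect_equal(ec_density_t(3, 100, 1), 0.00372092751392528,
               tolerance = 1e-10)
  expect_equal(ec_density_t(3, 100, 2), 0.00739672612151830,
               tolerance = 1e-10)
  # rho_0 equals the numerically integrated t tail
  dens <- function(x) dt(x, 100)
  tail_num <- integrate(dens, 3, Inf, rel.tol = 1e-12)$value
  expect_equal(ec_density_t(3, 100, 0), tail_num, tolerance = 1e-10)
  expect_error(ec_density_t(3, 100, 3), "order")
})

point_smoothness <- function(df, resels = c(r0 = 1, r1 = 0, r2 = 0),
                             n_cells = 1) {
  structure(list(fwhm_x = 1, fwhm_y = 1, resels = resels,
                 n_cells = n_cells, df = df),
            class = "smoothness_estimate")
}

test_that("a single-point search region reduces to the pointwise t test", {
  thr <- fwe_threshold(point_smoothness(175), df = 175, alpha = 0.05,
                       two_tailed = TRUE)
  expect_equal(thr$t_star, qt(0.975, 175), tolerance = 1e-6)
})

test_that("thresholds are monotone in search volume and alpha", {
  base <- fwe_threshold(point_smoothness(100, c(r0 = 1, r1 = 5, r2 = 50),
                                         n_cells = 500), 100,
                        method = "rft")
  bigger <- fwe_threshold(point_smoothness(100, c(r0 = 1, r1 = 5, r2 = 200),
                                           n_cells = 500), 100,
                          method = "rft")
  expect_gt(bigger$t_star, base$t_star)
  strict <- fwe_threshold(point_smoothness(100, c(r0 = 1, r1 = 5, r2 = 50),
                                           n_cells = 500), 100,
                          alpha = 0.01, method = "rft")
  expect_gt(strict$t_star, base$t_star)
  # min-of-both never exceeds either solution
  both <- fwe_threshold(point_smoothness(100, c(r0 = 1, r1 = 5, r2 = 50),
                                         n_cells = 500), 100)
  expect_lte(both$t_star, both$t_rft)
  expect_lte(both$t_star, both$t_bonf)
})

test_that("threshold t_star(alpha) is continuous and strictly decreasing", {
  sm <- point_smoothness(150, c(r0 = 1, r1 = 10, r2 = 100), n_cells = 676)
  alphas <- seq(0.01, 0.2, by = 0.01)
  ts <- vapply(alphas, function(a) {
    fwe_threshold(sm, 150, alpha = a, method = "rft")$t_star
  }, numeric(1))
  expect_true(all(diff(ts) < 0))
  expect_true(all(abs(diff(ts)) < 0.5)) # no jumps
})

test_that("masking uses |t| with an inclusive boundary and respects flags", {
  g <- small_grid(4)
  sm <- point_smoothness(100, n_cells = 16)
  thr <- fwe_threshold(sm, 100)
  t <- rep(0, 16)
  stat <- structure(list(t = t, df = 100, column = "x",
                         degenerate = rep(FALSE, 16), grid = g),
                    class = "stat_map")
  expect_equal(sum(threshold_map(stat, thr)), 0)
  t2 <- t
  t2[c(2, 5)] <- c(thr$t_star, -thr$t_star - 1) # boundary and negative tail
  t2[9] <- thr$t_star + 2
  stat2 <- stat; stat2$t <- t2
  expect_equal(which(threshold_map(stat2, thr)), c(2L, 5L, 9L))
  stat3 <- stat2; stat3$degenerate[2] <- TRUE
  expect_equal(which(threshold_map(stat3, thr)), c(5L, 9L))
})

test_that("unit-FWHM resels on the full grid equal the cell count", {
  g <- grid_spec() # 26 x 26
  k <- kernel_spec(1 - exp(-0.5), 2 * g$cell_size / sqrt(8 * log(2)))
  sm <- kernel_smoothness(k, g, df = 100) # fwhm exactly 1 cell
  expect_equal(unname(sm$resels["r2"]), 676, tolerance = 1e-10)
  expect_equal(unname(sm$resels["r0"]), 1)
})

test_that("residual smoothness recovers a known generating FWHM", {
  g <- grid_spec()
  res <- smoothed_residual_stack(200, g, fwhm_x = 2.4, seed = 11)
  sm <- estimate_smoothness(res, g, df = 197)
  expect_lt(abs(sm$fwhm_x - 2.4) / 2.4, 0.15)
  expect_lt(abs(sm$fwhm_y - 2.4) / 2.4, 0.15)
  # doubling the generating FWHM along one axis halves the resel area
  res2 <- smoothed_residual_stack(200, g, fwhm_x = 4.8, fwhm_y = 2.4,
                                  seed = 12)
  sm2 <- estimate_smoothness(res2, g, df = 197)
  ratio <- sm2$resels["r2"] / sm$resels["r2"]
  expect_lt(abs(ratio - 0.5) / 0.5, 0.2)
  expect_error(estimate_smoothness(matrix(1, 10, n_cells(g)), g, 7),
               "roughness")
})

test_that("analytic kernel smoothness matches the residual estimate", {
  # smoothing imposed by the response construction: the two smoothness
  # routes should broadly agree on a dense uniform cohort
  g <- grid_spec(n_cols = 14, n_rows = 14)
  k <- kernel_spec(0.95, 5000)
  d <- tiny_cohort(800, g, seed = 13)
  rs <- build_response_stack(d, g, k)
  design <- build_design(d, c("z1", "z2"), "cog", "pol")
  fit <- fit_voxelwise_glm(rs, design)
  sm_res <- estimate_smoothness(fit$residuals, g, fit$df)
  sm_kern <- kernel_smoothness(k, g, fit$df)
  expect_lt(abs(sm_res$fwhm_x - sm_kern$fwhm_x) / sm_kern$fwhm_x, 0.25)
})
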