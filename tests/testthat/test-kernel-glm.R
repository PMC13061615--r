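test_that("kernel sigma solves the Rayleigh containment rule", {
  # one-sigma containment of an isotropic 2-D Gaussian
  expect_equal(kernel_sigma(1 - exp(-0.5), 2), 1, tolerance = 1e-12)
  expect_equal(kernel_sigma(0.95, 5000), 1021.34745662998,
               tolerance = 1e-9)
  # independent 2-D quadrature oracle: the derived sigma really contains 95%
  s <- kernel_sigma(0.95, 5000)
  mass <- pracma::integral2(
    function(x, y) exp(-(x^2 + y^2) / (2 * s^2)) / (2 * pi * s^2),
    -2500, 2500,
    function(x) -sqrt(pmax(2500^2 - x^2, 0)),
    function(x) sqrt(pmax(2500^2 - x^2, 0))
  )$Q
  expect_equal(mass, 0.95, tolerance = 1e-4)
  # scale equivariance
  expect_equal(kernel_sigma(0.7, 8000), 2 * kernel_sigma(0.7, 4000))
  expect_error(kernel_sigma(1, 5000), "between 0 and 1")
  expect_error(kernel_sigma(0, 5000), "between 0 and 1")
})

test_that("numerical containment of the constructed kernel is 95%", {
  expect_equal(kernel_containment_pct(kernel_spec(), radius = 2500), 95,
               tolerance = 1e-3)
})

test_that("response rows peak at the home cell and share cells share rows", {
  g <- small_grid(8)
  cc <- cell_centres(g)
  cells <- c(12, 12, 40)
  d <- tibble::tibble(easting = cc$easting[cells],
                      northing = cc$northing[cells])
  rs <- build_response_stack(d, g, kernel_spec(0.95, 3000))
  expect_equal(unname(apply(rs, 1, which.max)), cells)
  expect_identical(rs[1, ], rs[2, ])
})

test_that("a central participant's discrete row mass is close to unit", {
  g <- grid_spec() # 26 x 26 km
  cc <- cell_centres(g)
  centre <- snap_to_grid(13000, 13000, g)$cell
  d <- tibble::tibble(easting = cc$easting[centre],
                      northing = cc$northing[centre])
  rs <- build_response_stack(d, g, kernel_spec()) # sigma ~ 1 km
  expect_gt(sum(rs[1, ]) * g$cell_size^2, 0.99)
  expect_lt(sum(rs[1, ]) * g$cell_size^2, 1.01)
})

test_that("degenerate smoothing triggers a warning", {
  g <- small_grid(4)
  cc <- cell_centres(g)
  d <- tibble::tibble(easting = cc$easting[1], northing = cc$northing[1])
  expect_warning(build_response_stack(d, g, kernel_spec(0.95, 150)),
                 "degenerate")
})

test_that("design matrix has the documented column structure", {
  withr::with_seed(1, {
    d <- tibble::as_tibble(matrix(rnorm(40 * 13), 40,
                                  dimnames = list(NULL, c(paste0("c", 1:11),
                                                          "cog", "pol"))))
  })
  x <- build_design(d, paste0("c", 1:11), "cog", "pol")
  expect_equal(ncol(x), 26) # 1 + 11 + 2 + 12
  expect_equal(unname(x[, 1]), rep(1, 40))
  expect_equal(unname(x[, "cog:pol"]), d$cog * d$pol)
  roles <- attr(x, "roles")
  expect_equal(sum(roles == "interaction"), 12)
  # zero cognition zeroes every interaction entry in that row
  d2 <- d; d2$cog[3] <- 0
  x2 <- build_design(d2, paste0("c", 1:11), "cog", "pol")
  expect_true(all(x2[3, roles == "interaction"] == 0))
  # permuting rows permutes the design identically
  perm <- sample(40)
  x3 <- build_design(d[perm, ], paste0("c", 1:11), "cog", "pol")
  strip <- function(m) matrix(m, nrow = nrow(m), dimnames = dimnames(m))
  expect_equal(strip(x3), strip(x)[perm, ])
})

test_that("collinear designs are rejected with the offending column named", {
  withr::with_seed(2, d <- tibble::tibble(a = rnorm(30), cog = rnorm(30),
                                          pol = rnorm(30)))
  d$b <- 2 * d$a
  expect_error(build_design(d, c("a", "b"), "cog", "pol"), "collinear")
  expect_error(build_design(d, c("a", "missing"), "cog", "pol"), "missing")
})

test_that("voxelwise OLS reproduces exact and degenerate cases", {
  g <- small_grid(4)
  d <- tiny_cohort(30, g, seed = 3)
  design <- build_design(d, c("z1", "z2"), "cog", "pol")
  # response constructed exactly as X b at every cell: perfect fit
  b <- matrix(rnorm(ncol(design) * n_cells(g)), ncol(design))
  y <- unclass(design) %*% b
  y[, 5] <- 0 # an identically zero cell
  fit <- fit_voxelwise_glm(structure(y, grid = g, class = "response_stack"),
                           design)
  b_expected <- b; b_expected[, 5] <- 0
  expect_equal(unname(fit$beta), b_expected, tolerance = 1e-8)
  expect_true(all(fit$sigma2 < 1e-16))
  expect_equal(fit$df, 30 - 8)
  expect_error(fit_voxelwise_glm(
    structure(y[1:8, ], grid = g, class = "response_stack"),
    design[1:8, ]),
    "N > P")
})

test_that("coefficients and t match the normal-equations oracle", {
  for (k in 1:5) {
    withr::with_seed(100 + k, {
      n <- 50; p <- 4
      x <- cbind(1, matrix(rnorm(n * (p - 1)), n))
      colnames(x) <- c("(Intercept)", "a", "b", "c")
      y <- matrix(rnorm(n), n, 1)
    })
    fit <- fit_voxelwise_glm(
      structure(y, grid = NULL, class = "response_stack"),
      structure(x, roles = c("(Intercept)" = "intercept", a = "confounder",
                             b = "cognition", c = "pollution"),
                class = c("design_matrix", "matrix", "array"))
    )
    xtx_inv <- solve(t(x) %*% x)
    beta_oracle <- xtx_inv %*% t(x) %*% y
    expect_equal(unname(fit$beta), unname(beta_oracle), tolerance = 1e-10)
    resid <- y - x %*% beta_oracle
    s2 <- sum(resid^2) / (n - p)
    t_oracle <- beta_oracle[3, 1] / sqrt(s2 * xtx_inv[3, 3])
    tm <- contrast_tmap(fit, "b")
    expect_equal(tm$t, unname(t_oracle), tolerance = 1e-10)
  }
})

test_that("t maps are invariant to per-cell rescaling of the response", {
  g <- small_grid(5)
  d <- tiny_cohort(60, g, seed = 4)
  rs <- build_response_stack(d, g, kernel_spec(0.95, 2500))
  design <- build_design(d, c("z1", "z2"), "cog", "pol")
  t1 <- contrast_tmap(fit_voxelwise_glm(rs, design), "cog:pol")$t
  rs2 <- unclass(rs); rs2[, 7] <- 7 * rs2[, 7]
  t2 <- contrast_tmap(fit_voxelwise_glm(
    structure(rs2, grid = g, class = "response_stack"), design), "cog:pol")$t
  expect_equal(t1, t2, tolerance = 1e-10)
  expect_error(contrast_tmap(fit_voxelwise_glm(rs, design), "nope"),
               "Unknown")
})

test_that("the response stack is translation-equivariant", {
  g1 <- small_grid(6)
  g2 <- grid_spec(50000, -20000, 1000, 6, 6)
  d1 <- tiny_cohort(25, g1, seed = 5)
  d2 <- d1
  d2$easting <- d1$easting + 50000
  d2$northing <- d1$northing - 20000
  k <- kernel_spec(0.95, 3000)
  expect_equal(as.vector(build_response_stack(d1, g1, k)),
               as.vector(build_response_stack(d2, g2, k)))
})

test_that("null-contrast t statistics follow the Student-t law", {
  g <- small_grid(8)
  k <- kernel_spec(0.95, 3000)
  km <- spatcog:::kernel_matrix(g, k)
  cell_probe <- 28
  tvals <- withr::with_seed(6, vapply(seq_len(500), function(r) {
    n <- 150
    cells <- sample.int(n_cells(g), n, replace = TRUE)
    d <- tibble::tibble(
      easting = cell_centres(g)$easting[cells],
      northing = cell_centres(g)$northing[cells],
      z1 = rnorm(n), z2 = rnorm(n), cog = rnorm(n), pol = rnorm(n)
    )
    design <- build_design(d, c("z1", "z2"), "cog", "pol")
    rs <- structure(km[cells, , drop = FALSE], grid = g,
                    class = "response_stack")
    fit <- fit_voxelwise_glm(rs, design)
    # the pollution main effect: an exact-t Gaussian null column
    contrast_tmap(fit, "pol")$t[cell_probe]
  }, numeric(1)))
  ks <- stats::ks.test(tvals, function(q) pt(q, df = 150 - 8))
  expect_gt(ks$p.value, 0.01)
})
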