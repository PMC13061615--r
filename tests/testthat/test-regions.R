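mask_on <- function(grid, cells) {
  m <- rep(FALSE, n_cells(grid))
  m[cells] <- TRUE
  m
}

test_that("diagonal adjacency distinguishes 4- from 8-connectivity", {
  g <- small_grid(5)
  # cells 1 (col 0,row 0) and 7 (col 1,row 1) touch only diagonally
  m <- mask_on(g, c(1, 7))
  expect_length(extract_regions(m, g, connectivity = 8), 1)
  expect_length(extract_regions(m, g, connectivity = 4), 2)
})

test_that("a full mask is one region and an empty mask none", {
  g <- small_grid(5)
  expect_equal(lengths(extract_regions(rep(TRUE, 25), g)), 25)
  expect_length(extract_regions(rep(FALSE, 25), g), 0)
})

test_that("an L-shaped blob and an isolated cell split correctly", {
  g <- small_grid(6)
  l_shape <- c(1, 2, 3, 7, 13) # row0: cols 0-2; col 0 of rows 1-2
  m <- mask_on(g, c(l_shape, 29)) # cell 29 isolated (col 4, row 4)
  regions <- extract_regions(m, g, connectivity = 4)
  expect_equal(sort(lengths(regions)), c(1, 5))
  expect_setequal(regions[[1]], l_shape)
})

test_that("components agree with an igraph flood-fill oracle", {
  g <- small_grid(10)
  for (conn in c(4, 8)) {
    for (rep in 1:10) {
      m <- withr::with_seed(200 + rep, runif(n_cells(g)) < 0.35)
      got <- extract_regions(m, g, connectivity = conn)
      cells <- which(m)
      col <- (cells - 1L) %% g$n_cols
      row <- (cells - 1L) %/% g$n_cols
      dx <- abs(outer(col, col, "-"))
      dy <- abs(outer(row, row, "-"))
      adj <- if (conn == 4) (dx + dy) == 1 else pmax(dx, dy) == 1
      gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(gr)$membership
      oracle <- unname(split(cells, comp))
      canon <- function(l) sort(vapply(l, function(x) {
        paste(sort(x), collapse = ",")
      }, character(1)))
      expect_equal(canon(got), canon(oracle))
    }
  }
})

test_that("participant counting is a direct membership count", {
  g <- small_grid(5)
  cc <- cell_centres(g)
  homes <- c(3, 3, 7, 12, 12, 12, 20, 25)
  d <- tibble::tibble(easting = cc$easting[homes],
                      northing = cc$northing[homes])
  expect_equal(count_participants(integer(0), d, g), 0)
  expect_equal(count_participants(c(3, 7), d, g), 3)
  expect_equal(count_participants(c(12,  20, 25), d, g), 5)
  expect_equal(count_participants(seq_len(25), d, g), 8)
})

test_that("sign-consistency classification reproduces the caption rules on all 27 sign patterns", {
  expected <- function(si, sc, sp) {
    if (si == 0 || sc == 0 || sp == 0) return("inconsistent")
    if (si > 0 && sc > 0 && sp > 0) return("consistent_rising")
    if (si > 0 && sc < 0 && sp < 0) return("consistent_falling")
    if (si < 0 && sc * sp < 0) return("crossed")
    "inconsistent"
  }
  cells <- 1:3
  for (si in -1:1) for (sc in -1:1) for (sp in -1:1) {
    out <- summarize_and_classify(cells,
                                  rep(si * 0.4, 3), rep(sc * 0.2, 3),
                                  rep(sp * 0.7, 3))
    expect_equal(out$classification, expected(si, sc, sp),
                 label = sprintf("signs (%d, %d, %d)", si, sc, sp))
    if (si == 0 || sc == 0 || sp == 0) expect_true(out$degenerate_sign)
  }
})

test_that("classification is invariant to positive rescaling of the maps", {
  withr::with_seed(21, {
    im <- rnorm(20); cm <- rnorm(20); pm <- rnorm(20)
  })
  cells <- c(2, 5, 9, 14)
  a <- summarize_and_classify(cells, im, cm, pm)
  b <- summarize_and_classify(cells, 7 * im, 0.01 * cm, 3 * pm)
  expect_equal(a$classification, b$classification)
})

test_that("region summaries are ordered quantiles of the region cells", {
  withr::with_seed(22, im <- rnorm(30))
  cells <- c(1, 4, 7, 8, 20)
  out <- summarize_and_classify(cells, im, im, im)
  expect_equal(out$interaction_min, min(im[cells]))
  expect_equal(out$interaction_median, median(im[cells]))
  expect_true(out$interaction_q25 <= out$interaction_median)
  expect_true(out$interaction_median <= out$interaction_q75)
  expect_equal(out$interaction_max, max(im[cells]))
})

test_that("the participant filter removes below-10 regions inclusively", {
  regions <- tibble::tibble(region_id = 1:3,
                            n_participants = c(9, 10, 250))
  kept <- filter_regions(regions)
  expect_equal(kept$region_id, c(2L, 3L))
  expect_equal(nrow(filter_regions(regions[0, ])), 0)
})

test_that("extracted regions partition the mask and carry definite signs", {
  g <- small_grid(7)
  d <- tiny_cohort(400, g, seed = 23)
  rs <- build_response_stack(d, g, kernel_spec(0.95, 2500))
  design <- build_design(d, c("z1", "z2"), "cog", "pol")
  coeffs <- fit_voxelwise_glm(rs, design)
  m <- withr::with_seed(24, runif(n_cells(g)) < 0.3)
  regions <- significant_regions(m, coeffs, d, g, min_participants = 0)
  all_cells <- sort(unlist(regions$cells))
  expect_equal(all_cells, which(m)) # union == mask, disjoint
  imap <- coeffs$beta[coeffs$design_attrs$interaction, ]
  for (i in seq_len(nrow(regions))) {
    signs <- sign(imap[regions$cells[[i]]])
    expect_lte(length(unique(signs)), 1)
  }
})
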