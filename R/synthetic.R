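# Synthetic urban cohorts with known ground truth.
#
# The generator emulates the structure the spatial analysis assumes: an
# uneven point cohort on a km-resolution grid, exposure covariates sharing a
# smooth-plus-ridges latent surface (the shape land-use-regression estimates
# take in cities), roughly a dozen correlated confounders, and outcome times
# linear in the covariates with an optional spatially localized
# exposure-by-outcome interaction planted in a known disk of cells.

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# distance from points to a segment c(x0, y0, x1, y1)
dist_to_segment <- function(px, py, seg) {
  dx <- seg[3] - seg[1]
  dy <- seg[4] - seg[2]
  len2 <- dx^2 + dy^2
  if (len2 == 0) {
    return(sqrt((px - seg[1])^2 + (py - seg[2])^2))
  }
  t <- pmin(1, pmax(0, ((px - seg[1]) * dx + (py - seg[2]) * dy) / len2))
  sqrt((px - seg[1] - t * dx)^2 + (py - seg[2] - t * dy)^2)
}

#' Generate a smooth spatial exposure field with road-like ridges
#'
#' Draws one value per grid cell as smoothed Gaussian noise (an isotropic
#' Gaussian-weighted average of per-cell white noise with length scale
#' `smooth_scale`) plus additive ridges that decay with squared distance to
#' the supplied line segments, then standardizes the surface to mean 0 and
#' sd 1 over cells.
#'
#' @param grid A [grid_spec()].
#' @param smooth_scale Length scale of the background smoothing, metres (> 0).
#' @param ridge_segments List of numeric vectors `c(x0, y0, x1, y1)` (metres):
#'   line segments along which ridge exposure is elevated.
#' @param ridge_width Gaussian decay scale of each ridge, metres.
#' @param ridge_amplitude Ridge height, in units of the (pre-standardization)
#'   background noise scale.
#' @param seed Optional integer seed; the ambient RNG state is restored.
#' @return A map tibble (see [map_tibble()]) with a `value` column; the
#'   pre-standardization surface is kept in attribute `raw`.
#' @export
make_spatial_field <- function(grid, smooth_scale = 4000,
                               ridge_segments = list(),
                               ridge_width = 1000, ridge_amplitude = 2,
                               seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(smooth_scale) || length(smooth_scale) != 1 ||
      !is.finite(smooth_scale) || smooth_scale <= 0) {
    abort("`smooth_scale` must be a single positive number.")
  }
  if (ridge_width <= 0) abort("`ridge_width` must be positive.")
  centres <- cell_centres(grid)
  raw <- with_seed_if(seed, {
    z <- rnorm(n_cells(grid))
    d2 <- outer(centres$easting, centres$easting, "-")^2 +
      outer(centres$northing, centres$northing, "-")^2
    w <- exp(-d2 / (2 * smooth_scale^2))
    smooth <- as.vector(w %*% z) / rowSums(w)
    for (seg in ridge_segments) {
      dd <- dist_to_segment(centres$easting, centres$northing, as.numeric(seg))
      smooth <- smooth + ridge_amplitude * exp(-dd^2 / (2 * ridge_width^2))
    }
    smooth
  })
  s <- sd(raw)
  value <- if (s > 0) (raw - mean(raw)) / s else rep(0, length(raw))
  out <- map_tibble(value, grid)
  attr(out, "raw") <- raw
  attr(out, "field_params") <- list(
    smooth_scale = smooth_scale, ridge_segments = ridge_segments,
    ridge_width = ridge_width, ridge_amplitude = ridge_amplitude
  )
  out
}

default_density_centres <- function(grid) {
  ext_x <- grid$n_cols * grid$cell_size
  ext_y <- grid$n_rows * grid$cell_size
  tibble(
    easting = grid$origin_easting + c(0.50, 0.30, 0.68, 0.75) * ext_x,
    northing = grid$origin_northing + c(0.50, 0.65, 0.30, 0.75) * ext_y,
    sd = c(0.13, 0.11, 0.11, 0.09) * (ext_x + ext_y) / 2,
    weight = c(0.35, 0.25, 0.22, 0.18)
  )
}

default_effect_sizes <- function() {
  c(conf_01 = 0.30, conf_02 = -0.20, conf_03 = 0.15, conf_04 = 0.10,
    conf_05 = -0.10, conf_06 = 0.08, conf_07 = -0.08, conf_08 = 0.05,
    conf_09 = -0.05, conf_10 = 0.05, sex = 0.10, no2 = 0.10)
}

default_pollution_field <- function(grid, ...) {
  cx <- grid$origin_easting + grid$n_cols * grid$cell_size / 2
  cy <- grid$origin_northing + grid$n_rows * grid$cell_size / 2
  ext <- grid$n_cols * grid$cell_size / 2
  make_spatial_field(
    grid,
    smooth_scale = 4000,
    ridge_segments = list(
      c(cx - ext, cy, cx + ext, cy),                 # east-west arterial
      c(cx - 0.7 * ext, cy - 0.7 * ext, cx + 0.7 * ext, cy + 0.7 * ext)
    ),
    ridge_width = 800, ridge_amplitude = 1.5, ...
  )
}

sample_mixture_locations <- function(n, centres, grid) {
  lo_e <- grid$origin_easting
  hi_e <- grid$origin_easting + grid$n_cols * grid$cell_size
  lo_n <- grid$origin_northing
  hi_n <- grid$origin_northing + grid$n_rows * grid$cell_size
  out_e <- numeric(0)
  out_n <- numeric(0)
  w <- centres$weight / sum(centres$weight)
  while (length(out_e) < n) {
    m <- max(2L * (n - length(out_e)), 100L)
    k <- sample.int(nrow(centres), m, replace = TRUE, prob = w)
    e <- rnorm(m, centres$easting[k], centres$sd[k])
    nn <- rnorm(m, centres$northing[k], centres$sd[k])
    ok <- e >= lo_e & e < hi_e & nn >= lo_n & nn < hi_n
    out_e <- c(out_e, e[ok])
    out_n <- c(out_n, nn[ok])
  }
  tibble(easting = out_e[seq_len(n)], northing = out_n[seq_len(n)])
}

#' Simulate a point cohort with a planted interaction effect
#'
#' Participants are drawn from a truncated Gaussian-mixture density over the
#' grid and snapped to cell centres. Ten continuous confounders share an
#' exchangeable correlation, a binary `sex` analogue is Bernoulli(0.5), and
#' three exposure covariates (`no2`, `nox`, `pm25`) combine one latent
#' spatial field with covariate-specific noise calibrated to a target mutual
#' correlation. Two outcome "times" are linear in the covariates on the
#' standardized latent scale, plus Gaussian noise, and — inside an optional
#' disk of cells — an extra `interaction_coef * exposure` term, the planted
#' effect the spatial analysis is meant to recover. Outcomes are mapped to a
#' positive time scale (`baseline + scale * latent`); the mapping is recorded
#' in the returned ground truth so tests can invert it exactly.
#'
#' @param grid A [grid_spec()].
#' @param n Number of participants.
#' @param density_centres Tibble with columns `easting`, `northing`, `sd`,
#'   `weight`; defaults to four unevenly weighted centres.
#' @param effect_sizes Named coefficients on the standardized latent scale
#'   for any of the covariate columns; see `spatcog:::default_effect_sizes()`.
#' @param interaction_disk `NULL`, or `list(easting=, northing=, radius=)` in
#'   metres: where the extra exposure term applies.
#' @param interaction_coef Size of the planted interaction, in outcome sd per
#'   exposure sd. Default 0.5.
#' @param noise_sd Residual sd of the outcome latents. Default 1.
#' @param pollution_field Optional map tibble from [make_spatial_field()];
#'   defaults to a smooth background with two road-like ridges crossing the
#'   grid centre.
#' @param pollution_cor Target mutual correlation of the three exposure
#'   covariates. Default 0.8.
#' @param confounder_cor Exchangeable correlation of the continuous
#'   confounders. Default 0.2.
#' @param movers_fraction Fraction of participants flagged as having moved
#'   (non_mover = FALSE). Default 0.25.
#' @param seed Optional integer seed; all randomness (including the default
#'   field) flows from it.
#' @return A list of class `synthetic_cohort`: `$cohort` (tibble with `id`,
#'   snapped `easting`/`northing`, covariates, `reaction_time`,
#'   `completion_time`, `non_mover`) and `$truth` (interaction mask, planted
#'   coefficients, outcome scale, field parameters, seed).
#' @export
generate_cohort <- function(grid, n = 17829,
                            density_centres = NULL,
                            effect_sizes = NULL,
                            interaction_disk = NULL,
                            interaction_coef = 0.5,
                            noise_sd = 1,
                            pollution_field = NULL,
                            pollution_cor = 0.8,
                            confounder_cor = 0.2,
                            movers_fraction = 0.25,
                            seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (n < 1) abort("`n` must be >= 1.")
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  density_centres <- density_centres %||% default_density_centres(grid)
  if (nrow(density_centres) == 0) abort("`density_centres` must be nonempty.")
  effect_sizes <- effect_sizes %||% default_effect_sizes()
  covariate_names <- c(paste0("conf_", sprintf("%02d", 1:10)), "sex",
                       "no2", "nox", "pm25")
  unknown <- setdiff(names(effect_sizes), covariate_names)
  if (length(unknown) > 0) {
    abort(paste0("Unknown effect_sizes entries: ", toString(unknown)))
  }

  with_seed_if(seed, {
    if (is.null(pollution_field)) {
      pollution_field <- default_pollution_field(grid)
    }
    loc <- sample_mixture_locations(n, density_centres, grid)
    snapped <- snap_to_grid(loc$easting, loc$northing, grid)
    centres <- cell_centres(grid)
    easting <- centres$easting[snapped$cell]
    northing <- centres$northing[snapped$cell]

    # confounders: exchangeable correlation through a shared factor
    g <- rnorm(n)
    conf <- sqrt(confounder_cor) * g +
      sqrt(1 - confounder_cor) * matrix(rnorm(n * 10), n, 10)
    colnames(conf) <- paste0("conf_", sprintf("%02d", 1:10))
    sex <- rbinom(n, 1, 0.5)

    # exposures: shared latent field at the home cell + covariate noise
    f <- pollution_field$value[snapped$cell]
    sd_f <- sd(f)
    noise_scale <- if (sd_f > 0) sd_f * sqrt(1 / pollution_cor - 1) else {
      sqrt(1 / pollution_cor - 1)
    }
    pol <- f + noise_scale * matrix(rnorm(n * 3), n, 3)
    colnames(pol) <- c("no2", "nox", "pm25")

    x <- cbind(conf, sex = sex, pol)
    eta_fixed <- as.vector(x[, names(effect_sizes), drop = FALSE] %*%
                             effect_sizes)

    in_disk_cell <- rep(FALSE, n_cells(grid))
    in_disk <- rep(FALSE, n)
    if (!is.null(interaction_disk)) {
      d_cell <- sqrt((centres$easting - interaction_disk$easting)^2 +
                       (centres$northing - interaction_disk$northing)^2)
      in_disk_cell <- d_cell <= interaction_disk$radius
      in_disk <- in_disk_cell[snapped$cell]
      pol_std <- (pol[, 1] - mean(pol[, 1])) / sd(pol[, 1])
      eta_fixed <- eta_fixed + interaction_coef * pol_std * in_disk
    }

    baseline <- c(reaction_time = 550, completion_time = 350)
    scale <- c(reaction_time = 100, completion_time = 70)
    eta_rt <- eta_fixed + rnorm(n, sd = noise_sd)
    eta_ct <- eta_fixed + rnorm(n, sd = noise_sd)
    cohort <- tibble(
      id = sprintf("p%06d", seq_len(n)),
      easting = easting,
      northing = northing,
      as_tibble(x),
      reaction_time = baseline[1] + scale[1] * eta_rt,
      completion_time = baseline[2] + scale[2] * eta_ct,
      non_mover = runif(n) >= movers_fraction
    )
    occupied <- tabulate(snapped$cell, nbins = n_cells(grid)) > 0
    truth <- list(
      interaction_mask = in_disk_cell,
      occupied_mask = occupied,
      interaction_disk = interaction_disk,
      effect_sizes = effect_sizes,
      interaction_coef = interaction_coef,
      interaction_exposure = "no2",
      noise_sd = noise_sd,
      outcome_baseline = baseline,
      outcome_scale = scale,
      field_params = attr(pollution_field, "field_params"),
      seed = seed
    )
    structure(list(cohort = cohort, truth = truth, grid = grid),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> n = %d on a %d x %d grid; planted interaction: %s\n",
    nrow(x$cohort), x$grid$n_cols, x$grid$n_rows,
    if (any(x$truth$interaction_mask)) {
      sprintf("%d cells, coef %.3g", sum(x$truth$interaction_mask),
              x$truth$interaction_coef)
    } else "none"
  ))
  invisible(x)
}

#' Overlap between a true and a detected cell mask
#'
#' Set-overlap metrics for recovery checks: Dice `2|A&B|/(|A|+|B|)`, Jaccard
#' `|A&B|/|A|B|`, and a hit flag (any overlap at all). Two empty masks count
#' as perfect agreement (Dice and Jaccard 1) but not a hit.
#'
#' @param truth_mask,detected_mask Logical vectors of equal length (or a
#'   `synthetic_cohort` truth's `interaction_mask`).
#' @return A one-row tibble: `n_truth`, `n_detected`, `n_overlap`, `dice`,
#'   `jaccard`, `hit`.
#' @export
overlap_report <- function(truth_mask, detected_mask) {
  if (is.list(truth_mask) && !is.null(truth_mask$interaction_mask)) {
    truth_mask <- truth_mask$interaction_mask
  }
  if (length(truth_mask) != length(detected_mask)) {
    abort("Masks must have identical dimensions.")
  }
  a <- as.logical(truth_mask)
  b <- as.logical(detected_mask)
  inter <- sum(a & b)
  uni <- sum(a | b)
  tibble(
    n_truth = sum(a),
    n_detected = sum(b),
    n_overlap = inter,
    dice = if (sum(a) + sum(b) == 0) 1 else 2 * inter / (sum(a) + sum(b)),
    jaccard = if (uni == 0) 1 else inter / uni,
    hit = inter > 0
  )
}
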