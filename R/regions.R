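# Significant-region interpretation: connected components of the
# suprathreshold mask, participant filtering, per-region coefficient
# summaries and the four-way sign-consistency classification.

#' Connected components of a significance mask
#'
#' Maximal connected components of the TRUE cells under 4- or 8-adjacency,
#' numbered in raster-scan order of their first cell (row 0 first, west to
#' east).
#'
#' @param mask Logical vector, one entry per cell of `grid`.
#' @param grid A [grid_spec()].
#' @param connectivity 4 or 8 (default 8, the planar analogue of common
#'   practice in statistical parametric mapping).
#' @return A list of integer vectors of cell ids; empty list for an empty
#'   mask.
#' @export
extract_regions <- function(mask, grid, connectivity = 8) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(mask) != n_cells(grid)) {
    abort("`mask` length must equal the grid's cell count.")
  }
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  mask <- as.logical(mask)
  nc <- grid$n_cols
  nr <- grid$n_rows
  offsets <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  }
  labels <- integer(length(mask))
  regions <- list()
  # raster-scan order: ascending cell id visits row 0 first, west to east
  for (start in which(mask)) {
    if (labels[start] != 0) next
    id <- length(regions) + 1L
    queue <- start
    labels[start] <- id
    members <- integer(0)
    while (length(queue) > 0) {
      cell <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      members <- c(members, cell)
      col <- (cell - 1L) %% nc
      row <- (cell - 1L) %/% nc
      ncol_ <- col + offsets[, 1]
      nrow_ <- row + offsets[, 2]
      ok <- ncol_ >= 0 & ncol_ < nc & nrow_ >= 0 & nrow_ < nr
      nb <- nrow_[ok] * nc + ncol_[ok] + 1L
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- id
      queue <- c(queue, nb)
    }
    regions[[id]] <- sort(members)
  }
  regions
}

#' Count participants whose home cell lies in a cell set
#'
#' @param cells Integer vector of cell ids.
#' @param data Cohort data frame with grid-snapped coordinates.
#' @param grid A [grid_spec()].
#' @return Number of participants in the cell set.
#' @export
count_participants <- function(cells, data, grid) {
  sum(home_cells(data, grid) %in% cells)
}

region_quantiles <- function(values, cells, prefix) {
  q <- quantile(values[cells], probs = c(0, 0.25, 0.5, 0.75, 1),
                names = FALSE, type = 7)
  stats::setNames(as.list(q), paste0(prefix, c("_min", "_q25", "_median",
                                               "_q75", "_max")))
}

#' Summarize and classify a significant region
#'
#' Computes the (min, q25, median, q75, max) of the interaction, cognition
#' and pollution coefficient maps over the region's cells, determines the
#' sign of each effect from its median, and classifies:
#' positive interaction with both individual effects positive is
#' `consistent_rising` (e.g. above-average exposure co-occurring with longer
#' response times); positive interaction with both individual effects
#' negative is `consistent_falling`; negative interaction with individual
#' effects of opposite signs is `crossed`; every other combination is
#' `inconsistent`. A median within 1e-12 of zero is treated as sign-degenerate
#' and classified `inconsistent`.
#'
#' @param cells Integer vector of cell ids (nonempty).
#' @param interaction_map,cognition_map,pollution_map Numeric per-cell
#'   coefficient maps of equal length.
#' @return A one-row tibble with the 15 summary columns, `classification`,
#'   and a `degenerate_sign` flag.
#' @export
summarize_and_classify <- function(cells, interaction_map, cognition_map,
                                   pollution_map) {
  if (length(cells) == 0) abort("`cells` must be nonempty.")
  if (length(cognition_map) != length(interaction_map) ||
      length(pollution_map) != length(interaction_map)) {
    abort("Coefficient maps must share dimensions.")
  }
  s <- c(
    region_quantiles(interaction_map, cells, "interaction"),
    region_quantiles(cognition_map, cells, "cognition"),
    region_quantiles(pollution_map, cells, "pollution")
  )
  med <- c(s$interaction_median, s$cognition_median, s$pollution_median)
  degenerate <- any(abs(med) < 1e-12)
  cls <- if (degenerate) {
    "inconsistent"
  } else {
    si <- sign(med[1]); sc <- sign(med[2]); sp <- sign(med[3])
    if (si > 0 && sc > 0 && sp > 0) {
      "consistent_rising"
    } else if (si > 0 && sc < 0 && sp < 0) {
      "consistent_falling"
    } else if (si < 0 && sc * sp < 0) {
      "crossed"
    } else {
      "inconsistent"
    }
  }
  dplyr::bind_cols(
    as_tibble(s),
    tibble(classification = cls, degenerate_sign = degenerate)
  )
}

#' Drop regions with too few participants
#'
#' @param regions A region tibble (e.g. from [significant_regions()]) with a
#'   `n_participants` column.
#' @param min_participants Minimum cohort size for a region to be reported.
#'   Default 10; a region with exactly 10 participants is retained.
#' @return The filtered tibble; the pre-filter numbering is preserved in
#'   `region_id`.
#' @export
filter_regions <- function(regions, min_participants = 10) {
  regions[regions$n_participants >= min_participants, , drop = FALSE]
}

#' Extract, summarize and filter significant regions
#'
#' Full region pipeline on a thresholded interaction map: connected
#' components, participant counts, coefficient summaries and sign
#' classification, then the minimum-participant filter.
#'
#' With a two-tailed threshold the suprathreshold set contains positive and
#' negative interaction cells; components are labelled separately within
#' each sign's excursion set (`split_by_sign`, default TRUE), so every
#' reported region carries a definite interaction sign and adjacent
#' opposite-signed excursions are not merged into one uninterpretable blob.
#'
#' @param mask Logical significance mask (per cell).
#' @param coeffs A [fit_voxelwise_glm()] result whose design carries the
#'   interaction, cognition and pollution columns.
#' @param data The cohort table.
#' @param grid A [grid_spec()].
#' @param min_participants Participant filter; default 10.
#' @param connectivity 4 or 8; default 8.
#' @param split_by_sign Label components separately within the positive and
#'   negative interaction excursions? Default TRUE.
#' @return A tibble with one row per retained region: `region_id` (raster
#'   order over all regions, before filtering), `n_cells`,
#'   `n_participants`, the 15 coefficient summaries, `classification`, and a
#'   `cells` list-column of cell ids.
#' @export
significant_regions <- function(mask, coeffs, data, grid,
                                min_participants = 10, connectivity = 8,
                                split_by_sign = TRUE) {
  stopifnot(inherits(coeffs, "coefficient_maps"))
  da <- coeffs$design_attrs
  interaction_map <- coeffs$beta[da$interaction, ]
  cognition_map <- coeffs$beta[da$cognition, ]
  pollution_map <- coeffs$beta[da$pollution, ]
  comps <- if (split_by_sign) {
    pos <- extract_regions(mask & interaction_map > 0, grid, connectivity)
    neg <- extract_regions(mask & interaction_map <= 0, grid, connectivity)
    all <- c(pos, neg)
    # renumber in raster-scan order of each component's first cell
    all[order(vapply(all, min, integer(1)))]
  } else {
    extract_regions(mask, grid, connectivity)
  }
  if (length(comps) == 0) {
    return(tibble(
      region_id = integer(0), n_cells = integer(0),
      n_participants = integer(0),
      classification = character(0), cells = list()
    ))
  }
  rows <- purrr::imap(comps, function(cells, i) {
    dplyr::bind_cols(
      tibble(region_id = i, n_cells = length(cells),
             n_participants = count_participants(cells, data, grid)),
      summarize_and_classify(cells, interaction_map, cognition_map,
                             pollution_map),
      tibble(cells = list(cells))
    )
  })
  filter_regions(dplyr::bind_rows(rows), min_participants)
}

#' Re-classify sub-components of a region at 4-connectivity
#'
#' Diagnostic for regions whose aggregate signs are inconsistent: a single
#' 8-connected region can straddle adjacent sub-regions whose individual
#' effects are each internally consistent. This splits a region into its
#' 4-connected sub-components and classifies each in isolation.
#'
#' @param cells Integer vector of cell ids of one region.
#' @inheritParams significant_regions
#' @return A region tibble with one row per 4-connected sub-component (no
#'   participant filter applied).
#' @export
subregion_diagnostic <- function(cells, coeffs, data, grid) {
  mask <- rep(FALSE, n_cells(grid))
  mask[cells] <- TRUE
  significant_regions(mask, coeffs, data, grid,
                      min_participants = 0, connectivity = 4)
}
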