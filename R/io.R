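# On-disk formats and the end-to-end pipeline driver. Everything is plain
# text: cohort tables as CSV, per-cell maps as ESRI ASCII grids, region
# outlines as GeoJSON (grid coordinates), and reports as JSON.

#' Read a cohort table from CSV
#'
#' Name-based parsing: column order is irrelevant. Requires `id`, `easting`
#' and `northing`; coordinate columns must parse as numbers (an error names
#' the first offending row), other columns are typed by content and missing
#' values are preserved for the preprocessing step to decide about.
#'
#' @param path Path to the CSV file.
#' @param required Columns that must be present.
#' @return A tibble.
#' @export
read_cohort_csv <- function(path, required = c("id", "easting", "northing")) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ", toString(missing_cols)))
  }
  for (v in intersect(c("easting", "northing"), names(out))) {
    if (!is.numeric(out[[v]])) {
      parsed <- suppressWarnings(as.numeric(out[[v]]))
      bad <- which(is.na(parsed) & !is.na(out[[v]]))
      if (length(bad) > 0) {
        abort(sprintf("Non-numeric value in column '%s' at data row %d: '%s'",
                      v, bad[1], out[[v]][bad[1]]))
      }
      out[[v]] <- parsed
    }
  }
  out
}

#' Write a cohort table to CSV
#'
#' @param data Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write a per-cell map as an ESRI ASCII grid
#'
#' Plain-text raster aligned to the grid: `ncols`/`nrows` header,
#' `xllcorner`/`yllcorner` at the grid origin, and values in north-up row
#' order (the file's first row is the grid's northernmost row). Values are
#' printed with 17 significant digits so a write/read cycle is bit-exact;
#' `NA`/`NaN` cells are stored as the nodata value.
#'
#' @param values Numeric vector, one entry per cell in linear cell order.
#' @param grid A [grid_spec()].
#' @param path Output path.
#' @param na_value Nodata sentinel. Default -9999.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, na_value = -9999) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) != n_cells(grid)) {
    abort("`values` length must equal the grid's cell count.")
  }
  m <- map_matrix(as.numeric(values), grid)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE] # north-up
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.17g", grid$origin_easting),
    sprintf("yllcorner %.17g", grid$origin_northing),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", na_value)
  )
  body <- apply(m, 1, function(r) {
    r[!is.finite(r)] <- na_value
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path written by [write_ascii_grid()] (or any ESRI ASCII grid
#'   with an `xllcorner`/`yllcorner` header).
#' @return A list with `values` (linear cell order, nodata as `NA`) and
#'   `grid` (a [grid_spec()]).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  grid <- grid_spec(header$xllcorner, header$yllcorner, header$cellsize,
                    header$ncols, header$nrows)
  m <- do.call(rbind, lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (!is.null(header$nodata_value)) {
    m[m == header$nodata_value] <- NA_real_
  }
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE] # back to south-first rows
  list(values = as.vector(t(m)), grid = grid)
}

# cell polygon (closed ring, counter-clockwise) for GeoJSON output
cell_ring <- function(cell, grid) {
  col <- (cell - 1L) %% grid$n_cols
  row <- (cell - 1L) %/% grid$n_cols
  x0 <- grid$origin_easting + col * grid$cell_size
  y0 <- grid$origin_northing + row * grid$cell_size
  s <- grid$cell_size
  list(list(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s),
            c(x0, y0)))
}

#' Write region outlines as GeoJSON
#'
#' One MultiPolygon feature per region (each cell as a square ring, planar
#' grid coordinates, no CRS member), with the region's id, counts and
#' classification as properties.
#'
#' @param regions A region tibble from [significant_regions()] (needs the
#'   `cells` list-column).
#' @param grid A [grid_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, grid, path) {
  features <- purrr::pmap(
    list(regions$region_id, regions$cells, regions$n_cells,
         regions$n_participants, regions$classification),
    function(id, cells, nc, np, cls) {
      list(
        type = "Feature",
        properties = list(region_id = id, n_cells = nc, n_participants = np,
                          classification = cls),
        geometry = list(
          type = "MultiPolygon",
          coordinates = lapply(cells, cell_ring, grid = grid)
        )
      )
    }
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# stable short hash of a configuration list (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline and write artifacts
#'
#' For every cognition-pollution combination in the configuration (six per
#' city in the production setting: two outcome times by three pollutants),
#' preprocesses the cohort, fits the spatial interaction model, fits the
#' non-spatial ridge comparator, and writes: coefficient and t-map ASCII
#' grids, the threshold report (JSON), the region report (JSON + GeoJSON),
#' the comparator summary (CSV), and a structured run log (JSON) recording
#' cohort sizes after each filter, df, smoothness, resels and the threshold.
#' Every artifact records the configuration hash and seed; identical config
#' and seed reproduce byte-identical reports.
#'
#' @param data Cohort data frame (raw scale), or a path to a cohort CSV.
#' @param config A list with elements `grid` ([grid_spec()] or its fields),
#'   `kernel` (diameter/fraction), `confounders`, `continuous` (columns to
#'   standardize), `cognition` (character vector), `pollution` (character
#'   vector), and optionally `alpha`, `min_participants`, `connectivity`,
#'   `trim` (lower/upper), `chain` ([chain_config()]), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the structured log as a list.
#' @export
run_pipeline <- function(data, config, out_dir) {
  if (is.character(data)) data <- read_cohort_csv(data)
  grid <- if (inherits(config$grid, "grid_spec")) config$grid else {
    do.call(grid_spec, config$grid)
  }
  kernel <- if (inherits(config$kernel, "kernel_spec")) config$kernel else {
    do.call(kernel_spec, config$kernel %||% list())
  }
  alpha <- config$alpha %||% 0.05
  min_participants <- config$min_participants %||% 10
  connectivity <- config$connectivity %||% 8
  trim <- config$trim %||% list(lower = 1, upper = 99)
  chain <- config$chain %||% chain_config()
  seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  hash_cfg <- list(
    grid = unclass(grid), kernel = unclass(kernel),
    confounders = config$confounders, continuous = config$continuous,
    cognition = config$cognition, pollution = config$pollution,
    alpha = alpha, min_participants = min_participants,
    connectivity = connectivity, trim = trim,
    chain = unclass(chain), seed = seed
  )
  hash <- config_hash(hash_cfg)

  n_raw <- nrow(data)
  prepared <- preprocess_cohort(data,
                                continuous = config$continuous,
                                cognition = config$cognition,
                                lower = trim$lower, upper = trim$upper)
  log <- list(
    config_hash = hash,
    seed = seed,
    n_raw = n_raw,
    n_removed_missing = attr(prepared, "n_removed_missing"),
    n_removed_extreme = attr(prepared, "n_removed_extreme"),
    n_analysed = nrow(prepared),
    models = list()
  )

  with_seed_if(seed, for (cog in config$cognition) {
    for (pol in config$pollution) {
      tag <- paste0(cog, "_x_", pol)
      fit <- fit_spatial_interaction(
        prepared, grid, cog, pol, config$confounders,
        kernel = kernel, alpha = alpha,
        min_participants = min_participants, connectivity = connectivity
      )
      for (eff in rownames(fit$effect_maps)) {
        safe <- gsub("[^A-Za-z0-9_.-]", "_", eff)
        write_ascii_grid(fit$effect_maps[eff, ], grid,
                         file.path(out_dir, paste0(tag, "_beta_", safe, ".asc")))
      }
      write_ascii_grid(fit$tmap$t, grid,
                       file.path(out_dir, paste0(tag, "_tmap.asc")))
      thr_report <- list(
        config_hash = hash, seed = seed, model = tag,
        alpha = alpha, two_tailed = TRUE,
        t_star = fit$threshold$t_star, method = fit$threshold$method,
        df = fit$df,
        fwhm = c(fit$smoothness$fwhm_x, fit$smoothness$fwhm_y),
        resels = as.list(fit$smoothness$resels)
      )
      jsonlite::write_json(thr_report,
                           file.path(out_dir, paste0(tag, "_threshold.json")),
                           auto_unbox = TRUE, digits = NA)
      region_report <- c(
        list(config_hash = hash, seed = seed, model = tag),
        list(regions = dplyr::select(fit$regions, -"cells"))
      )
      jsonlite::write_json(region_report,
                           file.path(out_dir, paste0(tag, "_regions.json")),
                           auto_unbox = TRUE, digits = NA)
      if (nrow(fit$regions) > 0) {
        write_regions_geojson(fit$regions, grid,
                              file.path(out_dir, paste0(tag, "_regions.geojson")))
      }
      ridge <- bayes_ridge(prepared, response = cog,
                           predictors = c(config$confounders, pol),
                           config = chain)
      readr::write_csv(ridge$summary,
                       file.path(out_dir, paste0(tag, "_bayes.csv")),
                       progress = FALSE)
      log$models[[tag]] <- list(
        cognition = cog, pollution = pol,
        df = fit$df,
        fwhm = c(fit$smoothness$fwhm_x, fit$smoothness$fwhm_y),
        resels = as.list(fit$smoothness$resels),
        t_star = fit$threshold$t_star,
        threshold_method = fit$threshold$method,
        n_sig_cells = sum(fit$mask),
        n_regions = nrow(fit$regions),
        bayes_r2 = ridge$r2
      )
    }
  })
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(log)
}
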