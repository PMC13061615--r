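# ggplot2 displays: per-cell maps, fitted interaction maps with region
# outlines, and posterior interval plots for the ridge comparator.

#' Plot a per-cell map
#'
#' @param values Numeric vector, one entry per cell.
#' @param grid A [grid_spec()].
#' @param name Legend title. Default "value".
#' @return A ggplot object (filled tiles in km coordinates).
#' @export
plot_map <- function(values, grid, name = "value") {
  df <- map_tibble(values, grid, name = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$easting / 1000,
                                   y = .data$northing / 1000,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = name, low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "easting (km)", y = "northing (km)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted spatial interaction model
#'
#' Displays the interaction t-map with the cells of each retained
#' significant region outlined.
#'
#' @param object A `spatcog_fit`.
#' @param map Which surface to show: `"t"` (default), `"interaction"`,
#'   `"cognition"` or `"pollution"` coefficients.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spatcog_fit
#' @export
autoplot.spatcog_fit <- function(object, map = c("t", "interaction",
                                                 "cognition", "pollution"),
                                 ...) {
  map <- match.arg(map)
  values <- switch(map,
    t = object$tmap$t,
    interaction = object$effect_maps[1, ],
    cognition = object$effect_maps[2, ],
    pollution = object$effect_maps[3, ]
  )
  p <- plot_map(values, object$grid,
                name = if (map == "t") "t" else paste0("beta (", map, ")"))
  if (nrow(object$regions) > 0) {
    sig <- map_tibble(object$mask, object$grid, name = "sig")
    sig <- sig[sig$sig, , drop = FALSE]
    p <- p + ggplot2::geom_tile(
      data = sig,
      ggplot2::aes(x = .data$easting / 1000, y = .data$northing / 1000),
      fill = NA, colour = "white", linewidth = 0.4, inherit.aes = FALSE
    )
  }
  p + ggplot2::ggtitle(sprintf("%s x %s (t* = %.2f, %d region(s))",
                               object$cognition, object$pollution,
                               object$threshold$t_star, nrow(object$regions)))
}

#' Plot posterior summaries of a ridge fit
#'
#' Posterior means with interquartile (thick) and 95% (thin) intervals per
#' predictor, flagged terms emphasised.
#'
#' @param object A `spatcog_ridge`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spatcog_ridge
#' @export
autoplot.spatcog_ridge <- function(object, ...) {
  s <- object$summary
  s$term <- factor(s$term, levels = rev(s$term))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_lower,
                                       xend = .data$ci_upper,
                                       yend = .data$term),
                          linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$q25, xend = .data$q75,
                                       yend = .data$term),
                          linewidth = 1.4, colour = "#2166ac") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$flag),
                       nudge_y = 0.25, size = 3) +
    ggplot2::labs(x = "posterior coefficient", y = NULL,
                  title = sprintf("%s (R² = %.3f)", object$response,
                                  object$r2)) +
    ggplot2::theme_minimal()
}
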