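# Minimal map rendering (ggplot2, suggested dependency).

#' Plot a suitability map
#'
#' Simple raster rendering of a class-rank map with the four-level
#' suitability legend. Requires ggplot2.
#'
#' @param map a `suitability_map` or integer rank matrix.
#' @param lat,lon coordinate vectors.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_suitability <- function(map, lat, lon, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  r <- as_rank_matrix(map)
  df <- data.frame(
    lat = rep(lat, times = length(lon)),
    lon = rep(lon, each = length(lat)),
    class = factor(suitability_levels()[as.vector(r)],
                   levels = suitability_levels())
  )
  df <- df[!is.na(df$class), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(limited = "#d73027",
                                          marginal = "#fdae61",
                                          moderate = "#a6d96a",
                                          optimal = "#1a9850"),
                               drop = FALSE, name = "suitability") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}
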