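#' Fixed categorical palette for walks
#'
#' A deterministic 36-color categorical palette (the "Polychrome 36" set),
#' cycled when more series are requested. Determinism across runs is
#' preferred over aesthetics: a sequence keeps its color no matter what else
#' is plotted.
#'
#' @param n Number of colors.
#' @return A character vector of `n` hex colors.
#' @export
walk_palette <- function(n) {
  base <- grDevices::palette.colors(36, palette = "Polychrome 36")
  unname(base[(seq_len(n) - 1L) %% length(base) + 1L])
}

#' Union bounding box of walk extents, with a display margin
#'
#' Returns the tight union of the visible walks' extents, expanded by 2% of
#' the union's span on each side so endpoint strokes stay visible. This is
#' the autoscaling rule applied when sequences are toggled on or off: bounds
#' are recomputed from the visible set alone.
#'
#' @param extents A tibble with one row per visible walk and columns
#'   `x_min`, `x_max`, `y_min`, `y_max` (as produced by [glance.dna_walk()]).
#' @param margin Fractional margin per side; default 0.02.
#' @return A one-row tibble with columns `x_min`, `x_max`, `y_min`, `y_max`.
#' @examples
#' autoscale_bounds(glance(gates_walk("ACGT")))
#' @export
autoscale_bounds <- function(extents, margin = 0.02) {
  if (nrow(extents) == 0L) {
    stop_arg("at least one visible walk is required to autoscale")
  }
  x0 <- min(extents$x_min); x1 <- max(extents$x_max)
  y0 <- min(extents$y_min); y1 <- max(extents$y_max)
  mx <- margin * (x1 - x0)
  my <- margin * (y1 - y0)
  tibble(x_min = x0 - mx, x_max = x1 + mx, y_min = y0 - my, y_max = y1 + my)
}

#' Assign legend colors to a batch
#'
#' In `by_sequence` mode each record receives the next palette index in
#' batch order; in `by_file` mode all records sharing a `source_file` share
#' one index, with files indexed in order of first appearance. Assignments
#' are deterministic, and toggling between modes and back restores the
#' original mapping. Hidden sequences keep their assignment, so re-showing
#' one never recolors the others.
#'
#' @param batch A tibble of records with `seq_id` and `source_file` columns.
#' @param legend_mode `"by_sequence"` or `"by_file"`.
#' @return A tibble with columns `source_file`, `seq_id`, `color_index`
#'   (0-based), `color` (hex) and `label` (the legend text: the sequence id
#'   or the file name).
#' @export
assign_colors <- function(batch, legend_mode = c("by_sequence", "by_file")) {
  legend_mode <- match.arg(legend_mode)
  if (nrow(batch) == 0L) stop_arg("`batch` must contain at least one record")
  if (legend_mode == "by_sequence") {
    idx <- seq_len(nrow(batch)) - 1L
    label <- batch$seq_id
  } else {
    files <- unique(batch$source_file)
    idx <- match(batch$source_file, files) - 1L
    label <- batch$source_file
  }
  tibble(
    source_file = batch$source_file,
    seq_id = batch$seq_id,
    color_index = as.integer(idx),
    color = walk_palette(max(idx) + 1L)[idx + 1L],
    label = label
  )
}

#' Plot specification for rendering stored walks
#'
#' @param visible A tibble of store keys to draw (`source_file`, `seq_id`,
#'   `method`), e.g. a subset of [store_keys()] rows. Toggling a sequence off
#'   means dropping its row here; axis bounds are recomputed from what
#'   remains.
#' @param legend_mode `"by_sequence"` or `"by_file"`.
#' @param title,subtitle Plot title and subtitle. Defaults are derived
#'   dynamically: the comma-joined source file names, and the comma-joined
#'   method names.
#' @param point_budget Even per-walk downsampling budget; default 1000.
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(visible, legend_mode = c("by_sequence", "by_file"),
                      title = NULL, subtitle = NULL, point_budget = 1000) {
  legend_mode <- match.arg(legend_mode)
  if (point_budget < 2 || point_budget %% 2 != 0) {
    stop_arg("`point_budget` must be an even integer >= 2")
  }
  structure(
    list(visible = as_tibble(visible), legend_mode = legend_mode,
         title = title, subtitle = subtitle, point_budget = point_budget),
    class = "plot_spec"
  )
}

# Query every visible key over a region; returns one row per key with a
# list-column of (downsampled) points. Keys with nothing in the region keep
# their row with an empty points table — they stay in the legend.
collect_visible <- function(store, spec, xmin = -Inf, xmax = Inf) {
  keys <- spec$visible
  manifest <- read_manifest(store$path)
  for (i in seq_len(nrow(keys))) {
    if (length(manifest_match(manifest, keys$source_file[i], keys$seq_id[i],
                              keys$method[i])) == 0L) {
      stop_not_found(sprintf(
        "no stored walk for key (source_file='%s', seq_id='%s', method='%s')",
        keys$source_file[i], keys$seq_id[i], keys$method[i]
      ))
    }
  }
  keys |>
    mutate(points = purrr::pmap(
      list(.data$source_file, .data$seq_id, .data$method),
      function(sf, id, m) {
        query_region(store, sf, id, m, xmin = xmin, xmax = xmax,
                     max_points = spec$point_budget)
      }
    ))
}

#' Retrieve the visible walks' points for a zoom region
#'
#' For each visible key, queries the store for the points in the closed
#' region and downsamples to the spec's budget — exactly what a zoom redraw
#' needs. A region narrower than half the budget in bases returns the stored
#' points in that interval without reduction (base-pair resolution). Keys
#' with no points in the region return an empty table but keep their row, so
#' they remain in the legend. Zooming to the full extent reproduces the
#' initial render's data.
#'
#' @param store A [walk_store()].
#' @param spec A [plot_spec()].
#' @param xmin,xmax Closed zoom interval.
#' @return A tibble with one row per visible key and a `points` list-column.
#' @export
zoom_walks <- function(store, spec, xmin = -Inf, xmax = Inf) {
  stopifnot(inherits(spec, "plot_spec"))
  collect_visible(store, spec, xmin = xmin, xmax = xmax)
}

#' Render stored walks as an overlay plot
#'
#' Draws each visible walk as a polyline in walk order, using the store's
#' range query with the spec's point budget (rendered data is always the
#' downsampled view, never the raw series when over budget), colors and
#' labels the legend per the spec's mode, applies autoscaled bounds with a
#' 2% margin, and optionally writes the figure to `file` in one of the four
#' publication formats.
#'
#' @param store A [walk_store()].
#' @param spec A [plot_spec()].
#' @param file Optional output path; its format is taken from `format`.
#' @param format One of `"svg"`, `"pdf"`, `"png"`, `"jpg"`. Defaults to the
#'   extension of `file`.
#' @param width,height Device size in inches.
#' @param xmin,xmax Optional zoom interval (defaults: full extent).
#' @return The ggplot object, invisibly if written to a file.
#' @export
render_walks <- function(store, spec, file = NULL, format = NULL,
                         width = 8, height = 5, xmin = -Inf, xmax = Inf) {
  stopifnot(inherits(spec, "plot_spec"))
  data <- collect_visible(store, spec, xmin = xmin, xmax = xmax)
  colors <- assign_colors(
    distinct(data[c("source_file", "seq_id")]),
    legend_mode = spec$legend_mode
  )
  data <- dplyr::left_join(data, colors, by = c("source_file", "seq_id"))
  # one polyline per walk, grouped by full key; color/legend by label
  flat <- data |>
    mutate(.group = paste(.data$source_file, .data$seq_id, .data$method,
                          sep = "\r")) |>
    tidyr::unnest("points")

  non_empty <- data$points[vapply(data$points, nrow, integer(1)) > 0L]
  extents <- bind_rows(purrr::map(non_empty, function(p) {
    tibble(x_min = min(p$x), x_max = max(p$x),
           y_min = min(p$y), y_max = max(p$y))
  }))
  bounds <- autoscale_bounds(extents)

  title <- spec$title %||% paste(unique(data$source_file), collapse = ", ")
  subtitle <- spec$subtitle %||% paste(unique(data$method), collapse = ", ")
  pal <- colors |> distinct(.data$label, .data$color)

  p <- ggplot2::ggplot(
    flat,
    ggplot2::aes(x = .data$x, y = .data$y, group = .data$.group,
                 colour = .data$label)
  ) +
    ggplot2::geom_path() +
    ggplot2::scale_colour_manual(values = setNames(pal$color, pal$label)) +
    ggplot2::coord_cartesian(
      xlim = c(bounds$x_min, bounds$x_max),
      ylim = c(bounds$y_min, bounds$y_max),
      expand = FALSE
    ) +
    ggplot2::labs(title = title, subtitle = subtitle, x = "x", y = "y",
                  colour = NULL) +
    ggplot2::theme_minimal()

  if (is.null(file)) return(p)
  export_plot(p, file, format = format, width = width, height = height)
  invisible(p)
}

#' Export a plot in a publication format
#'
#' @param plot A ggplot object.
#' @param file Output path.
#' @param format One of `"svg"`, `"pdf"`, `"png"`, `"jpg"`; defaults to the
#'   file extension.
#' @param width,height Device size in inches.
#' @param dpi Resolution for raster formats.
#' @return `file`, invisibly.
#' @export
export_plot <- function(plot, file, format = NULL, width = 8, height = 5,
                        dpi = 150) {
  format <- tolower(format %||% tools::file_ext(file))
  valid <- c("svg", "pdf", "png", "jpg")
  if (!format %in% valid) {
    stop_arg(sprintf("unknown export format '%s'; supported formats are: %s",
                     format, paste(valid, collapse = ", ")))
  }
  switch(format,
    svg = grDevices::svg(file, width = width, height = height),
    pdf = grDevices::pdf(file, width = width, height = height),
    png = grDevices::png(file, width = width, height = height, units = "in",
                         res = dpi),
    jpg = grDevices::jpeg(file, width = width, height = height, units = "in",
                          res = dpi)
  )
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
  invisible(file)
}

#' Plot a walk directly
#'
#' Convenience for plotting a single in-memory walk without a store.
#'
#' @param object A `dna_walk`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dna_walk <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = walk_palette(1)) +
    ggplot2::labs(
      title = attr(object, "seq_id"),
      subtitle = attr(object, "method"),
      x = "x", y = "y"
    ) +
    ggplot2::theme_minimal()
}
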