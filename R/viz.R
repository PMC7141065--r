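#' @import ggplot2
NULL

# save a ggplot to PNG or SVG (by extension), write the plotted values as a
# CSV sidecar and run metadata as a JSON sidecar, and return the data layer
render_save <- function(plot, data, meta, file, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(file))
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  dev <- switch(ext,
                png = grDevices::png,
                svg = grDevices::svg,
                stop("unsupported figure format '", ext, "' (use png or svg)"))
  ggsave(file, plot, device = dev, width = width, height = height, dpi = 120)
  utils::write.csv(data, paste0(file, ".csv"), row.names = FALSE)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(data)
}

#' Render pairwise distance matrices, one panel per group
#'
#' Draws participants on both axes with cell darkness proportional to
#' scanpath distance (darker = larger distance = less similar), on a shared
#' `[0, 1]` scale across group panels so the groups are directly comparable.
#' A raw (unnormalised) matrix is normalised first, with a message.
#'
#' @param matrix Distance matrix from [pairwise_distances()].
#' @param groups Optional group-assignment data frame; when given, one panel
#'   per group (within-group comparisons only).
#' @param file Output image path (`.png` or `.svg`).
#' @param title Figure title.
#' @param stimulus Stimulus id for group lookup (default: single stimulus in
#'   `groups`).
#' @return Invisibly, the plotted long-format data
#'   (`row`, `col`, `group`, `value`). Sidecars `<file>.csv` (those values)
#'   and `<file>.json` (normalisation constant, scale bounds) are written
#'   next to the image.
#' @export
render_distance_matrix <- function(matrix, groups = NULL, file,
                                   title = "Scanpath distance", stimulus = NULL) {
  if (!isTRUE(attr(matrix, "normalized"))) {
    message("normalizing distance matrix by its maximum for rendering")
    matrix <- normalize_distmat(matrix)
  }
  ids <- rownames(matrix)
  if (is.null(groups)) {
    grp <- rep("all", length(ids))
  } else {
    if (is.null(stimulus)) {
      stims <- unique(groups$stimulus)
      if (length(stims) != 1L) stop("groups table spans multiple stimuli; pass `stimulus`")
      stimulus <- stims
    }
    grp <- group_lookup(groups, ids, stimulus)
    if (anyNA(grp)) stop("participant(s) without group assignment")
  }
  panels <- lapply(unique(grp), function(g) {
    members <- ids[grp == g]
    sub <- matrix[members, members, drop = FALSE]
    data.frame(row = rep(members, times = length(members)),
               col = rep(members, each = length(members)),
               group = g, value = as.vector(sub))
  })
  df <- do.call(rbind, panels)
  df$row <- factor(df$row, levels = rev(ids))
  df$col <- factor(df$col, levels = ids)
  p <- ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "black", limits = c(0, 1),
                        name = "distance") +
    facet_wrap(~group, scales = "free") +
    labs(title = title, x = NULL, y = NULL) +
    theme_minimal(base_size = 9) +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
  meta <- list(figure = "distance_matrix", title = title,
               normalization_max = attr(matrix, "norm_max"),
               scale = c(0, 1), groups = unique(grp))
  render_save(p, df, meta, file)
}

#' Render a web (radar) diagram of scanpath lengths per stimulus
#'
#' One polygon per group over one axis per stimulus, with the radius on each
#' axis giving the group's mean truncated scanpath length for that stimulus.
#'
#' @param summaries Data frame with columns `stimulus`, `group`,
#'   `mean_length` (at least 3 stimuli).
#' @param file Output image path.
#' @param title Figure title.
#' @return Invisibly, the plotted data with polygon coordinates.
#' @export
render_web_diagram <- function(summaries, file,
                               title = "Mean scanpath length per stimulus") {
  need <- c("stimulus", "group", "mean_length")
  stopifnot(all(need %in% names(summaries)))
  stims <- unique(summaries$stimulus)
  if (length(stims) < 3L)
    stop("a web diagram needs at least 3 stimulus axes, got ", length(stims))
  ang <- stats::setNames(2 * pi * (seq_along(stims) - 1) / length(stims), stims)
  df <- summaries
  df$angle <- ang[df$stimulus]
  df$px <- df$mean_length * sin(df$angle)
  df$py <- df$mean_length * cos(df$angle)
  df <- df[order(df$group, df$angle), ]
  rmax <- max(df$mean_length)
  axes <- data.frame(stimulus = stims,
                     xend = 1.05 * rmax * sin(ang), yend = 1.05 * rmax * cos(ang))
  p <- ggplot(df, aes(x = .data$px, y = .data$py,
                      group = .data$group, colour = .data$group)) +
    geom_segment(data = axes, aes(x = 0, y = 0, xend = .data$xend,
                                  yend = .data$yend),
                 inherit.aes = FALSE, colour = "grey80") +
    geom_text(data = axes, aes(x = .data$xend * 1.08, y = .data$yend * 1.08,
                               label = .data$stimulus),
              inherit.aes = FALSE, size = 3) +
    geom_polygon(fill = NA, linewidth = 0.8) +
    geom_point(size = 1.5) +
    coord_equal() +
    labs(title = title, x = NULL, y = NULL, colour = "group") +
    theme_void(base_size = 10) +
    theme(plot.title = element_text(hjust = 0.5))
  meta <- list(figure = "web_diagram", title = title,
               n_axes = length(stims), groups = unique(df$group))
  render_save(p, df, meta, file, width = 6, height = 6)
}

#' Render a gridded dwell-time heatmap
#'
#' Shades each grid cell by total fixation duration; with `annotate = TRUE`
#' the dwell value (ms, rounded) is printed in each cell. Pass `scale_max`
#' (e.g. the maximum over both groups' grids) to render several grids on a
#' shared colour scale.
#'
#' @param dwell A `dwellgrid` from [bin_dwell()].
#' @param file Output image path.
#' @param annotate Print the value in each cell.
#' @param aoiset Optional [aoiset()] whose rectangle boundaries are overlaid.
#' @param scale_max Upper colour-scale bound in ms (default: this grid's
#'   maximum).
#' @param title Figure title.
#' @return Invisibly, the plotted long-format cell data.
#' @export
render_grid_heatmap <- function(dwell, file, annotate = TRUE, aoiset = NULL,
                                scale_max = NULL, title = "Dwell time per grid cell") {
  stopifnot(inherits(dwell, "dwellgrid"))
  g <- dwell$grid
  df <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  df$value <- dwell$values[cbind(df$row, df$col)]
  df$x <- (df$col - 0.5) * g$cell_width
  df$y <- (df$row - 0.5) * g$cell_height
  if (is.null(scale_max)) scale_max <- max(df$value)
  if (scale_max <= 0) scale_max <- 1
  p <- ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_tile(width = g$cell_width, height = g$cell_height, colour = "grey70") +
    scale_fill_gradient(low = "white", high = "red3",
                        limits = c(0, scale_max), name = "dwell (ms)") +
    scale_y_reverse() +
    coord_equal() +
    labs(title = title, x = "x (px)", y = "y (px)") +
    theme_minimal(base_size = 9)
  if (annotate)
    p <- p + geom_text(aes(label = round(.data$value)), size = 2)
  if (!is.null(aoiset)) {
    a <- aoiset$aois
    p <- p + annotate("rect", xmin = a$x0, xmax = a$x1,
                      ymin = a$y0, ymax = a$y1,
                      colour = "blue", fill = NA, linewidth = 0.3)
  }
  meta <- list(figure = "grid_heatmap", title = title,
               n_cols = g$n_cols, n_rows = g$n_rows,
               cell_width = g$cell_width, cell_height = g$cell_height,
               base_dimension = g$base_dimension,
               scale = c(0, scale_max),
               excluded_n = dwell$excluded_n,
               excluded_duration = dwell$excluded_duration)
  render_save(p, df, meta, file)
}

#' Render a directed chord diagram of AOI transitions
#'
#' Places AOIs on a circle and draws one curved, arrow-headed ribbon per
#' directed edge, with line width proportional to the transition count and
#' the count printed at the arrow head. Self-transitions are drawn as loops
#' beside their node.
#'
#' @param edges Edge list from [subset_and_edges()] (non-empty).
#' @param file Output image path.
#' @param title Figure title.
#' @param max_width Line width given to the largest count.
#' @return Invisibly, the edge data with computed widths and endpoints.
#' @export
render_chord <- function(edges, file, title = "AOI transitions", max_width = 6) {
  if (!nrow(edges)) stop("cannot render a chord diagram from an empty edge list")
  nodes <- sort(unique(c(edges$from, edges$to)))
  ang <- stats::setNames(2 * pi * (seq_along(nodes) - 1) / length(nodes), nodes)
  df <- edges
  df$width <- df$count / max(df$count) * max_width
  inset <- 0.08
  df$x0 <- sin(ang[df$from]) * (1 - inset)
  df$y0 <- cos(ang[df$from]) * (1 - inset)
  df$x1 <- sin(ang[df$to]) * (1 - inset)
  df$y1 <- cos(ang[df$to]) * (1 - inset)
  self <- df$from == df$to
  nd <- data.frame(node = nodes, x = sin(ang), y = cos(ang))
  p <- ggplot() +
    geom_curve(data = df[!self, , drop = FALSE],
               aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$width,
                   colour = .data$from),
               curvature = 0.2,
               arrow = grid::arrow(length = grid::unit(6, "pt"))) +
    geom_point(data = nd[nd$node %in% df$from[self], , drop = FALSE],
               aes(x = .data$x * 1.12, y = .data$y * 1.12),
               shape = 21, size = 6, stroke = 1.2, fill = NA) +
    geom_text(data = nd, aes(x = .data$x * 1.25, y = .data$y * 1.25,
                             label = .data$node), size = 4) +
    geom_text(data = df[!self, , drop = FALSE],
              aes(x = (.data$x0 + .data$x1) / 2 * 0.75,
                  y = (.data$y0 + .data$y1) / 2 * 0.75,
                  label = .data$count), size = 2.6) +
    geom_text(data = df[self, , drop = FALSE],
              aes(x = .data$x0 * 1.12 / (1 - inset),
                  y = .data$y0 * 1.12 / (1 - inset), label = .data$count),
              size = 2.6) +
    scale_linewidth_identity() +
    coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    labs(title = title) +
    theme_void(base_size = 10) +
    theme(legend.position = "none",
          plot.title = element_text(hjust = 0.5))
  meta <- list(figure = "chord", title = title, nodes = nodes,
               max_count = max(df$count), max_width = max_width)
  render_save(p, df, meta, file, width = 6, height = 6)
}
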