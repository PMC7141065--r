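#' Density-based clustering of fixation points (DBSCAN)
#'
#' Standard DBSCAN with the Euclidean metric: a point is a *core point* when
#' at least `min_pts` points (itself included) lie within radius `eps`;
#' clusters are maximal sets of density-connected core points plus the border
#' points they reach. Border points reachable from several clusters are
#' assigned deterministically to the cluster of their nearest core neighbour
#' (lowest index on a tie), so results do not depend on visit order.
#'
#' @param points Two-column matrix or data frame of `(x, y)` pixel
#'   coordinates.
#' @param eps Neighbourhood radius in pixels, `> 0`.
#' @param min_pts Minimum neighbourhood size (including the point itself),
#'   `>= 1`.
#' @return List with `cluster` (integer per point, `0` = noise) and `core`
#'   (logical per point).
#' @export
fit_dbscan <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 1)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n == 0L) return(list(cluster = integer(0), core = logical(0)))
  d <- as.matrix(stats::dist(pts))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  cluster <- integer(n)
  cid <- 0L
  # density-connected components over core points
  for (i in which(core)) {
    if (cluster[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    cluster[i] <- cid
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      reach <- which(nb[p, ] & core & cluster == 0L)
      cluster[reach] <- cid
      queue <- c(queue, reach)
    }
  }
  # border points: nearest core neighbour within eps decides the cluster
  for (i in which(!core)) {
    cand <- which(nb[i, ] & core)
    if (length(cand)) {
      best <- cand[order(d[i, cand], cand)][1]
      cluster[i] <- cluster[best]
    }
  }
  list(cluster = cluster, core = core)
}

#' Derive the smallest core-point radius
#'
#' Walks a descending ladder of candidate radii and returns the smallest
#' radius at which the point cloud still contains at least one DBSCAN core
#' point (a point with `min_pts` neighbours, itself included, within the
#' radius). This data-driven radius sets the grid cell dimension for dwell
#' maps: cell side = core-point diameter. If no candidate yields a core
#' point, the largest candidate is returned with a warning.
#'
#' @inheritParams fit_dbscan
#' @param eps_candidates Strictly decreasing vector of positive candidate
#'   radii (pixels).
#' @return A single radius in pixels.
#' @export
derive_core_radius <- function(points, min_pts,
                               eps_candidates = c(64, 48, 32, 24, 16, 12, 8)) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) == 0L) stop("cannot derive a core radius from zero points")
  if (!length(eps_candidates) || any(eps_candidates <= 0) ||
      is.unsorted(rev(eps_candidates), strictly = TRUE))
    stop("eps_candidates must be positive and strictly decreasing")
  d <- as.matrix(stats::dist(pts))
  for (eps in sort(eps_candidates)) {  # try smallest first
    if (any(rowSums(d <= eps) >= min_pts)) return(eps)
  }
  warning("no candidate radius yields a core point; returning the largest (",
          max(eps_candidates), " px)")
  max(eps_candidates)
}

#' Build a grid specification from a core-point radius
#'
#' The minimum cell dimension is the core-point diameter
#' (`2 * core_radius`). Each axis is divided into the largest number of cells
#' whose side is at least that diameter, then the cells are stretched to tile
#' the stimulus exactly — cells may therefore be rectangular, which increases
#' coverage of a rectangular stimulus.
#'
#' @param stim_w,stim_h Stimulus dimensions in pixels.
#' @param core_radius Core-point radius in pixels.
#' @return Object of class `gridspec`: list with `width`, `height`, `n_cols`,
#'   `n_rows`, `cell_width`, `cell_height`, `base_dimension`.
#' @export
make_grid <- function(stim_w, stim_h, core_radius) {
  stopifnot(stim_w > 0, stim_h > 0, core_radius > 0)
  base <- 2 * core_radius
  if (base > min(stim_w, stim_h))
    warning("core-point diameter (", base,
            " px) exceeds a stimulus dimension; grid degenerates toward 1x1")
  n_cols <- max(1L, floor(stim_w / base))
  n_rows <- max(1L, floor(stim_h / base))
  structure(list(width = stim_w, height = stim_h,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 cell_width = stim_w / n_cols, cell_height = stim_h / n_rows,
                 base_dimension = base),
            class = "gridspec")
}

#' @export
print.gridspec <- function(x, ...) {
  cat(sprintf("<gridspec> %gx%g px, %d cols x %d rows (cells %.1fx%.1f px, base %g px)\n",
              x$width, x$height, x$n_cols, x$n_rows,
              x$cell_width, x$cell_height, x$base_dimension))
  invisible(x)
}

#' Bin fixation durations into a dwell-time grid
#'
#' Adds each in-bounds fixation's full duration to the single grid cell
#' containing its point. Cells are half-open; a point exactly on the
#' stimulus's right or bottom edge is assigned to the last cell. Fixations
#' outside the stimulus are excluded and their count/duration recorded.
#'
#' @param fixations Fixation data frame.
#' @param grid A [make_grid()] `gridspec`.
#' @return Object of class `dwellgrid`: list with `grid`, `values`
#'   (`n_rows x n_cols` matrix of total dwell in ms), `excluded_n`,
#'   `excluded_duration`.
#' @export
bin_dwell <- function(fixations, grid) {
  stopifnot(inherits(grid, "gridspec"))
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  x <- fixations$x; y <- fixations$y; dur <- fixations$duration_ms
  inb <- x >= 0 & x <= grid$width & y >= 0 & y <= grid$height
  col <- pmin(floor(x[inb] / grid$cell_width) + 1L, grid$n_cols)
  row <- pmin(floor(y[inb] / grid$cell_height) + 1L, grid$n_rows)
  for (k in seq_along(col)) vals[row[k], col[k]] <- vals[row[k], col[k]] + dur[inb][k]
  structure(list(grid = grid, values = vals,
                 excluded_n = sum(!inb),
                 excluded_duration = sum(dur[!inb])),
            class = "dwellgrid")
}

#' Cell-wise difference between two dwell grids
#'
#' Subtracts grid `b` from grid `a` cell by cell so the distribution of
#' attention of two groups over the same stimulus can be compared
#' numerically, and reports each grid's hottest cell.
#'
#' @param grid_a,grid_b `dwellgrid` objects over identical grid
#'   specifications.
#' @return List with `diff` (signed matrix `a - b`), `argmax_a`, `argmax_b`
#'   (each a `(row, col)` integer vector for the grid's maximum cell).
#' @export
group_dwell_diff <- function(grid_a, grid_b) {
  stopifnot(inherits(grid_a, "dwellgrid"), inherits(grid_b, "dwellgrid"))
  if (!isTRUE(all.equal(unclass(grid_a$grid), unclass(grid_b$grid))))
    stop("dwell grids have different grid specifications")
  amax <- which(grid_a$values == max(grid_a$values), arr.ind = TRUE)[1, ]
  bmax <- which(grid_b$values == max(grid_b$values), arr.ind = TRUE)[1, ]
  list(diff = grid_a$values - grid_b$values,
       argmax_a = unname(amax), argmax_b = unname(bmax))
}
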