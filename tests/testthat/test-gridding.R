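test_that("fit_dbscan recovers blob structure and labels isolated points as noise", {
  set.seed(21)
  blob <- function(cx, cy, n = 10, s = 4) cbind(rnorm(n, cx, s), rnorm(n, cy, s))
  pts <- rbind(blob(100, 100), blob(600, 100))
  got <- fit_dbscan(pts, eps = 20, min_pts = 4)
  expect_equal(length(unique(got$cluster)), 2)
  expect_true(all(got$cluster != 0))

  iso <- cbind(c(0, 100, 200), c(0, 100, 200))
  got2 <- fit_dbscan(iso, eps = 10, min_pts = 2)
  expect_equal(got2$cluster, c(0L, 0L, 0L))
  expect_false(any(got2$core))

  one <- fit_dbscan(cbind(5, 5), eps = 1, min_pts = 1)
  expect_equal(one$cluster, 1L)
  expect_true(one$core)

  empty <- fit_dbscan(matrix(numeric(0), ncol = 2), eps = 1, min_pts = 1)
  expect_length(empty$cluster, 0)
})

test_that("fit_dbscan matches the graph-components reference on mixed geometries", {
  set.seed(33)
  for (rep in 1:6) {
    theta <- runif(60, 0, 2 * pi)
    pts <- rbind(
      cbind(rnorm(50, 200, 10), rnorm(50, 200, 10)),          # blob
      cbind(400 + 80 * cos(theta), 300 + 80 * sin(theta)) +
        matrix(rnorm(120, 0, 3), ncol = 2),                   # ring
      cbind(runif(40, 0, 600), runif(40, 0, 600))             # noise
    )
    eps <- sample(c(15, 25, 40), 1)
    min_pts <- sample(3:6, 1)
    got <- fit_dbscan(pts, eps, min_pts)
    ref <- dbscan_oracle(pts, eps, min_pts)
    expect_equal(got$core, ref$core)
    expect_true(same_partition(got$cluster, ref$cluster))
  }
})

test_that("derive_core_radius returns the smallest radius admitting a core point", {
  coincident <- cbind(rep(1, 5), rep(1, 5))
  expect_equal(derive_core_radius(coincident, 5, c(32, 16, 8, 4, 2, 1)), 1)

  square <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
  # all four points within eps only once eps >= diagonal (14.14)
  expect_equal(derive_core_radius(square, 4, c(32, 16, 8)), 16)
  # brute-force check of the same answer
  d <- as.matrix(dist(square))
  expect_false(any(rowSums(d <= 8) >= 4))
  expect_true(any(rowSums(d <= 16) >= 4))

  expect_warning(r <- derive_core_radius(square, 4, c(12, 8)), "no candidate")
  expect_equal(r, 12)

  expect_error(derive_core_radius(square[0, ], 2), "zero points")
  expect_error(derive_core_radius(square, 2, c(8, 16)), "decreasing")

  # monotone: larger min_pts never shrinks the radius
  set.seed(2)
  pts <- cbind(runif(80, 0, 400), runif(80, 0, 400))
  ladder <- c(64, 48, 32, 24, 16, 12, 8)
  radii <- vapply(1:8, function(mp)
    suppressWarnings(derive_core_radius(pts, mp, ladder)), numeric(1))
  expect_true(all(diff(radii) >= 0))
})

test_that("make_grid tiles the stimulus with cells at least a core diameter wide", {
  g <- make_grid(1000, 500, 50)
  expect_equal(c(g$n_cols, g$n_rows), c(10L, 5L))
  expect_equal(c(g$cell_width, g$cell_height), c(100, 100))
  expect_equal(g$base_dimension, 100)

  g2 <- make_grid(1050, 500, 50)
  expect_equal(g2$n_cols, 10L)
  expect_equal(g2$cell_width, 105)
  expect_gte(g2$cell_width, g2$base_dimension)
  expect_equal(g2$n_cols * g2$cell_width, 1050)

  expect_warning(g3 <- make_grid(1000, 500, 600), "1x1")
  expect_equal(c(g3$n_cols, g3$n_rows), c(1L, 1L))
})

test_that("bin_dwell conserves duration and assigns cells half-open", {
  g <- make_grid(300, 300, 50)  # 3x3 cells of 100
  fx <- data.frame(participant = "P1", stimulus = "s", onset_ms = 0,
                   x = 150, y = 150, duration_ms = 300)
  dw <- bin_dwell(fx, g)
  expect_equal(dw$values[2, 2], 300)
  expect_equal(sum(dw$values), 300)

  # interior boundary point goes to the higher-index cell; stimulus edge to the last
  bd <- data.frame(participant = "P1", stimulus = "s", onset_ms = c(0, 100),
                   x = c(100, 300), y = c(100, 300), duration_ms = c(10, 20))
  dwb <- bin_dwell(bd, g)
  expect_equal(dwb$values[2, 2], 10)
  expect_equal(dwb$values[3, 3], 20)
  # brute-force containment scan over all cells agrees
  cell_of <- function(px, py) {
    for (r in 1:3) for (cc in 1:3) {
      x0 <- (cc - 1) * 100; y0 <- (r - 1) * 100
      if (px >= x0 && (px < x0 + 100 || (cc == 3 && px == 300)) &&
          py >= y0 && (py < y0 + 100 || (r == 3 && py == 300))) return(c(r, cc))
    }
    NULL
  }
  expect_equal(cell_of(100, 100), c(2, 2))
  expect_equal(cell_of(300, 300), c(3, 3))

  set.seed(13)
  rnd <- data.frame(participant = "P1", stimulus = "s", onset_ms = seq_len(1000),
                    x = runif(1000, -50, 350), y = runif(1000, -50, 350),
                    duration_ms = rexp(1000, 1 / 200))
  dwr <- bin_dwell(rnd, g)
  expect_equal(sum(dwr$values) + dwr$excluded_duration, sum(rnd$duration_ms))
  inb <- rnd$x >= 0 & rnd$x <= 300 & rnd$y >= 0 & rnd$y <= 300
  expect_equal(dwr$excluded_n, sum(!inb))
})

test_that("group_dwell_diff subtracts cellwise and reports hottest cells", {
  g <- make_grid(200, 200, 50)
  mk <- function(vals) structure(list(grid = g, values = vals,
                                      excluded_n = 0L, excluded_duration = 0),
                                 class = "dwellgrid")
  a <- mk(matrix(c(5, 0, 0, 0), 2))
  b <- mk(matrix(0, 2, 2))
  d <- group_dwell_diff(a, b)
  expect_equal(d$diff, a$values)
  expect_equal(d$argmax_a, c(1, 1))

  expect_equal(group_dwell_diff(a, a)$diff, matrix(0, 2, 2))

  g2 <- make_grid(300, 300, 50)
  c2 <- structure(list(grid = g2, values = matrix(0, 3, 3),
                       excluded_n = 0L, excluded_duration = 0),
                  class = "dwellgrid")
  expect_error(group_dwell_diff(a, c2), "different grid")
})

test_that("group dwell grids separate hotspots built into synthetic groups", {
  layout <- tiny_layout()
  hs_a <- data.frame(cx = c(25, 25, 25, 25), cy = c(25, 25, 25, 25), sd = 4)
  hs_d <- data.frame(cx = c(75, 75, 75, 75), cy = c(75, 75, 75, 75), sd = 4)
  ident <- diag(4)
  m_a <- gaze_model(layout, trans = ident, initial_dist = c(1, 0, 0, 0),
                    hotspots = hs_a, p_uniform = 0)
  m_d <- gaze_model(layout, trans = ident, initial_dist = c(0, 0, 0, 1),
                    hotspots = hs_d, p_uniform = 0)
  st <- simulate_study(m_a, m_d, 5, 5, seed = 99, stimulus_id = "stim1")
  grid <- make_grid(100, 100, 25)
  grp <- st$groups$group[match(st$fixations$participant, st$groups$participant)]
  dg_a <- bin_dwell(st$fixations[grp == "correct", ], grid)
  dg_d <- bin_dwell(st$fixations[grp == "incorrect", ], grid)
  d <- group_dwell_diff(dg_a, dg_d)
  expect_false(identical(d$argmax_a, d$argmax_b))
  expect_equal(d$argmax_a, c(1, 1))
  expect_equal(d$argmax_b, c(2, 2))
})
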