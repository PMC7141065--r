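test_that("assign_aoi matches a brute-force containment scan and handles edges", {
  layout <- tiny_layout()
  expect_equal(assign_aoi(60, 10, layout), "B")
  expect_equal(assign_aoi(150, 150, layout), off_aoi())
  # half-open rectangles: shared edges belong to the AOI starting there
  expect_equal(assign_aoi(50, 0, layout), "B")
  expect_equal(assign_aoi(0, 50, layout), "C")
  expect_equal(assign_aoi(100, 100, layout), off_aoi())

  set.seed(7)
  x <- runif(10000, -20, 120)
  y <- runif(10000, -20, 120)
  expect_equal(assign_aoi(x, y, layout), brute_assign(x, y, layout))
})

test_that("build_scanpath reproduces a token sequence from fixation positions", {
  layout <- default_ecg_layout()
  visits <- c("M","M","I","I","M","G","G","E","E","B","A","A","M","M","I","I")
  fx <- fixations_at(visits, layout, participant = "P25")
  sp <- build_scanpath(fx, layout)
  expect_s3_class(sp, "scanpath")
  expect_equal(sp$tokens, visits)
  expect_equal(sp$participant, "P25")
})

test_that("build_scanpath applies the off-AOI policy and validates input", {
  layout <- tiny_layout()
  fx <- fixations_at(c("A", "B"), layout)
  fx$x[2] <- 500  # push second fixation off-stimulus
  expect_equal(build_scanpath(fx, layout, "drop")$tokens, "A")
  expect_equal(build_scanpath(fx, layout, "keep")$tokens, c("A", off_aoi()))

  off <- fixations_at(c("A", "A"), layout)
  off$x <- 500
  expect_length(build_scanpath(off, layout, "drop")$tokens, 0)

  mixed <- rbind(fixations_at("A", layout, "P1"), fixations_at("B", layout, "P2"))
  expect_error(build_scanpath(mixed, layout), "single participant")

  shuffled <- fixations_at(c("A", "B", "C"), layout)
  shuffled$onset_ms <- c(400, 200, 600)
  expect_error(build_scanpath(shuffled, layout), "increasing")

  expect_length(build_scanpath(fx[0, ], layout)$tokens, 0)
})

test_that("truncation collapses runs, preserves order, and is idempotent", {
  expect_equal(truncate_scanpath(c("M","M","M","B","B","A","B","C")),
               c("M","B","A","B","C"))
  expect_equal(truncate_scanpath(c("M","B","A","B","C")),
               c("M","B","A","B","C"))
  expect_equal(truncate_scanpath("A"), "A")
  expect_equal(truncate_scanpath(character(0)), character(0))

  sp <- new_scanpath_test("P1", "s", c("A","A","B"))
  tsp <- truncate_scanpath(sp)
  expect_true(tsp$truncated)
  expect_equal(tsp$tokens, c("A", "B"))

  set.seed(11)
  for (i in 1:200) {
    s <- sample(c("A","B","C"), sample(0:30, 1), replace = TRUE)
    t1 <- truncate_scanpath(s)
    expect_lte(length(t1), length(s))
    expect_equal(truncate_scanpath(t1), t1)
    if (length(t1) > 1) expect_true(all(t1[-1] != t1[-length(t1)]))
  }
})

test_that("levenshtein agrees with recursive oracles and satisfies metric axioms", {
  p25 <- c("M","M","I","I","M","G","G","E","E","B","A","A","M","M","I","I")
  p19 <- c("H","E","D","D","E","H","H","G","G","G","I","F","F","F","D")
  d_oracle <- lev_memo_r(p25, p19)
  expect_equal(levenshtein(p25, p19), d_oracle)
  expect_equal(unname(utils::adist(paste(p25, collapse = ""),
                                   paste(p19, collapse = ""))[1, 1]), d_oracle)

  set.seed(3)
  for (i in 1:50) {
    a <- sample(LETTERS[1:5], sample(0:8, 1), replace = TRUE)
    b <- sample(LETTERS[1:5], sample(0:8, 1), replace = TRUE)
    c_ <- sample(LETTERS[1:5], sample(0:8, 1), replace = TRUE)
    dab <- levenshtein(a, b)
    expect_equal(dab, levenshtein_reference(a, b))
    expect_equal(dab, lev_memo_r(a, b))
    expect_equal(dab, levenshtein(b, a))                       # symmetry
    expect_equal(levenshtein(a, a), 0)                         # identity
    expect_equal(levenshtein(character(0), a), length(a))      # empty case
    expect_lte(dab, levenshtein(a, c_) + levenshtein(c_, b))   # triangle
  }
  # distance zero implies equality
  expect_gt(levenshtein(c("A","B"), c("A","C")), 0)
  # multi-character tokens are single symbols
  expect_equal(levenshtein(c("V1","V2"), c("V1","V3")), 1)
})

test_that("pairwise_distances builds a symmetric zero-diagonal labelled matrix", {
  sps <- list(new_scanpath_test("P1", "s", c("A","B")),
              new_scanpath_test("P2", "s", c("A","B")))
  m <- pairwise_distances(sps)
  expect_equal(unname(m), matrix(0, 2, 2), ignore_attr = TRUE)

  sps2 <- list(new_scanpath_test("P1", "s", "A"),
               new_scanpath_test("P2", "s", c("A","B")))
  expect_equal(pairwise_distances(sps2)["P1", "P2"], 1)

  set.seed(5)
  sps3 <- lapply(1:6, function(i)
    random_scanpath(LETTERS[1:4], 8, participant = paste0("P", i)))
  m3 <- pairwise_distances(sps3)
  expect_true(isSymmetric(unname(m3)))
  expect_equal(diag(m3), setNames(rep(0, 6), rownames(m3)))
  expect_false(attr(m3, "normalized"))
  for (i in 1:6) for (j in 1:6)
    expect_equal(m3[i, j], lev_memo_r(sps3[[i]]$tokens, sps3[[j]]$tokens))

  dup <- c(sps3, list(random_scanpath(LETTERS[1:4], 3, participant = "P1")))
  expect_error(pairwise_distances(dup), "duplicate")
  other <- list(sps3[[1]], new_scanpath_test("P9", "other", "A"))
  expect_error(pairwise_distances(other), "stimuli")
  expect_error(pairwise_distances(sps3[1]), "at least 2")
})

test_that("normalization maps into [0,1], preserves ordering, handles degenerate input", {
  m <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a","b"), c("a","b")))
  attr(m, "normalized") <- FALSE
  nm <- normalize_distmat(m)
  expect_equal(unname(nm), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_true(attr(nm, "normalized"))
  expect_equal(attr(nm, "norm_max"), 4)
  expect_error(normalize_distmat(nm), "already")

  z <- matrix(0, 3, 3); attr(z, "normalized") <- FALSE
  nz <- normalize_distmat(z)
  expect_equal(unname(nz), matrix(0, 3, 3), ignore_attr = TRUE)
  expect_true(attr(nz, "normalized"))

  set.seed(9)
  sps <- lapply(1:5, function(i)
    random_scanpath(LETTERS[1:3], sample(3:12, 1), participant = paste0("P", i)))
  raw <- pairwise_distances(sps)
  nrm <- normalize_distmat(raw)
  expect_true(all(nrm >= 0 & nrm <= 1))
  expect_equal(max(nrm), 1)
  expect_equal(order(raw), order(nrm))  # entry ordering preserved
})

test_that("length_summary computes mean, sample SD, smallest mode, and range", {
  sps <- lapply(c(9, 9, 23), function(L) random_scanpath("A", L))
  s <- length_summary(sps)
  expect_equal(round(s$mean, 2), 13.67)
  expect_equal(s$sd, sd(c(9, 9, 23)))
  expect_equal(s$mode, 9)
  expect_equal(s$range, 14)
  expect_equal(s$n, 3)

  one <- length_summary(list(random_scanpath("A", 7)))
  expect_equal(one[, c("mean", "sd", "mode", "range")],
               data.frame(mean = 7, sd = 0, mode = 7, range = 0))

  tie <- length_summary(lapply(c(3, 3, 5, 5), function(L) random_scanpath("A", L)))
  expect_equal(tie$mode, 3)  # tie broken toward the smallest length

  # truncated lengths measured after run collapsing
  sp <- new_scanpath_test("P1", "s", c("A","A","B","B","B","C"))
  expect_equal(length_summary(list(sp), truncated = TRUE)$mean, 3)
  expect_error(length_summary(list()), "at least one")
})
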