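#' Mann-Whitney U test between two samples
#'
#' Wraps `stats::wilcox.test` with the W convention of that function: W is
#' the U statistic of the first sample, the number of pairs `(x_i, y_j)` with
#' `x_i > y_j`, ties counting one half. Two-sided throughout. With
#' `method = "auto"` the exact distribution is enumerated when both samples
#' have at most 8 observations and the pooled data contain no ties; otherwise
#' the normal approximation with continuity and tie correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param method `"auto"` (default), `"exact"`, or `"normal"`.
#' @param alpha_adjusted Significance threshold recorded alongside the result
#'   (e.g. a Bonferroni-adjusted level); default 0.05.
#' @return One-row data frame with columns `W`, `p`, `n_x`, `n_y`,
#'   `alpha_adjusted`, `significant`.
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal"),
                         alpha_adjusted = 0.05) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  x <- as.numeric(x); y <- as.numeric(y)
  n_x <- length(x); n_y <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    # every pairwise comparison is a tie: no evidence either way
    return(mw_row(n_x * n_y / 2, 1, n_x, n_y, alpha_adjusted))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- switch(method,
                  exact = TRUE,
                  normal = FALSE,
                  auto = n_x <= 8 && n_y <= 8 && !ties)
  if (exact && ties)
    stop("exact method is unavailable with ties; use method = 'normal'")
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                           alternative = "two.sided")
  mw_row(unname(ht$statistic), ht$p.value, n_x, n_y, alpha_adjusted)
}

mw_row <- function(W, p, n_x, n_y, alpha_adjusted) {
  data.frame(W = W, p = p, n_x = n_x, n_y = n_y,
             alpha_adjusted = alpha_adjusted,
             significant = p < alpha_adjusted)
}

#' Bonferroni-adjusted significance level
#'
#' Divides the family-wise level by the number of tests; e.g. 0.05 over the
#' 13 AOIs of a 12-lead ECG (leads plus rhythm strip) gives 0.00385,
#' conventionally reported as 0.004.
#'
#' @param alpha Family-wise level in `(0, 1)`.
#' @param m Number of tests, `>= 1`.
#' @return The adjusted per-test level `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Per-AOI fixation-duration group comparisons
#'
#' For every AOI, pools the individual fixation durations landing in that AOI
#' by interpretation group and runs a two-sided Mann-Whitney test
#' (correct vs. incorrect) at the Bonferroni-adjusted level
#' `alpha / n_AOIs`. AOIs never fixated by one of the groups are flagged
#' untestable rather than failing the whole table.
#'
#' @param fixations Fixation data frame (one stimulus).
#' @param groups Group-assignment data frame from [read_groups()].
#' @param aoiset The stimulus's [aoiset()].
#' @param alpha Family-wise level, default 0.05.
#' @return Data frame with one row per AOI: `aoi`, `n_correct`,
#'   `n_incorrect`, `W`, `p`, `alpha_adjusted`, `significant`, `testable`.
#' @export
per_aoi_duration_tests <- function(fixations, groups, aoiset, alpha = 0.05) {
  stopifnot(inherits(aoiset, "aoiset"))
  aoi <- assign_aoi(fixations$x, fixations$y, aoiset)
  grp <- group_lookup(groups, fixations$participant, fixations$stimulus)
  if (anyNA(grp))
    stop("participant(s) without group assignment: ",
         paste(unique(fixations$participant[is.na(grp)]), collapse = ", "))
  labels <- aoiset$aois$label
  alpha_adj <- bonferroni_alpha(alpha, length(labels))
  rows <- lapply(labels, function(lab) {
    dx <- fixations$duration_ms[aoi == lab & grp == "correct"]
    dy <- fixations$duration_ms[aoi == lab & grp == "incorrect"]
    if (!length(dx) || !length(dy)) {
      return(data.frame(aoi = lab, n_correct = length(dx),
                        n_incorrect = length(dy), W = NA_real_, p = NA_real_,
                        alpha_adjusted = alpha_adj, significant = NA,
                        testable = FALSE))
    }
    mw <- mann_whitney(dx, dy, method = "normal", alpha_adjusted = alpha_adj)
    data.frame(aoi = lab, n_correct = length(dx), n_incorrect = length(dy),
               W = mw$W, p = mw$p, alpha_adjusted = alpha_adj,
               significant = mw$significant, testable = TRUE)
  })
  do.call(rbind, rows)
}

group_lookup <- function(groups, participant, stimulus) {
  key <- paste(groups$participant, groups$stimulus, sep = "\r")
  as.character(groups$group)[match(paste(participant, stimulus, sep = "\r"), key)]
}

#' Compare average within-group Levenshtein distances between groups
#'
#' Tests whether one interpretation group's scanpaths are more variable
#' (mutually distant) than the other's. With the default observation unit,
#' `per-participant-mean`, each participant contributes the mean Levenshtein
#' distance to their same-group peers; with `pooled-pairs` the observations
#' are all within-group pairwise distances. The two observation sets are then
#' compared with a two-sided Mann-Whitney test.
#'
#' @param matrix Distance matrix from [pairwise_distances()] (raw counts).
#' @param groups Group-assignment data frame covering the matrix's
#'   participants for the matrix's stimulus.
#' @param unit `"per-participant-mean"` (default) or `"pooled-pairs"`.
#' @param stimulus Stimulus id used to look up groups; defaults to the single
#'   stimulus present in `groups`.
#' @return List with `test` (one-row [mann_whitney()] result, x = correct
#'   group) and `summary` (per-group n, mean, sample SD of the observations).
#' @export
group_distance_test <- function(matrix, groups,
                                unit = c("per-participant-mean", "pooled-pairs"),
                                stimulus = NULL) {
  unit <- match.arg(unit)
  ids <- rownames(matrix)
  if (is.null(stimulus)) {
    stims <- unique(groups$stimulus)
    if (length(stims) != 1L)
      stop("groups table spans multiple stimuli; pass `stimulus`")
    stimulus <- stims
  }
  grp <- group_lookup(groups, ids, stimulus)
  if (anyNA(grp))
    stop("participant(s) without group assignment: ",
         paste(ids[is.na(grp)], collapse = ", "))
  obs <- lapply(c("correct", "incorrect"), function(g) {
    members <- which(grp == g)
    if (!length(members)) stop("group '", g, "' is empty")
    sub <- matrix[members, members, drop = FALSE]
    if (unit == "per-participant-mean") {
      if (length(members) < 2L)
        stop("group '", g, "' has a single participant; ",
             "per-participant-mean needs peers (use unit = 'pooled-pairs')")
      rowSums(sub) / (length(members) - 1L)
    } else {
      sub[upper.tri(sub)]
    }
  })
  names(obs) <- c("correct", "incorrect")
  test <- mann_whitney(obs$correct, obs$incorrect, method = "normal")
  summary <- data.frame(
    group = names(obs),
    n_obs = vapply(obs, length, integer(1)),
    mean = vapply(obs, mean, numeric(1)),
    sd = vapply(obs, function(v) if (length(v) > 1) stats::sd(v) else 0,
                numeric(1)),
    row.names = NULL
  )
  list(test = test, summary = summary, unit = unit)
}
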