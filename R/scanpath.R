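#' Sentinel token for fixations landing outside every AOI
#'
#' @return The single-token string used to mark off-AOI fixations.
#' @export
off_aoi <- function() ".off"

#' Map fixation coordinates to AOI labels
#'
#' Returns, for each point, the label of the first AOI (in AOI-set order)
#' whose half-open rectangle `[x0, x1) x [y0, y1)` contains it, or the
#' [off_aoi()] sentinel if none does. Total function: never errors on
#' out-of-bounds points.
#'
#' @param x,y Numeric vectors of pixel coordinates (origin top-left,
#'   y downward).
#' @param aoiset An [aoiset()].
#' @return Character vector of AOI labels / sentinels, same length as `x`.
#' @export
assign_aoi <- function(x, y, aoiset) {
  stopifnot(inherits(aoiset, "aoiset"), length(x) == length(y))
  out <- rep(off_aoi(), length(x))
  undecided <- rep(TRUE, length(x))
  a <- aoiset$aois
  for (i in seq_len(nrow(a))) {
    hit <- undecided &
      x >= a$x0[i] & x < a$x1[i] &
      y >= a$y0[i] & y < a$y1[i]
    out[hit] <- a$label[i]
    undecided <- undecided & !hit
    if (!any(undecided)) break
  }
  out
}

#' Build a scanpath from one participant's fixations
#'
#' A scanpath is the ordered sequence of AOI labels visited by a participant's
#' fixations on one stimulus, representable as a token string (e.g.
#' `{M,M,I,I,M,...}`). Fixations that land outside every AOI are either
#' dropped (default; the resulting string contains only AOI labels) or kept
#' as the [off_aoi()] sentinel token for sensitivity analyses.
#'
#' @param fixations Fixation data frame for exactly one participant x
#'   stimulus, sorted by onset.
#' @param aoiset The stimulus's [aoiset()].
#' @param off_policy `"drop"` (default) or `"keep"`.
#' @return An object of class `scanpath`: list with `participant`, `stimulus`,
#'   `tokens` (character vector) and `truncated` flag.
#' @export
build_scanpath <- function(fixations, aoiset, off_policy = c("drop", "keep")) {
  off_policy <- match.arg(off_policy)
  stopifnot(inherits(aoiset, "aoiset"))
  if (nrow(fixations) == 0L) {
    return(new_scanpath(NA_character_, aoiset$stimulus, character(0)))
  }
  if (length(unique(fixations$participant)) != 1L ||
      length(unique(fixations$stimulus)) != 1L)
    stop("fixations must belong to a single participant x stimulus")
  if (is.unsorted(fixations$onset_ms, strictly = TRUE))
    stop("fixations must be sorted by strictly increasing onset")
  tokens <- assign_aoi(fixations$x, fixations$y, aoiset)
  if (off_policy == "drop") tokens <- tokens[tokens != off_aoi()]
  new_scanpath(fixations$participant[1], fixations$stimulus[1], tokens)
}

new_scanpath <- function(participant, stimulus, tokens, truncated = FALSE) {
  structure(list(participant = participant, stimulus = stimulus,
                 tokens = as.character(tokens), truncated = truncated),
            class = "scanpath")
}

#' @export
print.scanpath <- function(x, ...) {
  cat(sprintf("<scanpath> %s @ %s [%d tokens%s]: {%s}\n",
              x$participant, x$stimulus, length(x$tokens),
              if (x$truncated) ", truncated" else "",
              paste(x$tokens, collapse = ",")))
  invisible(x)
}

#' Truncate (collapse) a scanpath
#'
#' Collapses every maximal run of identical consecutive tokens to a single
#' token, removing fixation frequency while retaining visit order:
#' `{M,M,M,B,B,A,B,C}` becomes `{M,B,A,B,C}`. Idempotent, never lengthens a
#' sequence.
#'
#' @param scanpath A `scanpath` object or a bare character token vector.
#' @return Same type as the input, with the `truncated` flag set for
#'   `scanpath` objects.
#' @export
truncate_scanpath <- function(scanpath) {
  if (inherits(scanpath, "scanpath")) {
    out <- scanpath
    out$tokens <- collapse_runs(scanpath$tokens)
    out$truncated <- TRUE
    return(out)
  }
  collapse_runs(as.character(scanpath))
}

collapse_runs <- function(tokens) {
  if (!length(tokens)) return(tokens)
  rle(tokens)$values
}

scanpath_tokens <- function(x) {
  if (inherits(x, "scanpath")) x$tokens else as.character(x)
}

#' Levenshtein distance between two token sequences
#'
#' Minimum number of unit-cost insertions, deletions and substitutions
#' required to transform one token sequence into the other. Tokens are
#' compared as whole labels, so multi-character AOI names are single symbols.
#'
#' @param a,b `scanpath` objects or character token vectors.
#' @return Non-negative integer distance.
#' @seealso [levenshtein_reference()] for the naive recursive reference.
#' @export
levenshtein <- function(a, b) {
  a <- scanpath_tokens(a); b <- scanpath_tokens(b)
  alphabet <- unique(c(a, b))
  lev_dp_cpp(match(a, alphabet), match(b, alphabet))
}

#' Reference Levenshtein distance (naive recursion)
#'
#' Memoisation-free recursive evaluation of the edit-distance recurrence.
#' Exponential time; intended as an independent reference for validating the
#' dynamic-programming implementation on short sequences, not for analysis
#' use.
#'
#' @inheritParams levenshtein
#' @return Non-negative integer distance.
#' @export
levenshtein_reference <- function(a, b) {
  a <- scanpath_tokens(a); b <- scanpath_tokens(b)
  alphabet <- unique(c(a, b))
  lev_rec_cpp(match(a, alphabet), match(b, alphabet))
}

#' Pairwise Levenshtein distance matrix
#'
#' Compares every participant's scanpath against every other participant's
#' for one stimulus, producing a symmetric matrix with zero diagonal suitable
#' for simultaneous visual comparison of the whole group.
#'
#' @param scanpaths List of `scanpath` objects, one per participant, all for
#'   the same stimulus.
#' @return A numeric matrix with participant labels as dimnames and attribute
#'   `normalized = FALSE`.
#' @export
pairwise_distances <- function(scanpaths) {
  if (length(scanpaths) < 2L) stop("need at least 2 scanpaths")
  stopifnot(all(vapply(scanpaths, inherits, logical(1), "scanpath")))
  ids <- vapply(scanpaths, function(s) s$participant, character(1))
  if (anyDuplicated(ids))
    stop("duplicate participant(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stims <- unique(vapply(scanpaths, function(s) s$stimulus, character(1)))
  if (length(stims) != 1L)
    stop("scanpaths span multiple stimuli: ", paste(stims, collapse = ", "))
  n <- length(scanpaths)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- levenshtein(scanpaths[[i]], scanpaths[[j]])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  attr(m, "normalized") <- FALSE
  m
}

#' Normalise a distance matrix by its maximum
#'
#' Divides every entry by the matrix maximum so that all values lie in
#' `[0, 1]` and (for a non-degenerate matrix) the largest distance maps to 1,
#' allowing several matrices to share one visual scale. An all-zero matrix is
#' returned unchanged, flagged normalised.
#'
#' @param matrix Distance matrix from [pairwise_distances()].
#' @return The normalised matrix, attribute `normalized = TRUE` and
#'   `norm_max` recording the divisor.
#' @export
normalize_distmat <- function(matrix) {
  if (isTRUE(attr(matrix, "normalized")))
    stop("matrix is already normalized")
  mx <- max(matrix)
  out <- if (mx > 0) matrix / mx else matrix
  attr(out, "normalized") <- TRUE
  attr(out, "norm_max") <- mx
  out
}

#' Summarise scanpath lengths
#'
#' Reports the mean, sample standard deviation (n-1 denominator; 0 for a
#' single scanpath), mode (most frequent length, smallest on a tie) and range
#' (max minus min, a single number) of scanpath lengths, optionally after
#' truncation.
#'
#' @param scanpaths List of `scanpath` objects (or character token vectors).
#' @param truncated If `TRUE`, lengths are measured after
#'   [truncate_scanpath()].
#' @return One-row data frame with columns `mean`, `sd`, `mode`, `range`, `n`.
#' @export
length_summary <- function(scanpaths, truncated = FALSE) {
  if (!length(scanpaths)) stop("need at least one scanpath")
  lens <- vapply(scanpaths, function(s) {
    tok <- scanpath_tokens(s)
    if (truncated) tok <- collapse_runs(tok)
    length(tok)
  }, integer(1))
  tab <- table(lens)
  modes <- as.integer(names(tab)[tab == max(tab)])
  data.frame(mean = mean(lens),
             sd = if (length(lens) > 1L) stats::sd(lens) else 0,
             mode = min(modes),
             range = max(lens) - min(lens),
             n = length(lens))
}

#' Export scanpaths as token strings
#'
#' Writes one line per participant in the form
#' `participant<TAB>M,M,I,I,...`.
#'
#' @param scanpaths List of `scanpath` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scanpaths <- function(scanpaths, path) {
  lines <- vapply(scanpaths, function(s) {
    paste0(s$participant, "\t", paste(s$tokens, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
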