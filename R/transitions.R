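#' Directed AOI transition counts for one scanpath
#'
#' Counts, for every ordered AOI pair `(from, to)`, the number of adjacent
#' token pairs in the scanpath, including self-transitions (consecutive
#' fixations within the same AOI). Use un-truncated scanpaths: truncation
#' removes exactly the self-transitions. For a scanpath of `n` tokens the
#' total count is `n - 1` (`0` if `n <= 1`).
#'
#' @param scanpath A `scanpath` object or character token vector.
#' @param alphabet Character vector fixing AOI order in the matrix; every
#'   scanpath token must be in it.
#' @return Integer matrix `counts[from, to]` with `alphabet` dimnames.
#' @export
transition_matrix <- function(scanpath, alphabet) {
  tokens <- scanpath_tokens(scanpath)
  bad <- setdiff(tokens, alphabet)
  if (length(bad))
    stop("scanpath token(s) outside alphabet: ", paste(unique(bad), collapse = ", "))
  k <- length(alphabet)
  m <- matrix(0L, k, k, dimnames = list(alphabet, alphabet))
  n <- length(tokens)
  if (n >= 2L) {
    from <- match(tokens[-n], alphabet)
    to <- match(tokens[-1L], alphabet)
    for (i in seq_along(from)) m[from[i], to[i]] <- m[from[i], to[i]] + 1L
  }
  m
}

#' Aggregate transition counts over many scanpaths
#'
#' Element-wise sum of per-scanpath transition matrices; the grand total is
#' the sum over scanpaths of (length - 1).
#'
#' @param scanpaths List of `scanpath` objects / token vectors.
#' @inheritParams transition_matrix
#' @return Integer matrix `counts[from, to]`.
#' @export
aggregate_transitions <- function(scanpaths, alphabet) {
  k <- length(alphabet)
  total <- matrix(0L, k, k, dimnames = list(alphabet, alphabet))
  for (s in scanpaths) total <- total + transition_matrix(s, alphabet)
  total
}

#' Extract a chord-diagram edge list from a transition matrix
#'
#' Restricts the matrix to a subset of AOIs (e.g. the anterior leads V1-V4
#' carrying the salient information) and returns its nonzero directed edges,
#' self-loops included, ordered by `from` then `to` in alphabet order.
#'
#' @param matrix Transition matrix from [transition_matrix()] or
#'   [aggregate_transitions()].
#' @param keep_labels Labels to keep; must be a subset of the matrix labels.
#' @return Data frame with columns `from`, `to`, `count` (zero-count edges
#'   omitted).
#' @export
subset_and_edges <- function(matrix, keep_labels) {
  labels <- rownames(matrix)
  bad <- setdiff(keep_labels, labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  keep <- labels[labels %in% keep_labels]  # alphabet order
  block <- matrix[keep, keep, drop = FALSE]
  edges <- expand.grid(to = keep, from = keep, stringsAsFactors = FALSE)
  edges <- edges[, c("from", "to")]
  edges$count <- as.vector(t(block))
  edges <- edges[order(match(edges$from, keep), match(edges$to, keep)), ]
  edges <- edges[edges$count > 0, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write a transition edge list as CSV
#'
#' @param edges Data frame from [subset_and_edges()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.csv(edges[, c("from", "to", "count")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
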