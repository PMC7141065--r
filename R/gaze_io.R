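#' Read a fixation table
#'
#' Parses a tab-separated fixation export (one row per fixation) into a
#' validated fixation data frame. The canonical dialect has a single header
#' row with columns `participant`, `stimulus`, `onset_ms`, `x`, `y`,
#' `duration_ms`; other exports (e.g. Tobii-style column names) can be adapted
#' via `col_map`. Rows violating the fixation invariants (non-numeric values,
#' `duration_ms <= 0`, `onset_ms < 0`, or an onset that does not strictly
#' increase within a participant x stimulus series) are reported and skipped
#' rather than aborting the read: real gaze exports contain dropouts.
#'
#' @param path Path to a TSV file with a header row.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(participant = "ParticipantName", duration_ms = "GazeEventDuration")`.
#' @return A `data.frame` with columns `participant`, `stimulus`, `onset_ms`,
#'   `x`, `y`, `duration_ms`, in file order. Rejected rows are attached as
#'   attribute `"rejected"` (a data frame with `line` and `reason`); a warning
#'   summarises them.
#' @seealso [write_fixations()], [build_scanpath()]
#' @export
read_fixations <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("fixation file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("participant", "stimulus", "onset_ms", "x", "y", "duration_ms")
  wanted <- stats::setNames(canonical, canonical)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), canonical)
    if (length(bad)) stop("unknown canonical column(s) in col_map: ",
                          paste(bad, collapse = ", "))
    wanted[names(col_map)] <- col_map
  }
  missing <- wanted[!wanted %in% names(raw)]
  if (length(missing)) {
    stop("fixation file is missing required column(s): ",
         paste(sprintf("'%s'", missing), collapse = ", "))
  }
  fx <- data.frame(
    participant = as.character(raw[[wanted["participant"]]]),
    stimulus    = as.character(raw[[wanted["stimulus"]]]),
    onset_ms    = suppressWarnings(as.numeric(raw[[wanted["onset_ms"]]])),
    x           = suppressWarnings(as.numeric(raw[[wanted["x"]]])),
    y           = suppressWarnings(as.numeric(raw[[wanted["y"]]])),
    duration_ms = suppressWarnings(as.numeric(raw[[wanted["duration_ms"]]])),
    stringsAsFactors = FALSE
  )
  line <- seq_len(nrow(fx)) + 1L  # header is line 1
  reason <- rep(NA_character_, nrow(fx))
  num_bad <- is.na(fx$onset_ms) | is.na(fx$x) | is.na(fx$y) | is.na(fx$duration_ms)
  reason[num_bad] <- "non-numeric onset/coordinate/duration"
  dur_bad <- !num_bad & fx$duration_ms <= 0
  reason[dur_bad] <- "duration_ms <= 0"
  onset_bad <- !num_bad & !dur_bad & fx$onset_ms < 0
  reason[onset_bad] <- "onset_ms < 0"
  # onsets must strictly increase within participant x stimulus, in file order
  ok <- is.na(reason)
  key <- paste(fx$participant, fx$stimulus, sep = "\r")
  last <- new.env(parent = emptyenv())
  for (i in which(ok)) {
    prev <- get0(key[i], envir = last, ifnotfound = -Inf)
    if (fx$onset_ms[i] <= prev) {
      reason[i] <- "onset_ms not strictly increasing within participant x stimulus"
    } else {
      assign(key[i], fx$onset_ms[i], envir = last)
    }
  }
  keep <- is.na(reason)
  rejected <- data.frame(line = line[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- fx[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  if (nrow(rejected)) {
    warning(sprintf("rejected %d of %d fixation row(s); see attr(, 'rejected') (first: line %d, %s)",
                    nrow(rejected), nrow(fx), rejected$line[1], rejected$reason[1]))
  }
  out
}

#' Write a fixation table
#'
#' Writes the canonical tab-separated fixation dialect read by
#' [read_fixations()].
#'
#' @param fixations Fixation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  cols <- c("participant", "stimulus", "onset_ms", "x", "y", "duration_ms")
  stopifnot(all(cols %in% names(fixations)))
  utils::write.table(fixations[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct an AOI set
#'
#' An AOI set is an ordered collection of labelled, axis-aligned rectangles
#' over one stimulus, e.g. the 13 regions of a 12-lead ECG printout (one per
#' lead plus the rhythm strip). Rectangles are half-open,
#' `[x0, x1) x [y0, y1)` in pixel coordinates with the origin at the top-left
#' and y increasing downward, so rectangles that tile the stimulus never
#' double-claim a point.
#'
#' @param stimulus Stimulus identifier.
#' @param width,height Stimulus dimensions in pixels.
#' @param aois Data frame with columns `label`, `x0`, `y0`, `x1`, `y1`.
#' @return An object of class `aoiset`.
#' @export
aoiset <- function(stimulus, width, height, aois) {
  stopifnot(is.data.frame(aois),
            all(c("label", "x0", "y0", "x1", "y1") %in% names(aois)))
  aois$label <- as.character(aois$label)
  if (anyDuplicated(aois$label))
    stop("duplicate AOI label(s): ",
         paste(unique(aois$label[duplicated(aois$label)]), collapse = ", "))
  if (any(aois$x1 <= aois$x0) || any(aois$y1 <= aois$y0))
    stop("degenerate AOI rectangle(s): need x1 > x0 and y1 > y0")
  if (any(aois$x0 < 0) || any(aois$y0 < 0) ||
      any(aois$x1 > width) || any(aois$y1 > height))
    stop("AOI rectangle(s) outside stimulus bounds ", width, "x", height)
  structure(
    list(stimulus = as.character(stimulus),
         width = as.numeric(width), height = as.numeric(height),
         aois = aois[, c("label", "x0", "y0", "x1", "y1")]),
    class = "aoiset"
  )
}

#' @export
print.aoiset <- function(x, ...) {
  cat(sprintf("<aoiset> stimulus '%s' (%gx%g px), %d AOIs: %s\n",
              x$stimulus, x$width, x$height, nrow(x$aois),
              paste(x$aois$label, collapse = " ")))
  invisible(x)
}

#' Read AOI definitions
#'
#' Reads a CSV of labelled rectangles with columns
#' `stimulus, label, x0, y0, x1, y1, stim_w, stim_h` and returns the
#' [aoiset()] for one stimulus, preserving file order of the AOIs.
#'
#' @param path Path to the CSV file.
#' @param stimulus Which stimulus to extract; may be omitted when the file
#'   describes a single stimulus.
#' @return An `aoiset`.
#' @export
read_aois <- function(path, stimulus = NULL) {
  if (!file.exists(path)) stop("AOI file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus", "label", "x0", "y0", "x1", "y1", "stim_w", "stim_h")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("AOI file is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(stimulus)) {
    stims <- unique(raw$stimulus)
    if (length(stims) != 1L)
      stop("AOI file describes ", length(stims),
           " stimuli; pass `stimulus` to pick one")
    stimulus <- stims
  }
  sel <- raw[raw$stimulus == stimulus, , drop = FALSE]
  if (!nrow(sel)) stop("no AOIs for stimulus '", stimulus, "' in ", path)
  dims <- unique(sel[, c("stim_w", "stim_h")])
  if (nrow(dims) != 1L) stop("inconsistent stimulus dimensions in AOI file")
  aoiset(stimulus, dims$stim_w, dims$stim_h,
         sel[, c("label", "x0", "y0", "x1", "y1")])
}

#' Write AOI definitions
#'
#' @param aoiset An [aoiset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_aois <- function(aoiset, path) {
  stopifnot(inherits(aoiset, "aoiset"))
  df <- cbind(stimulus = aoiset$stimulus, aoiset$aois,
              stim_w = aoiset$width, stim_h = aoiset$height)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read group assignments
#'
#' Reads a CSV with columns `participant, stimulus, group` assigning each
#' participant x stimulus pair to the `correct` or `incorrect` interpretation
#' group.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `participant`, `stimulus`, `group`
#'   (factor with levels `correct`, `incorrect`).
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("group file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "stimulus", "group")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("group file is missing required column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(raw$group), c("correct", "incorrect"))
  if (length(bad))
    stop("unknown group value(s): ", paste(sprintf("'%s'", bad), collapse = ", "),
         " (expected 'correct' or 'incorrect')")
  key <- paste(raw$participant, raw$stimulus, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (participant, stimulus) key(s) in group file, e.g. ",
         raw$participant[duplicated(key)][1])
  out <- data.frame(participant = as.character(raw$participant),
                    stimulus = as.character(raw$stimulus),
                    group = factor(raw$group, levels = c("correct", "incorrect")),
                    stringsAsFactors = FALSE)
  out
}

#' Write group assignments
#' @param groups Data frame as returned by [read_groups()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  stopifnot(all(c("participant", "stimulus", "group") %in% names(groups)))
  utils::write.csv(groups[, c("participant", "stimulus", "group")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a labelled square matrix as CSV
#'
#' Writes a square matrix with a labelled header row and label column, at a
#' precision (15 significant digits) that round-trips through [read_matrix()]
#' well below 1e-9.
#'
#' @param matrix Square numeric matrix.
#' @param labels Character vector of row/column labels, one per matrix row.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, labels, path) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("matrix must be square")
  if (length(labels) != nrow(matrix))
    stop("got ", length(labels), " labels for a matrix of order ", nrow(matrix))
  lines <- c(paste(c("", labels), collapse = ","),
             vapply(seq_len(nrow(matrix)), function(i) {
               paste(c(labels[i], sprintf("%.15g", matrix[i, ])), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled square matrix written by [write_matrix()]
#'
#' @param path Path to the CSV file.
#' @return Numeric matrix with dimnames set to the stored labels.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) stop("stored matrix is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("stored matrix row and column labels disagree")
  m
}
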