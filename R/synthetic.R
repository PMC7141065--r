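#' Default 12-lead ECG AOI layout
#'
#' Thirteen labelled rectangles tiling the stimulus: a 4-column x 3-row block
#' of lead AOIs over the upper three quarters of the image, plus a full-width
#' bottom strip for the rhythm strip (a lead repeated for a longer period
#' across the bottom of a printed ECG). Labels are `A`..`M` in reading order
#' (left-to-right, top-to-bottom; `M` is the rhythm strip), mirroring the
#' lead order I, II, III, aVR, aVL, aVF, V1..V6.
#'
#' @param width,height Stimulus dimensions in pixels (default 1280 x 960).
#' @return An [aoiset()] of 13 AOIs covering the stimulus exactly.
#' @export
default_ecg_layout <- function(width = 1280, height = 960) {
  strip_h <- height / 4
  lead_h <- (height - strip_h) / 3
  lead_w <- width / 4
  labs <- LETTERS[1:12]
  grid <- expand.grid(col = 0:3, row = 0:2)
  aois <- data.frame(
    label = labs,
    x0 = grid$col * lead_w,
    y0 = grid$row * lead_h,
    x1 = (grid$col + 1) * lead_w,
    y1 = (grid$row + 1) * lead_h
  )
  aois <- rbind(aois, data.frame(label = "M", x0 = 0, y0 = height - strip_h,
                                 x1 = width, y1 = height))
  aoiset("ecg", width, height, aois)
}

#' Construct a gaze-generating model
#'
#' A first-order Markov model of AOI visits plus simple spatial and temporal
#' marginals, sufficient to emulate the structure of a multi-participant
#' ECG-reading study: scanpath lengths are drawn from a rounded lognormal
#' (heavy right skew), fixation durations from a lognormal, and fixation
#' positions from a per-AOI Gaussian hotspot mixed with a uniform component.
#'
#' @param aoiset The [aoiset()] the model walks over.
#' @param trans Row-stochastic AOI x AOI transition matrix (rows sum to 1).
#' @param initial_dist Probability vector over AOIs for the first fixation.
#' @param duration_meanlog,duration_sdlog Lognormal parameters of fixation
#'   duration in ms.
#' @param hotspots Data frame with one row per AOI: `cx`, `cy` (hotspot
#'   centre, px) and `sd` (isotropic spatial SD, px). Default: AOI centres,
#'   SD one sixth of the smaller AOI side.
#' @param p_uniform Probability a fixation is placed uniformly in its AOI
#'   instead of at the hotspot.
#' @param length_meanlog,length_sdlog Lognormal parameters of scanpath length
#'   (rounded, minimum 1). Defaults are moment-matched to a mean of 23 AOI
#'   visits with SD 18.25.
#' @return Object of class `gaze_model`.
#' @export
gaze_model <- function(aoiset,
                       trans = NULL,
                       initial_dist = NULL,
                       duration_meanlog = 5.52, duration_sdlog = 0.606,
                       hotspots = NULL,
                       p_uniform = 0.2,
                       length_meanlog = 2.8913, length_sdlog = 0.6989) {
  stopifnot(inherits(aoiset, "aoiset"))
  k <- nrow(aoiset$aois)
  labs <- aoiset$aois$label
  if (is.null(trans)) trans <- reading_order_transitions(k)
  trans <- as.matrix(trans)
  stopifnot(nrow(trans) == k, ncol(trans) == k)
  if (any(abs(rowSums(trans) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1")
  if (any(trans < 0)) stop("transition probabilities must be non-negative")
  dimnames(trans) <- list(labs, labs)
  if (is.null(initial_dist)) {
    initial_dist <- c(0.6, rep(0.4 / (k - 1), k - 1))
  }
  if (abs(sum(initial_dist) - 1) > 1e-9 || any(initial_dist < 0))
    stop("initial_dist must be a probability vector")
  if (is.null(hotspots)) {
    a <- aoiset$aois
    hotspots <- data.frame(cx = (a$x0 + a$x1) / 2, cy = (a$y0 + a$y1) / 2,
                           sd = pmin(a$x1 - a$x0, a$y1 - a$y0) / 6)
  }
  stopifnot(nrow(hotspots) == k, all(hotspots$sd > 0),
            p_uniform >= 0, p_uniform <= 1,
            duration_sdlog > 0, length_sdlog > 0)
  structure(list(aoiset = aoiset, trans = trans,
                 initial_dist = as.numeric(initial_dist),
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog,
                 hotspots = hotspots, p_uniform = p_uniform,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog),
            class = "gaze_model")
}

#' Reading-order transition matrix
#'
#' A cyclic first-order chain over the AOIs in their layout order: with
#' probability `p_self` the gaze re-fixates the current AOI (a repeat
#' fixation within a lead; the defaults give mean run length ~1.8, the run
#' structure typical of AOI strings from ECG reading), with `p_next` it moves
#' to the next AOI in reading order (wrapping from the last back to the
#' first), and the remaining mass is spread uniformly over all other AOIs
#' (cross-referencing jumps). `p_self = 0, p_next = 1` gives the idealized
#' strictly systematic scan used as the reference reader in the group
#' separation experiments.
#'
#' @param n_aois Number of AOIs, `>= 3`.
#' @param p_self,p_next Probabilities of a repeat fixation and of the
#'   next-in-order step; `p_self + p_next <= 1`.
#' @return Row-stochastic `n_aois x n_aois` matrix.
#' @export
reading_order_transitions <- function(n_aois, p_self = 0.45, p_next = 0.30) {
  stopifnot(n_aois >= 3, p_self >= 0, p_next >= 0, p_self + p_next <= 1)
  p_rest <- (1 - p_self - p_next) / (n_aois - 2)
  m <- matrix(p_rest, n_aois, n_aois)
  diag(m) <- p_self
  for (i in seq_len(n_aois)) m[i, if (i < n_aois) i + 1L else 1L] <- p_next
  m
}

#' Idealized systematic reader model
#'
#' A [gaze_model()] whose AOI walk is the deterministic taught reading
#' sequence: start at the first AOI and step through the layout in reading
#' order, cycling. All scanpath variability then comes from scanpath length,
#' so two such readers' token sequences differ exactly by their length
#' difference. This is the reference "correct reader" for the group
#' separation experiments: blending it toward a uniform walk with
#' [blend_toward_uniform()] produces an "incorrect reader" whose scanpaths
#' are mutually more distant, with the blend weight as the single separation
#' dial.
#'
#' @param aoiset The stimulus [aoiset()] (default [default_ecg_layout()]).
#' @param ... Further arguments passed to [gaze_model()].
#' @return A `gaze_model`.
#' @export
systematic_gaze_model <- function(aoiset = default_ecg_layout(), ...) {
  k <- nrow(aoiset$aois)
  gaze_model(aoiset,
             trans = reading_order_transitions(k, p_self = 0, p_next = 1),
             initial_dist = c(1, rep(0, k - 1)),
             ...)
}

#' Blend a model's dynamics toward uniform
#'
#' Interpolates the transition matrix (and initial distribution) between the
#' model's own dynamics and a uniform walk:
#' `(1 - lambda) * P + lambda * U`. `lambda = 0` returns the model
#' unchanged; `lambda = 1` is a memoryless uniform scan. Used to construct an
#' "incorrect-group" model with greater scanpath variability than the
#' systematic "correct-group" model.
#'
#' @param model A [gaze_model()].
#' @param lambda Blend weight in `[0, 1]`.
#' @return A new `gaze_model`.
#' @export
blend_toward_uniform <- function(model, lambda) {
  stopifnot(inherits(model, "gaze_model"), lambda >= 0, lambda <= 1)
  k <- nrow(model$trans)
  model$trans <- (1 - lambda) * model$trans + lambda / k
  model$initial_dist <- (1 - lambda) * model$initial_dist + lambda / k
  model
}

#' Simulate one participant's fixations
#'
#' Draws a scanpath length, walks the AOI Markov chain, and emits one
#' fixation per step: lognormal duration, position from the AOI's hotspot
#' mixture clipped inside the AOI rectangle, onsets cumulative with a small
#' inter-fixation gap. Fully reproducible for a given seed.
#'
#' @param model A [gaze_model()].
#' @param participant_id,stimulus_id Identifiers stamped on the output.
#' @param seed Integer seed for this participant.
#' @return Fixation data frame (columns as [read_fixations()]).
#' @export
simulate_participant <- function(model, participant_id, stimulus_id, seed) {
  stopifnot(inherits(model, "gaze_model"))
  set.seed(as.integer(seed))
  k <- nrow(model$trans)
  n <- max(1L, round(stats::rlnorm(1, model$length_meanlog, model$length_sdlog)))
  state <- integer(n)
  state[1] <- sample.int(k, 1, prob = model$initial_dist)
  for (i in seq_len(n - 1L))
    state[i + 1L] <- sample.int(k, 1, prob = model$trans[state[i], ])
  dur <- stats::rlnorm(n, model$duration_meanlog, model$duration_sdlog)
  a <- model$aoiset$aois[state, ]
  hs <- model$hotspots[state, ]
  uni <- stats::runif(n) < model$p_uniform
  x <- ifelse(uni, stats::runif(n, a$x0, a$x1),
              stats::rnorm(n, hs$cx, hs$sd))
  y <- ifelse(uni, stats::runif(n, a$y0, a$y1),
              stats::rnorm(n, hs$cy, hs$sd))
  # clamp into the half-open AOI rectangle so token recovery is exact
  eps <- 1e-6
  x <- pmin(pmax(x, a$x0), a$x1 - eps)
  y <- pmin(pmax(y, a$y0), a$y1 - eps)
  gap <- stats::runif(n, 20, 80)
  onset <- cumsum(c(0, (dur + gap)[-n]))
  data.frame(participant = as.character(participant_id),
             stimulus = as.character(stimulus_id),
             onset_ms = onset, x = x, y = y, duration_ms = dur,
             stringsAsFactors = FALSE)
}

#' Simulate a two-group study
#'
#' Simulates `n_correct` participants from one model and `n_incorrect` from
#' another (typically a [blend_toward_uniform()] variant), with stable
#' per-participant seeds derived from the master seed, so adding participants
#' to one group never perturbs the data of existing participants in either
#' group.
#'
#' @param model_correct,model_incorrect [gaze_model()]s sharing one AOI set.
#' @param n_correct,n_incorrect Group sizes, `>= 1`.
#' @param seed Master integer seed.
#' @param stimulus_id Stimulus identifier stamped on the output.
#' @return List with `fixations` (combined data frame) and `groups`
#'   (assignment data frame with participants `C01..`, `I01..`).
#' @export
simulate_study <- function(model_correct, model_incorrect,
                           n_correct, n_incorrect, seed,
                           stimulus_id = "ecg") {
  stopifnot(n_correct >= 1, n_incorrect >= 1)
  sim_group <- function(model, n, prefix, offset) {
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    fx <- lapply(seq_len(n), function(i) {
      simulate_participant(model, ids[i], stimulus_id,
                           participant_seed(seed, offset + i))
    })
    list(fix = do.call(rbind, fx), ids = ids)
  }
  cor <- sim_group(model_correct, n_correct, "C", 0L)
  inc <- sim_group(model_incorrect, n_incorrect, "I", 100000L)
  groups <- data.frame(
    participant = c(cor$ids, inc$ids),
    stimulus = stimulus_id,
    group = factor(rep(c("correct", "incorrect"), c(n_correct, n_incorrect)),
                   levels = c("correct", "incorrect")),
    stringsAsFactors = FALSE
  )
  list(fixations = rbind(cor$fix, inc$fix), groups = groups)
}

participant_seed <- function(master, index) {
  (as.integer(master) %% 1000003L) * 2011L + index * 7L
}
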