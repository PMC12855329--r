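#' Pseudo-random expected/unexpected congruency schedule
#'
#' Generates the fixed per-block schedule of trial expectedness labels:
#' exactly `n_unexpected` trials are labelled `"unexpected"` and the rest
#' `"expected"`, in a seeded pseudo-random permutation. The 80/20 contingency
#' is realised as a fixed 40/10 count per 50-trial block rather than iid
#' draws, matching the prespecified order-sequence design.
#'
#' @param n_trials Number of trials in the block.
#' @param n_unexpected Number of `"unexpected"` trials (0 <= n_unexpected <=
#'   n_trials).
#' @param seed Integer seed; the same `(n_trials, n_unexpected, seed)` always
#'   yields the same sequence.
#' @return Character vector of length `n_trials` with values `"expected"` /
#'   `"unexpected"`.
#' @examples
#' table(make_congruency_schedule(50, 10, seed = 1))
#' @export
make_congruency_schedule <- function(n_trials, n_unexpected, seed) {
  if (!is.numeric(n_trials) || n_trials < 1 || n_trials != round(n_trials)) {
    stop("n_trials must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_unexpected) || n_unexpected < 0 ||
      n_unexpected > n_trials || n_unexpected != round(n_unexpected)) {
    stop("n_unexpected must be an integer in [0, n_trials]", call. = FALSE)
  }
  labels <- rep("expected", n_trials)
  if (n_unexpected > 0) {
    idx <- with_local_seed(seed, sample.int(n_trials, n_unexpected))
    labels[idx] <- "unexpected"
  }
  labels
}

#' Probability-controlled release-side allocation
#'
#' Block-1 rule: expected trials release from the likely (high-probability)
#' side, unexpected trials from the other side.
#'
#' @param label `"expected"` or `"unexpected"` (vectorised).
#' @param likely_side `"left"` or `"right"`: the counterbalanced
#'   high-probability side.
#' @return Release side(s), `"left"` / `"right"`.
#' @examples
#' allocate_probability_controlled("expected", "right")    # "right"
#' allocate_probability_controlled("unexpected", "right")  # "left"
#' @export
allocate_probability_controlled <- function(label, likely_side) {
  check_sides(likely_side)
  check_labels(label)
  ifelse(label == "expected", likely_side, other_side(likely_side))
}

#' Gaze-contingent (PbAC) release-side allocation
#'
#' Block-2 rule: the side the user is gazing toward at the gate time (50 ms
#' before onset) becomes the prediction; expected trials release from the
#' gazed-at side, unexpected trials from the opposite side. Gaze exactly on
#' the midline (x = 0) classifies as left (logged via a message when
#' `quiet = FALSE`). A missing gate sample falls back to `fallback_x`
#' (the last valid sample), with a message.
#'
#' @param gaze_x_at_gate Horizontal in-world gaze coordinate at the gate
#'   time, metres (positive = right of midline).
#' @param label `"expected"` or `"unexpected"`.
#' @param fallback_x Last valid gaze sample, used when `gaze_x_at_gate` is
#'   missing/non-finite.
#' @param quiet Suppress log messages.
#' @return Release side, `"left"` / `"right"`.
#' @examples
#' allocate_pbac(0.9, "expected")     # "right"
#' allocate_pbac(-0.9, "unexpected")  # "right"
#' @export
allocate_pbac <- function(gaze_x_at_gate, label, fallback_x = NULL,
                          quiet = TRUE) {
  check_labels(label)
  x <- gaze_x_at_gate
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    if (is.null(fallback_x) || !is.finite(fallback_x)) {
      stop("invalid gaze sample at gate and no valid fallback", call. = FALSE)
    }
    if (!quiet) message("gate gaze sample invalid; using last valid sample")
    x <- fallback_x
  }
  gaze_side <- if (x > 0) "right" else "left"
  if (x == 0 && !quiet) message("gaze exactly on midline; classified left")
  if (label == "expected") gaze_side else other_side(gaze_side)
}

#' Matched-order block derived from a completed PbAC block
#'
#' Block-3 rule: release sides exactly replicate, trial by trial, those of
#' the source PbAC block, and expectedness labels are inherited unchanged;
#' only the condition tag changes to `"matched"`.
#'
#' @param pbac_block A block schedule tibble (as produced during simulation)
#'   with columns `trial_index`, `congruency_label`, `release_side`; every
#'   `release_side` must be filled in.
#' @return The same tibble with `condition` (and `block`) set to
#'   `"matched"`.
#' @export
allocate_matched <- function(pbac_block) {
  if (!is.data.frame(pbac_block) || nrow(pbac_block) == 0) {
    stop("source PbAC block is empty", call. = FALSE)
  }
  need <- c("trial_index", "congruency_label", "release_side")
  if (!all(need %in% names(pbac_block))) {
    stop("source block lacks columns: ",
         paste(setdiff(need, names(pbac_block)), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(pbac_block$release_side)) {
    stop("incomplete source block: release_side missing", call. = FALSE)
  }
  out <- pbac_block
  if ("condition" %in% names(out)) out$condition <- "matched"
  if ("block" %in% names(out)) out$block <- "matched"
  out
}

#' Build the full session design
#'
#' Lays out the practice block (10 trials, 8/2 expected/unexpected) and the
#' three 50-trial experimental blocks in study order: probability-controlled,
#' PbAC, matched-order. Release sides are filled in for the
#' probability-controlled blocks; PbAC sides are determined at run time by
#' gaze, and the matched block copies them afterwards. Onset delays are drawn
#' uniformly on [0, 5] s.
#'
#' @param likely_side Counterbalanced high-probability side (block-1
#'   definition), `"left"` or `"right"`.
#' @param n_trials Trials per experimental block (default 50).
#' @param n_unexpected Unexpected trials per experimental block (default 10).
#' @param practice Include the 10-trial practice block.
#' @param seed Integer seed for schedules and onset delays.
#' @return A tibble with one row per trial: `trial_index` (within block),
#'   `block`, `condition`, `congruency_label`, `release_side` (NA where
#'   gaze-determined), `onset_delay_s`, `likely_side`.
#' @examples
#' design <- build_session_design("right", seed = 1)
#' dplyr::count(design, block, congruency_label)
#' @export
build_session_design <- function(likely_side = c("right", "left"),
                                 n_trials = 50, n_unexpected = 10,
                                 practice = TRUE, seed = 1L) {
  likely_side <- match.arg(likely_side)
  blocks <- list()
  if (practice) {
    n_p <- 10L
    n_pu <- 2L
    blocks$practice <- tibble::tibble(
      trial_index = seq_len(n_p),
      block = "practice", condition = "practice",
      congruency_label = make_congruency_schedule(n_p, n_pu, seed),
      likely_side = likely_side
    ) |>
      dplyr::mutate(release_side = allocate_probability_controlled(
        .data$congruency_label, likely_side))
  }
  mk <- function(name, sub) {
    tibble::tibble(
      trial_index = seq_len(n_trials),
      block = name, condition = name,
      congruency_label = make_congruency_schedule(n_trials, n_unexpected,
                                                  seed + sub),
      likely_side = likely_side
    )
  }
  blocks$probability <- mk("probability", 1L) |>
    dplyr::mutate(release_side = allocate_probability_controlled(
      .data$congruency_label, likely_side))
  blocks$pbac <- mk("pbac", 2L) |>
    dplyr::mutate(release_side = NA_character_)
  # matched block inherits labels and (at run time) sides from the pbac block
  blocks$matched <- blocks$pbac |>
    dplyr::mutate(block = "matched", condition = "matched")
  out <- dplyr::bind_rows(blocks)
  delays <- with_local_seed(seed + 9L, stats::runif(nrow(out), 0, 5))
  out$onset_delay_s <- delays
  out[, c("trial_index", "block", "condition", "congruency_label",
          "release_side", "onset_delay_s", "likely_side")]
}

#' Binary input sequence with periodic contingency reversals
#'
#' Builds a volatile binary sequence for model-validation studies: the
#' majority side holds within each segment (a fixed minority count per
#' segment, seeded pseudo-random positions, as in
#' [make_congruency_schedule()]) and flips between consecutive segments.
#' Reversal schedules of this kind are the standard setting in which
#' hierarchical (volatility-tracking) learners are identifiable against
#' fixed-rate ones; a single stationary 80/20 block leaves them nearly
#' equivalent.
#'
#' @param n_segments Number of stable segments.
#' @param segment_length Trials per segment.
#' @param n_minority Minority-side trials per segment.
#' @param seed Integer seed.
#' @return Binary vector of length `n_segments * segment_length`
#'   (1 = the side that is the majority in odd segments).
#' @examples
#' u <- make_reversal_sequence(6, 25, 2, seed = 1)
#' tapply(u, rep(1:6, each = 25), mean)  # alternates high/low
#' @export
make_reversal_sequence <- function(n_segments, segment_length, n_minority,
                                   seed) {
  stopifnot(n_segments >= 1)
  unlist(lapply(seq_len(n_segments), function(s) {
    lab <- make_congruency_schedule(segment_length, n_minority,
                                    seed * 131L + s)
    base <- as.integer(lab == "expected")
    if (s %% 2 == 0) 1L - base else base
  }))
}

# --- internal helpers ------------------------------------------------------

other_side <- function(side) ifelse(side == "left", "right", "left")

check_sides <- function(side) {
  if (!all(side %in% c("left", "right"))) {
    stop("side must be 'left' or 'right'", call. = FALSE)
  }
  invisible(side)
}

check_labels <- function(label) {
  if (!all(label %in% c("expected", "unexpected"))) {
    stop("label must be 'expected' or 'unexpected'", call. = FALSE)
  }
  invisible(label)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
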