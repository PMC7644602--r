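#' LED distances of the peripersonal-space task
#'
#' Eleven LEDs spaced 10 cm apart along the box, the first 5 cm from the edge
#' nearest the participant's hand, so D1 = 5 cm ... D11 = 105 cm.
#'
#' @return Numeric vector of 11 distances in cm.
#' @export
pps_distances <- function() seq(5, 105, by = 10)

# Visual sequence timing: each LED is lit 50 ms with a 200 ms inter-stimulus
# interval, i.e. one 250 ms step per LED.
.led_step_s <- 0.25

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Tactile onset time of a PPS trial
#'
#' The tactile stimulus is synchronous with the LED at `distance_index`.
#' The approaching sequence runs D11 -> D1 and the receding sequence D1 -> D11,
#' so the LED at D_i lights at step `11 - i` (approach) or `i - 1` (recede),
#' each step lasting 250 ms. Approach D_i and recede D_(12-i) are therefore
#' matched in time — the pairing the expectancy-corrected subtraction relies
#' on.
#'
#' @param distance_index Integer in 1..11.
#' @param direction `"approach"` or `"recede"`.
#' @return Onset time in seconds from trial (visual sequence) start.
#' @export
pps_onset_time <- function(distance_index, direction) {
  stopifnot(all(distance_index %in% 1:11), all(direction %in% .pps_directions))
  steps <- ifelse(direction == "approach", 11 - distance_index, distance_index - 1)
  steps * .led_step_s
}

# Shuffle labels under the constraint that no label occupies more than
# `max_run` consecutive slots. Rejection sampling off the current RNG stream;
# runs over 4 are rare for these designs so a handful of tries suffices.
shuffle_constrained <- function(labels, max_run = 4, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    ord <- sample.int(length(labels))
    r <- rle(labels[ord])
    if (max(r$lengths) <= max_run) return(ord)
  }
  stop("could not satisfy the run-length constraint in ", max_tries, " tries")
}

new_session_plan <- function(task, trials, distances_cm, iti_spec) {
  structure(
    list(task = task, trials = trials, distances_cm = distances_cm,
         iti_spec = iti_spec),
    class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat("<session_plan> task:", x$task, "-", nrow(x$trials), "trials\n")
  if (x$task == "PPS") {
    cat(" ", sum(x$trials$condition == "experimental"), "experimental /",
        sum(x$trials$condition == "baseline"), "baseline /",
        sum(x$trials$condition == "catch"), "catch;",
        length(unique(x$trials$block)), "blocks\n")
  }
  invisible(x)
}

#' Build a crossmodal-congruency (CCE) session plan
#'
#' Six trial types — tactile-only baseline, spatially congruent and spatially
#' incongruent visual cue, each for the thumb and the index finger — repeated
#' 15 times each, 90 trials in total, in a seed-controlled random order with
#' no condition cell repeated more than 4 times in a row. Inter-trial
#' intervals are drawn uniformly between 1.5 and 2.5 s.
#'
#' @param seed Integer seed; the plan is a pure function of it.
#' @return A `session_plan` whose `$trials` tibble has one row per trial.
#' @export
build_cce_session <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  cells <- expand.grid(condition = .cce_conditions, digit = .cce_digits,
                       stringsAsFactors = FALSE)
  trials <- cells[rep(seq_len(nrow(cells)), each = 15), ]
  drawn <- with_seed(seed, {
    list(ord = shuffle_constrained(paste(trials$condition, trials$digit)),
         iti = runif(nrow(trials), 1.5, 2.5))
  })
  trials <- trials[drawn$ord, ]
  plan <- tibble(
    task = "CCE",
    trial_index = seq_len(nrow(trials)),
    condition = trials$condition,
    digit = trials$digit,
    direction = NA_character_,
    distance_index = NA_integer_,
    onset_time_s = 0,
    iti_s = drawn$iti,
    block = 1L)
  new_session_plan("CCE", plan, distances_cm = NULL,
                   iti_spec = list(dist = "uniform", min = 1.5, max = 2.5))
}

#' Build a peripersonal-space (PPS) session plan
#'
#' 22 experimental conditions (approach/recede x 11 distances) repeated 16
#' times, two tactile-only baseline conditions (timed like the nearest- and
#' farthest-equivalent visual onsets) repeated 16 times, and two catch
#' conditions (visual-only, approach and recede) repeated 39 times: 462
#' trials (~17% catch) in three equal blocks, fixed 2.5 s inter-trial
#' interval. Order is a seed-controlled shuffle with no condition cell
#' repeated more than 4 times consecutively. Catch trials carry no tactile
#' onset.
#'
#' @inheritParams build_cce_session
#' @return A `session_plan`; `$trials` has 462 rows.
#' @export
build_pps_session <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  exper <- expand.grid(direction = .pps_directions, distance_index = 1:11,
                       stringsAsFactors = FALSE)
  exper <- exper[rep(seq_len(nrow(exper)), each = 16), ]
  exper$condition <- "experimental"
  # baseline timing mimics the visual sequence reaching the nearest (D1,
  # 2.5 s into the approach stream) or farthest-equivalent (first step, 0 s)
  # position; no distance is stimulated, only its temporal equivalent.
  base <- data.frame(direction = NA_character_,
                     distance_index = NA_integer_,
                     condition = "baseline",
                     onset = rep(c(10 * .led_step_s, 0), each = 16))
  catch <- data.frame(direction = rep(.pps_directions, each = 39),
                      distance_index = NA_integer_,
                      condition = "catch",
                      onset = NA_real_)
  exper$onset <- pps_onset_time(exper$distance_index, exper$direction)
  trials <- rbind(exper, base, catch)

  key <- paste(trials$condition, trials$direction, trials$distance_index,
               trials$onset)
  ord <- with_seed(seed, shuffle_constrained(key))
  trials <- trials[ord, ]

  plan <- tibble(
    task = "PPS",
    trial_index = seq_len(nrow(trials)),
    condition = trials$condition,
    digit = NA_character_,
    direction = trials$direction,
    distance_index = trials$distance_index,
    onset_time_s = trials$onset,
    iti_s = 2.5,
    block = rep(1:3, each = nrow(trials) / 3))
  new_session_plan("PPS", plan, distances_cm = pps_distances(),
                   iti_spec = list(dist = "fixed", value = 2.5))
}
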