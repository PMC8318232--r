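#' Canonical stimulus set of the value/risk bandit task
#'
#' The task uses four stimuli whose reward distributions cross two means
#' (60 vs 40 points) with two standard deviations (20 vs 5 points):
#' risky-high, safe-high, risky-low, safe-low. Stimulus indices are fixed
#' so that the risky arms are stimuli 1 and 3 and the safe arms 2 and 4.
#'
#' @return A data.frame with one row per stimulus and columns
#'   `stimulus_id`, `mean`, `sd`, `risk_class` (`"risky"`/`"safe"`) and
#'   `value_class` (`"high"`/`"low"`).
#' @examples
#' stimulus_specs()
#' @export
stimulus_specs <- function() {
  data.frame(
    stimulus_id = 1:4,
    mean = c(60, 60, 40, 40),
    sd = c(20, 5, 20, 5),
    risk_class = c("risky", "safe", "risky", "safe"),
    value_class = c("high", "high", "low", "low"),
    stringsAsFactors = FALSE
  )
}

# the 12 ordered pairs of distinct stimuli, in a fixed canonical order
ordered_pairs <- function() {
  grid <- expand.grid(first = 1:4, second = 1:4)
  grid <- grid[grid$first != grid$second, c("first", "second")]
  grid <- grid[order(grid$first, grid$second), ]
  rownames(grid) <- NULL
  grid
}

#' Build a balanced pseudo-random trial schedule
#'
#' Every one of the 12 ordered stimulus pairs occurs exactly
#' `reps_per_pair` times within each block (the default, 10, gives the
#' standard 120-trial block); trial order within a block is a seeded
#' uniform permutation with no further constraints.
#'
#' @param n_blocks Number of blocks (default 4).
#' @param reps_per_pair Occurrences of each ordered pair per block
#'   (default 10).
#' @param seed Integer seed; the same seed reproduces the schedule
#'   bit-for-bit.
#' @return A data.frame of class `trial_schedule` with columns `block`,
#'   `trial` (1-based within block), `stim_first`, `stim_second` and
#'   `condition`.
#' @examples
#' sched <- build_schedule(n_blocks = 1, reps_per_pair = 1, seed = 1)
#' table(sched$condition)
#' @export
build_schedule <- function(n_blocks = 4, reps_per_pair = 10, seed = 1) {
  if (length(n_blocks) != 1 || is.na(n_blocks) || n_blocks < 1 ||
      n_blocks != round(n_blocks)) {
    stop("`n_blocks` must be a positive integer", call. = FALSE)
  }
  if (length(reps_per_pair) != 1 || is.na(reps_per_pair) || reps_per_pair < 1 ||
      reps_per_pair != round(reps_per_pair)) {
    stop("`reps_per_pair` must be a positive integer", call. = FALSE)
  }
  set.seed(seed)
  pairs <- ordered_pairs()
  n_per_block <- nrow(pairs) * reps_per_pair
  blocks <- lapply(seq_len(n_blocks), function(b) {
    idx <- rep(seq_len(nrow(pairs)), times = reps_per_pair)
    idx <- sample(idx, length(idx), replace = FALSE)
    data.frame(
      block = b,
      trial = seq_len(n_per_block),
      stim_first = pairs$first[idx],
      stim_second = pairs$second[idx]
    )
  })
  out <- do.call(rbind, blocks)
  out$condition <- classify_condition(out$stim_first, out$stim_second)
  class(out) <- c("trial_schedule", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Classify a stimulus pair into the three task conditions
#'
#' Trials are grouped by the value classes of the two shown stimuli:
#' `both-high` (both means 60), `both-low` (both means 40), `different`
#' otherwise.
#'
#' @param first,second Vectors of stimulus ids in 1..4; the two members
#'   of each pair must differ.
#' @return Character vector of conditions.
#' @examples
#' classify_condition(1, 2)  # both-high
#' classify_condition(c(3, 1), c(4, 4))
#' @export
classify_condition <- function(first, second) {
  if (length(first) != length(second)) {
    stop("`first` and `second` must have equal length", call. = FALSE)
  }
  ok <- first %in% 1:4 & second %in% 1:4
  if (!all(ok)) stop("stimulus ids must be in 1..4", call. = FALSE)
  if (any(first == second)) {
    stop("a pair must contain two distinct stimuli", call. = FALSE)
  }
  value_class <- stimulus_specs()$value_class
  vf <- value_class[first]
  vs <- value_class[second]
  ifelse(vf == "high" & vs == "high", "both-high",
    ifelse(vf == "low" & vs == "low", "both-low", "different"))
}

#' Sample integer rewards from a stimulus's generative distribution
#'
#' Rewards are approximately Gaussian integers: a normal draw with the
#' stimulus's generative mean and SD, rounded to the nearest integer and
#' clipped into the valid 1--99 point range. Clipping (rather than
#' resampling) keeps the realized means within 0.2 points of the nominal
#' 60/40.
#'
#' @param stimulus_id Stimulus id in 1..4, or a data.frame row with
#'   `mean` and `sd` columns.
#' @param n Number of draws.
#' @return Integer vector of rewards in `[1, 99]`.
#' @examples
#' set.seed(1)
#' mean(sample_reward(1, 1000))
#' @export
sample_reward <- function(stimulus_id, n = 1) {
  if (is.data.frame(stimulus_id)) {
    mu <- stimulus_id$mean[1]
    sd <- stimulus_id$sd[1]
  } else {
    if (!stimulus_id %in% 1:4) stop("stimulus id must be in 1..4", call. = FALSE)
    specs <- stimulus_specs()
    mu <- specs$mean[stimulus_id]
    sd <- specs$sd[stimulus_id]
  }
  r <- round(stats::rnorm(n, mu, sd))
  as.integer(pmin(99, pmax(1, r)))
}

#' Write / read trial data in the package CSV dialect
#'
#' One row per trial with header
#' `participant,block,trial,stim_first,stim_second,condition,choice,reward`
#' (`stim_first`/`stim_second` give the ordered pair; `choice` is the
#' chosen stimulus id, not a screen side). Extra columns such as `rep`
#' are preserved.
#'
#' @param trials A data.frame of trials (e.g. from [simulate_session()]).
#' @param path File path.
#' @return `read_trials()` returns the data.frame; `write_trials()` its
#'   path, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant", "block", "trial", "stim_first", "stim_second",
              "condition", "choice", "reward")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("trial file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out
}
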