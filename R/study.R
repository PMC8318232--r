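#' Simulate many repetitions of the full experiment
#'
#' One parameter set per simulated participant; each repetition
#' simulates a complete fresh experiment (every participant: new
#' schedule, new choices and rewards). Repetitions are seeded
#' reproducibly from the master seed.
#'
#' @param model Model name.
#' @param param_sets List of named parameter sets, one per participant.
#' @param n_reps Number of experiment repetitions (the reference
#'   protocol uses 1000; package-scale studies typically use 50).
#' @param seed Master seed.
#' @param n_blocks,reps_per_pair Task size.
#' @return An object of class `peirs_experiments`: `model`, `n_reps`,
#'   `sessions` (list over reps, each a list over participants of
#'   `peirs_session`), `param_sets`.
#' @export
simulate_experiments <- function(model, param_sets, n_reps, seed = 1,
                                 n_blocks = 4, reps_per_pair = 10) {
  n_part <- length(param_sets)
  sessions <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sessions[[r]] <- lapply(seq_len(n_part), function(i) {
      s <- .sub_seed(seed, (r - 1L) * n_part + i, 3L)
      sched <- build_schedule(n_blocks, reps_per_pair, seed = s)
      set.seed(.sub_seed(seed, (r - 1L) * n_part + i, 4L))
      simulate_session(model, param_sets[[i]], sched, seed = NULL,
                       participant_id = i)
    })
  }
  structure(list(model = model, n_reps = n_reps, sessions = sessions,
                 param_sets = param_sets, seed = seed),
            class = "peirs_experiments")
}

#' @export
print.peirs_experiments <- function(x, ...) {
  cat("<peirs_experiments>", x$model, "-", length(x$param_sets),
      "participants x", x$n_reps, "repetitions\n")
  invisible(x)
}

.risky_ids <- c(1, 3)

#' Risk preference of a session in one condition
#'
#' The fraction of the session's trials of the given matched-mean
#' condition in which the risky (broad-distribution) member of the pair
#' was chosen. Values above 0.5 indicate risk-seeking, below 0.5
#' risk-aversion.
#'
#' @param trials A trial table or `peirs_session`.
#' @param condition `"both-high"` or `"both-low"` (any condition label
#'   present in the data is accepted).
#' @return A proportion in `[0,1]`, or `NA` if the session contains no
#'   trials of the condition.
#' @export
risk_preference <- function(trials, condition) {
  tr <- .as_trials(trials)
  sel <- tr$condition == condition
  if (!any(sel)) return(NA_real_)
  mean(tr$choice[sel] %in% .risky_ids)
}

#' Per-participant risk summary of a trial table
#'
#' @param trials A (possibly multi-participant) trial table.
#' @return A data.frame with one row per participant: `both_high`,
#'   `both_low` risk preferences and their `difference`.
#' @export
risk_summary <- function(trials) {
  tr <- .as_trials(trials)
  parts <- unique(tr$participant)
  out <- do.call(rbind, lapply(parts, function(p) {
    sub <- tr[tr$participant == p, ]
    bh <- risk_preference(sub, "both-high")
    bl <- risk_preference(sub, "both-low")
    data.frame(participant = p, both_high = bh, both_low = bl,
               difference = bh - bl)
  }))
  rownames(out) <- NULL
  out
}

#' Risk-preference trace over within-block trial position
#'
#' For every within-block trial position, the probability of choosing
#' the risky option in the given condition, aggregated in the fixed
#' order: average the risky-choice indicator over blocks within a
#' session, then over experiment repetitions for each participant, then
#' over participants; finally smooth with a moving average (shrinking
#' window at the trace edges, so no data is fabricated beyond the
#' block).
#'
#' @param experiments A `peirs_experiments`, `peirs_cohort`, or a single
#'   session/trial table.
#' @param condition Condition label.
#' @param window Moving-average window length in trials (default 20;
#'   1 = no smoothing).
#' @return A data.frame of class `risk_trace`: `trial`, `mean`, `se`
#'   (across participants, of the unsmoothed means), `smoothed`,
#'   `condition`; the window length is stored as an attribute.
#' @export
risk_trace <- function(experiments, condition, window = 20) {
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  per_part <- .per_participant_traces(experiments, condition)
  mean_trace <- apply(per_part, 2, mean, na.rm = TRUE)
  n_eff <- apply(per_part, 2, function(v) sum(!is.na(v)))
  se_trace <- apply(per_part, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_eff, 1))
  out <- data.frame(trial = seq_along(mean_trace), mean = mean_trace,
                    se = se_trace,
                    smoothed = moving_average(mean_trace, window),
                    condition = condition)
  rownames(out) <- NULL
  attr(out, "window") <- window
  class(out) <- c("risk_trace", "data.frame")
  out
}

# matrix participants x trial-position of risky-choice proportions,
# averaging repetitions before participants
.per_participant_traces <- function(x, condition) {
  rep_list <- if (inherits(x, "peirs_experiments")) {
    x$sessions
  } else if (inherits(x, "peirs_cohort")) {
    list(x$sessions)
  } else {
    list(list(x))
  }
  n_part <- length(rep_list[[1]])
  n_pos <- max(.as_trials(rep_list[[1]][[1]])$trial)
  out <- matrix(NA_real_, n_part, n_pos)
  for (i in seq_len(n_part)) {
    per_rep <- vapply(rep_list, function(cohort) {
      tr <- .as_trials(cohort[[i]])
      sel <- tr$condition == condition
      pos <- tr$trial[sel]
      risky <- as.numeric(tr$choice[sel] %in% .risky_ids)
      vapply(seq_len(n_pos), function(tt) {
        idx <- pos == tt
        if (any(idx)) mean(risky[idx]) else NA_real_
      }, numeric(1))
    }, numeric(n_pos))
    out[i, ] <- rowMeans(per_rep, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Moving average with shrinking edge windows
#'
#' Centred moving average; near the edges the window shrinks to the
#' available samples instead of padding.
#'
#' @param x Numeric vector.
#' @param window Window length (1 returns `x`).
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(x, window = 20) {
  if (window <= 1) return(x)
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half_lo)
    hi <- min(n, i + half_hi)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Condition difference in risk preference
#'
#' For a single session: p(risky | both-high) minus p(risky | both-low).
#' For a repetition collection: the same quantity averaged over
#' repetitions per participant, then summarized over participants as
#' mean and standard error.
#'
#' @param x A session/trial table, `peirs_cohort`, or
#'   `peirs_experiments`.
#' @return For a session, a single number in `[-1, 1]` (possibly `NA`);
#'   otherwise a list with `per_participant`, `mean` and `se`.
#' @export
effect_size <- function(x) {
  if (!inherits(x, c("peirs_experiments", "peirs_cohort"))) {
    tr <- .as_trials(x)
    return(risk_preference(tr, "both-high") - risk_preference(tr, "both-low"))
  }
  rep_list <- if (inherits(x, "peirs_experiments")) x$sessions else list(x$sessions)
  n_part <- length(rep_list[[1]])
  per_part <- vapply(seq_len(n_part), function(i) {
    diffs <- vapply(rep_list, function(cohort) effect_size(cohort[[i]]),
                    numeric(1))
    mean(diffs, na.rm = TRUE)
  }, numeric(1))
  list(per_participant = per_part, mean = mean(per_part, na.rm = TRUE),
       se = stats::sd(per_part, na.rm = TRUE) / sqrt(sum(!is.na(per_part))))
}

#' Two-dimensional density of per-participant risk preferences
#'
#' Gaussian kernel density estimate on the unit square of
#' (both-high, both-low) risk-preference pairs, with per-axis Silverman
#' bandwidths, plus contour polylines with levels spread over the
#' density's value range. Points below the diagonal indicate
#' participants who are more risk-seeking when means are high than when
#' they are low.
#'
#' @param points A data.frame with columns `both_high` and `both_low`
#'   (e.g. from [risk_summary()]); at least 2 complete rows.
#' @param n_grid Grid resolution per axis.
#' @param n_levels Number of contour levels.
#' @return A list of class `preference_density`: grid vectors `x`, `y`,
#'   density matrix `z`, `bandwidth`, and `contours` (a list of
#'   polylines as returned by [grDevices::contourLines()]).
#' @export
preference_density <- function(points, n_grid = 64, n_levels = 5) {
  pts <- points[stats::complete.cases(points[, c("both_high", "both_low")]), ]
  if (nrow(pts) < 2) stop("need at least 2 points", call. = FALSE)
  silverman <- function(v) {
    0.9 * min(stats::sd(v), stats::IQR(v) / 1.34) * length(v)^(-1 / 5)
  }
  hx <- silverman(pts$both_high)
  hy <- silverman(pts$both_low)
  if (any(!is.finite(c(hx, hy)) | c(hx, hy) <= 0)) {
    warning("degenerate point cloud: falling back to bandwidth floor")
    if (!is.finite(hx) || hx <= 0) hx <- 0.02
    if (!is.finite(hy) || hy <= 0) hy <- 0.02
  }
  # MASS::kde2d uses h/4 as the Gaussian kernel sd
  dens <- MASS::kde2d(pts$both_high, pts$both_low, h = 4 * c(hx, hy),
                      n = n_grid, lims = c(0, 1, 0, 1))
  levels <- max(dens$z) * seq_len(n_levels) / (n_levels + 1)
  contours <- grDevices::contourLines(dens$x, dens$y, dens$z, levels = levels)
  structure(list(x = dens$x, y = dens$y, z = dens$z,
                 bandwidth = c(both_high = hx, both_low = hy),
                 contours = contours),
            class = "preference_density")
}

#' @export
print.preference_density <- function(x, ...) {
  cat("<preference_density>", length(x$x), "x", length(x$y),
      "grid, bandwidths", paste(round(x$bandwidth, 3), collapse = "/"),
      "-", length(x$contours), "contour lines\n")
  invisible(x)
}
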