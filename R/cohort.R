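#' Draw or list parameter sets for a model
#'
#' Three sources: `"prior"` draws raw-space Gaussians from the fitting
#' priors and maps them through the transforms; `"default"` replicates a
#' documented plausible set per model; `"fixed"` returns a user-supplied
#' list verbatim.
#'
#' @param model Model name.
#' @param n Number of parameter sets.
#' @param seed Seed for prior draws.
#' @param source `"prior"`, `"default"` or `"fixed"`.
#' @param fixed For `source = "fixed"`: a list of `n` named parameter
#'   sets.
#' @return A list of `n` named natural-space parameter vectors.
#' @examples
#' sample_parameters("RW", 2, seed = 1)
#' @export
sample_parameters <- function(model, n, seed = 1,
                              source = c("prior", "default", "fixed"),
                              fixed = NULL) {
  source <- match.arg(source)
  if (source == "fixed") {
    if (is.null(fixed) || length(fixed) != n) {
      stop("`fixed` must be a list of length `n`", call. = FALSE)
    }
    return(fixed)
  }
  if (source == "default") {
    return(replicate(n, default_parameters(model), simplify = FALSE))
  }
  ps <- prior_spec(model)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    raw <- stats::rnorm(nrow(ps), ps$mean, sqrt(ps$var))
    transform_parameters(raw, model)
  })
}

#' Documented plausible default parameters per model
#'
#' A single fixed parameter set per model, used by the synthetic-data
#' generator when a homogeneous, well-behaved cohort is wanted: moderate
#' learning rate (0.3), softmax inverse temperature 0.2 (on the
#' 1--99-point reward scale), mild curvatures for the utility families,
#' a modest valence asymmetry, and for the gated models the spread rate
#' 0.1, gating gain 0.5 and initial spread 10.
#'
#' @param model Model name.
#' @return A named numeric vector of natural-space parameters.
#' @export
default_parameters <- function(model) {
  out <- switch(model,
    "RW" = c(alpha = 0.3, beta = 0.2),
    "concave-UTIL" = c(alpha = 0.3, beta = 0.2, k_concave = 0.2),
    "convex-UTIL" = c(alpha = 0.3, beta = 0.2, k_convex = -0.2),
    "s-shaped-UTIL" = c(alpha = 0.3, beta = 0.2, k_s_shaped = 0.7),
    "inverse-s-UTIL" = c(alpha = 0.3, beta = 0.2, k_inverse_s = 1.5),
    "pos-neg-RATES" = c(alpha_pos = 0.35, alpha_neg = 0.25, beta = 0.2),
    "variance-RATES" = c(alpha_risky = 0.35, alpha_safe = 0.25, beta = 0.2),
    "attention-RATES" = c(alpha = 0.3, k_attention = 0.2, beta = 0.2),
    "scaled-PE" = c(alpha_q = 0.3, alpha_s = 0.1, s0 = 10, beta = 0.2),
    "PEIRS" = c(alpha_q = 0.3, alpha_s = 0.1, beta = 0.2, omega = 0.5, s0 = 10),
    "PIRS" = c(alpha_q = 0.3, alpha_s = 0.1, beta = 0.2, omega = 0.5, s0 = 10),
    "OEIRS" = c(alpha_q = 0.3, alpha_s = 0.1, beta = 0.2, omega = 0.5, s0 = 10),
    stop("unknown model: ", model, call. = FALSE))
  out[model_spec(model)$params]
}

# master seed -> per-participant seed, fixed-stride counter
.sub_seed <- function(seed, i, stream = 0L) {
  as.integer((as.numeric(seed) * 131 + i * 10007 + stream * 7) %% 2147483647)
}

#' Generate a ground-truth synthetic cohort
#'
#' Simulates `n_participants` independent sessions from one model, each
#' with a fresh balanced schedule and its own derived seed, and attaches
#' the generating parameters. With `sanity_filter = TRUE` parameter sets
#' whose agent fails the behavioural inclusion filter (above-65%
#' high-value choice in late different-condition trials) are redrawn, so
#' the cohort resembles an analyzable population rather than random
#' responders; a participant failing 100 redraws is a configuration
#' error.
#'
#' @param model Model name.
#' @param n_participants Cohort size (the reference experiment analyzed
#'   27).
#' @param source Parameter source, as in [sample_parameters()].
#' @param seed Master seed; per-participant seeds are derived by a fixed
#'   stride and recorded.
#' @param sanity_filter Redraw parameter sets until the simulated agent
#'   passes [inclusion_filter()].
#' @param fixed Parameter list for `source = "fixed"`.
#' @param n_blocks,reps_per_pair Task size (defaults 4 blocks x 120
#'   trials).
#' @return An object of class `peirs_cohort`: `model`, `sessions` (list
#'   of `peirs_session`), `params` (list of generating parameter sets),
#'   `seeds` (per-participant), `seed`, `filtered`.
#' @examples
#' coh <- generate_cohort("RW", 2, source = "default", seed = 1,
#'                        sanity_filter = FALSE, n_blocks = 1)
#' coh
#' @export
generate_cohort <- function(model, n_participants,
                            source = c("prior", "default", "fixed"),
                            seed = 1, sanity_filter = TRUE, fixed = NULL,
                            n_blocks = 4, reps_per_pair = 10) {
  source <- match.arg(source)
  sessions <- vector("list", n_participants)
  params <- vector("list", n_participants)
  seeds <- integer(n_participants)
  for (i in seq_len(n_participants)) {
    seed_i <- .sub_seed(seed, i)
    seeds[i] <- seed_i
    sched <- build_schedule(n_blocks, reps_per_pair, seed = seed_i)
    set.seed(.sub_seed(seed, i, 1L))
    for (attempt in seq_len(100)) {
      p <- switch(source,
        "prior" = {
          ps <- prior_spec(model)
          transform_parameters(stats::rnorm(nrow(ps), ps$mean, sqrt(ps$var)),
                               model)
        },
        "default" = default_parameters(model),
        "fixed" = unlist(fixed[[i]]))
      sess <- simulate_session(model, p, sched, seed = NULL,
                               participant_id = i)
      if (!sanity_filter || isTRUE(inclusion_filter(sess))) break
      sess <- NULL
      if (attempt == 100 || source != "prior") {
        stop("sanity filter: no admissible agent within 100 redraws for ",
             "participant ", i, " (model ", model, ", source ", source, ")",
             call. = FALSE)
      }
    }
    sessions[[i]] <- sess
    params[[i]] <- p
  }
  structure(list(model = model, sessions = sessions, params = params,
                 seeds = seeds, seed = seed, filtered = sanity_filter),
            class = "peirs_cohort")
}

#' @export
print.peirs_cohort <- function(x, ...) {
  cat("<peirs_cohort> model:", x$model, "-", length(x$sessions),
      "participants", if (x$filtered) "(sanity-filtered)" else "", "\n")
  invisible(x)
}

#' Stack a cohort's sessions into one long trial table
#'
#' @param cohort A `peirs_cohort`.
#' @return A data.frame in the package CSV dialect with a `participant`
#'   column.
#' @export
cohort_trials <- function(cohort) {
  do.call(rbind, lapply(cohort$sessions, function(s) s$trials))
}

#' Parameter recovery study
#'
#' Generates a sanity-filtered prior-draw cohort from one model, refits
#' that model to every session, and summarizes how well the generating
#' natural-space parameters are recovered: Pearson correlation and
#' median absolute error per parameter, plus the optimizer-adequacy
#' check that every recovered log-posterior is at least the log-posterior
#' of the generating parameters.
#'
#' @param model Model name.
#' @param n_participants Number of simulated agents.
#' @param seed Master seed.
#' @param n_starts Optimizer starts per fit.
#' @param n_blocks,reps_per_pair Task size per agent.
#' @return A list of class `parameter_recovery`: `params` (data.frame of
#'   generating and recovered values), `correlations`, `median_abs_error`
#'   (named by parameter), `logpost_gap` (recovered minus generating
#'   log-posterior, per agent), `low_n` flag.
#' @export
parameter_recovery <- function(model, n_participants, seed = 1,
                               n_starts = 6, n_blocks = 4,
                               reps_per_pair = 10) {
  cohort <- generate_cohort(model, n_participants, source = "prior",
                            seed = seed, sanity_filter = TRUE,
                            n_blocks = n_blocks,
                            reps_per_pair = reps_per_pair)
  pnames <- model_spec(model)$params
  gen <- do.call(rbind, lapply(cohort$params, function(p) unlist(p)[pnames]))
  rec <- matrix(NA_real_, n_participants, length(pnames),
                dimnames = list(NULL, pnames))
  gap <- numeric(n_participants)
  for (i in seq_len(n_participants)) {
    fit <- fit_map(model, cohort$sessions[[i]], n_starts = n_starts,
                   seed = .sub_seed(seed, i, 2L))
    rec[i, ] <- fit$natural[pnames]
    gap[i] <- fit$logpost -
      log_posterior(model, cohort$params[[i]], cohort$sessions[[i]])
  }
  correlations <- vapply(pnames, function(p) {
    stats::cor(gen[, p], rec[, p])
  }, numeric(1))
  mae <- vapply(pnames, function(p) {
    stats::median(abs(gen[, p] - rec[, p]))
  }, numeric(1))
  df <- data.frame(participant = rep(seq_len(n_participants), each = length(pnames)),
                   param = rep(pnames, n_participants),
                   generating = as.numeric(t(gen)),
                   recovered = as.numeric(t(rec)))
  structure(list(model = model, params = df, correlations = correlations,
                 median_abs_error = mae, logpost_gap = gap,
                 low_n = n_participants < 5),
            class = "parameter_recovery")
}

#' @export
print.parameter_recovery <- function(x, ...) {
  cat("<parameter_recovery>", x$model, "\n")
  print(round(rbind(correlation = x$correlations,
                    median_abs_error = x$median_abs_error), 3))
  if (x$low_n) cat("note: very small cohort, correlations unstable\n")
  invisible(x)
}

#' Serialize / load a cohort manifest
#'
#' Writes the cohort's ground truth (model, master and per-participant
#' seeds, generating parameters) as JSON alongside the stacked trial
#' table as CSV, and reads them back losslessly.
#'
#' @param cohort A `peirs_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   list with `manifest` and `trials`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(model = cohort$model, seed = cohort$seed,
                   filtered = cohort$filtered, seeds = cohort$seeds,
                   params = lapply(cohort$params, as.list))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_trials(cohort_trials(cohort), file.path(dir, "trials.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = FALSE)
  manifest <- list(model = m$model, seed = m$seed, filtered = m$filtered,
                   seeds = as.integer(unlist(m$seeds)),
                   params = lapply(m$params, function(p) unlist(p)))
  trials <- read_trials(file.path(dir, "trials.csv"))
  list(manifest = manifest, trials = trials)
}
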