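#' Maximum a posteriori fit of one model to one session
#'
#' Maximizes the log-posterior (replay log-likelihood plus Gaussian
#' log-prior on the raw, unconstrained parameterization) with
#' multi-start quasi-Newton search (BFGS, numerical gradients). The
#' first start is the vector of prior means; the remaining starts are
#' prior draws, so the whole fit is deterministic given `seed`.
#'
#' @param model Model name from [model_names()].
#' @param trials A trial table or `peirs_session`.
#' @param n_starts Number of optimizer starts (default 10).
#' @param seed Integer seed for the start draws.
#' @return An object of class `peirs_fit`: `model`, `raw` and `natural`
#'   parameter estimates, `loglik` and `logpost` at the optimum, `k`
#'   (free-parameter count), `n_trials`, `bic` (`k*log(n) - 2*loglik`),
#'   `n_starts`, `converged` (any start reported optimizer convergence)
#'   and `seed`.
#' @examples
#' \donttest{
#' sess <- simulate_session("RW", c(alpha = 0.3, beta = 0.2), seed = 1)
#' fit_map("RW", sess, n_starts = 3, seed = 1)
#' }
#' @export
fit_map <- function(model, trials, n_starts = 10, seed = 1) {
  spec <- model_spec(model)
  ps <- prior_spec(model)
  tr <- .as_trials(trials)
  if (nrow(tr) == 0) stop("empty session", call. = FALSE)
  k <- nrow(ps)

  util <- .util_code[[spec$utility_family]]
  rate <- .rate_code[[spec$rate_rule]]
  gatec <- .gate_code[[spec$risk_gate]]
  blk <- as.integer(tr$block); f1 <- as.integer(tr$stim_first)
  f2 <- as.integer(tr$stim_second); ch <- as.integer(tr$choice)
  rw <- as.numeric(tr$reward)
  pm <- ps$mean; psd <- sqrt(ps$var); transforms <- ps$transform

  loglik_raw <- function(raw) {
    nat <- vapply(seq_len(k), function(i) .apply_transform(raw[i], transforms[i]),
                  numeric(1))
    names(nat) <- ps$param
    packed <- .pack_params(spec, nat)
    replay_session_cpp(blk, f1, f2, ch, rw, util, rate, spec$pe_scaling,
                       gatec, packed, FALSE)$loglik
  }
  neg_post <- function(raw) {
    ll <- loglik_raw(raw)
    lp <- sum(stats::dnorm(raw, pm, psd, log = TRUE))
    v <- -(ll + lp)
    if (!is.finite(v)) 1e10 else v
  }

  set.seed(seed)
  starts <- rbind(pm, matrix(stats::rnorm((n_starts - 1) * k, rep(pm, each = n_starts - 1),
                                          rep(psd, each = n_starts - 1)),
                             ncol = k, byrow = FALSE))
  starts <- starts[seq_len(n_starts), , drop = FALSE]

  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], neg_post, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(list(model = model, raw = NULL, natural = NULL,
                          loglik = NA_real_, logpost = NA_real_, k = k,
                          n_trials = nrow(tr), bic = NA_real_,
                          n_starts = n_starts, converged = FALSE,
                          fit_failed = TRUE, seed = seed),
                     class = "peirs_fit"))
  }
  raw <- best$par
  names(raw) <- ps$param
  natural <- transform_parameters(raw, model)
  ll <- loglik_raw(raw)
  structure(list(model = model, raw = raw, natural = natural,
                 loglik = ll, logpost = -best$value, k = k,
                 n_trials = nrow(tr),
                 bic = k * log(nrow(tr)) - 2 * ll,
                 n_starts = n_starts, converged = any_conv,
                 fit_failed = FALSE, seed = seed),
            class = "peirs_fit")
}

#' @export
print.peirs_fit <- function(x, ...) {
  cat("<peirs_fit>", x$model, "- logL", format(x$loglik, digits = 6),
      "BIC", format(x$bic, digits = 6), "k =", x$k, "\n")
  if (!is.null(x$natural)) {
    print(round(x$natural, 4))
  }
  invisible(x)
}

#' Log-posterior of a parameter set on a session
#'
#' Convenience for optimizer-adequacy checks: the replay log-likelihood
#' plus the raw-space log-prior at a given natural-space parameter set.
#'
#' @inheritParams fit_map
#' @param params Named natural-space parameter set.
#' @return A single number.
#' @export
log_posterior <- function(model, params, trials) {
  raw <- untransform_parameters(unlist(params), model)
  session_log_likelihood(model, params, trials) + log_prior(raw, model)
}

#' Fixed-effects model comparison by summed BIC
#'
#' Sums each model's BIC over participants and ranks models ascending
#' (lower summed BIC = more parsimonious account of the cohort).
#'
#' @param fit_table A data.frame with columns `participant`, `model` and
#'   `bic`, covering the full participants-by-models grid, or a list of
#'   `peirs_fit` objects plus a matching `participant` vector.
#' @return A data.frame of class `bic_comparison` with columns `model`,
#'   `total_bic` and `rank`, sorted by rank.
#' @export
compare_models <- function(fit_table) {
  ft <- as.data.frame(fit_table)
  needed <- c("participant", "model", "bic")
  if (!all(needed %in% names(ft))) {
    stop("`fit_table` needs columns participant, model, bic", call. = FALSE)
  }
  grid <- table(ft$model, ft$participant)
  if (any(grid != 1)) {
    stop("incomplete comparison: every participant must be fitted under ",
         "every model exactly once", call. = FALSE)
  }
  if (any(!is.finite(ft$bic))) {
    stop("non-finite BIC entries in the fit table", call. = FALSE)
  }
  total <- tapply(ft$bic, ft$model, sum)
  out <- data.frame(model = names(total), total_bic = as.numeric(total),
                    stringsAsFactors = FALSE)
  out <- out[order(out$total_bic), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("bic_comparison", "data.frame")
  out
}

#' Model recovery study
#'
#' Simulates datasets from each generating model (parameters drawn from
#' the priors, redrawn until the agent passes the behavioural inclusion
#' filter), fits every candidate model to every dataset, selects the
#' winner per dataset by summed BIC, and tabulates the confusion matrix.
#' A reliable pipeline shows a dominant diagonal and, in particular,
#' rarely selects the PEIRS model for data generated without a risk
#' gate (false positives).
#'
#' @param generating_models Character vector of generating model names.
#' @param n_datasets Simulated datasets per generating model.
#' @param seed Master seed.
#' @param candidate_models Models fitted to each dataset (default all 12).
#' @param n_participants Participants per dataset (default 1).
#' @param n_starts Optimizer starts per fit.
#' @param n_blocks,reps_per_pair Task size per participant.
#' @return A list of class `recovery_report`: `confusion` (generating x
#'   selected counts), `selected` (per-dataset winners), and
#'   `generating_params` / `recovered_params` for the generating model's
#'   own fit on each dataset.
#' @export
model_recovery <- function(generating_models, n_datasets, seed = 1,
                           candidate_models = model_names(),
                           n_participants = 1, n_starts = 4,
                           n_blocks = 4, reps_per_pair = 10) {
  if (n_datasets < 1) stop("`n_datasets` must be >= 1", call. = FALSE)
  confusion <- matrix(0L, length(generating_models), length(candidate_models),
                      dimnames = list(generating_models, candidate_models))
  selected <- list()
  gen_params <- list()
  rec_params <- list()

  for (g in seq_along(generating_models)) {
    gm <- generating_models[g]
    for (d in seq_len(n_datasets)) {
      ds_seed <- (seed * 131 + g * 7919 + d * 104729) %% 2147483647L
      cohort <- generate_cohort(gm, n_participants, source = "prior",
                                seed = ds_seed, sanity_filter = TRUE,
                                n_blocks = n_blocks,
                                reps_per_pair = reps_per_pair)
      sums <- numeric(length(candidate_models))
      names(sums) <- candidate_models
      for (cm in candidate_models) {
        fits <- lapply(cohort$sessions, function(sess) {
          fit_map(cm, sess, n_starts = n_starts, seed = ds_seed)
        })
        sums[cm] <- sum(vapply(fits, `[[`, numeric(1), "bic"))
        if (cm == gm && n_participants == 1) {
          rec_params[[paste(gm, d)]] <- fits[[1]]$natural
        }
      }
      win <- names(sums)[which.min(sums)]
      confusion[gm, win] <- confusion[gm, win] + 1L
      selected[[paste(gm, d)]] <- win
      gen_params[[paste(gm, d)]] <- unlist(cohort$params[[1]])
    }
  }
  structure(list(confusion = confusion,
                 selected = unlist(selected),
                 generating_params = gen_params,
                 recovered_params = rec_params),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> confusion matrix (rows generate, cols selected):\n")
  print(x$confusion)
  invisible(x)
}
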