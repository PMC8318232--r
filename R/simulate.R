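# flag encodings shared with the C++ replay kernel
.util_code <- c("identity" = 0L, "concave" = 1L, "convex" = 1L,
                "s-shaped" = 2L, "inverse-s" = 2L)
.rate_code <- c("fixed" = 0L, "valence" = 1L, "variance" = 2L,
                "attention" = 3L)
.gate_code <- c("none" = 0L, "stimulus-PE" = 1L, "prediction" = 2L,
                "prev-outcome-PE" = 3L)

# pack a named natural-space parameter set into the fixed-slot vector the
# C++ kernel expects
.pack_params <- function(spec, params) {
  params <- as.list(params)
  missing <- setdiff(spec$params, names(params))
  if (length(missing)) {
    stop("parameter set for ", spec$name, " lacks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  k_util <- switch(spec$utility_family,
    "identity" = 0,
    "concave" = params$k_concave,
    "convex" = params$k_convex,
    "s-shaped" = params$k_s_shaped,
    "inverse-s" = params$k_inverse_s)
  pick <- function(nm, default = 0) {
    if (!is.null(params[[nm]])) params[[nm]] else default
  }
  c(pick("alpha", pick("alpha_q")), pick("alpha_pos"), pick("alpha_neg"),
    pick("alpha_risky"), pick("alpha_safe"), pick("k_attention"), k_util,
    pick("alpha_s"), params$beta, pick("omega"), pick("s0", 1))
}

.as_trials <- function(x) {
  if (inherits(x, "peirs_session")) return(x$trials)
  as.data.frame(x)
}

#' Simulate one participant-session of the bandit task
#'
#' Runs the model's trial loop over a schedule: compute the gating signal
#' from pre-choice values, form action activations, draw the choice from
#' the softmax probabilities, draw the reward from the chosen stimulus's
#' generative distribution, then apply the model's learning updates.
#' Latents (values, spreads, the previous outcome prediction error used
#' by OEIRS) are reset at every block start, since each block uses a new
#' set of stimulus images.
#'
#' @param model Model name from [model_names()].
#' @param params Named natural-space parameter set (see [model_spec()]).
#' @param schedule A [build_schedule()] data.frame.
#' @param seed Integer seed; `NULL` continues from the current RNG state.
#' @param participant_id Identifier stored in the trial table.
#' @return An object of class `peirs_session`: a list with `trials` (the
#'   CSV-dialect trial table) and `trace` (per-trial pre-choice `Q1..Q4`,
#'   `S1..S4`, gating signal, outcome prediction error, and the
#'   probability assigned to the first-listed and to the chosen option).
#' @examples
#' sess <- simulate_session("RW", c(alpha = 0.3, beta = 0.2),
#'                          build_schedule(1, 2, seed = 1), seed = 1)
#' head(sess$trials)
#' @export
simulate_session <- function(model, params, schedule = build_schedule(),
                             seed = NULL, participant_id = 1L) {
  spec <- model_spec(model)
  params <- as.list(params)
  .validate_params(spec, params)
  if (!is.null(seed)) set.seed(seed)
  sched <- as.data.frame(schedule)
  n <- nrow(sched)
  gated <- spec$risk_gate != "none"
  s_floor <- 1e-3

  choice <- integer(n)
  reward <- integer(n)
  trace <- matrix(NA_real_, n, 12,
    dimnames = list(NULL, c(paste0("Q", 1:4), paste0("S", 1:4),
                            "gate", "delta_out", "p_first", "p_chosen")))
  q <- s <- NULL
  prev_pe <- 0
  cur_block <- NA_integer_
  s0 <- if (!is.null(params$s0)) params$s0 else 1
  specs <- stimulus_specs()

  for (t in seq_len(n)) {
    if (is.na(cur_block) || sched$block[t] != cur_block) {
      cur_block <- sched$block[t]
      q <- rep(Q0_FIXED, 4)
      s <- rep(s0, 4)
      prev_pe <- 0
    }
    pair <- c(sched$stim_first[t], sched$stim_second[t])
    gate <- switch(spec$risk_gate,
      "none" = 0,
      "stimulus-PE" = stimulus_prediction_error(q, pair, "stimulus-PE"),
      "prediction" = stimulus_prediction_error(q, pair, "prediction"),
      "prev-outcome-PE" = prev_pe)
    a <- action_activations(q, s, pair, gated = gated,
                            omega = if (gated) params$omega else 0,
                            gate = gate)
    p <- softmax_probabilities(a, params$beta)
    ch <- pair[1 + (stats::runif(1) >= p[1])]
    r <- sample_reward(ch)
    trace[t, 1:4] <- q
    trace[t, 5:8] <- s

    u <- if (spec$utility_family == "identity") r else {
      utility_transform(r, spec$utility_family,
                        k = params[[switch(spec$utility_family,
                          "concave" = "k_concave", "convex" = "k_convex",
                          "s-shaped" = "k_s_shaped",
                          "inverse-s" = "k_inverse_s")]])
    }
    delta <- outcome_prediction_error(u, q[ch])
    delta_use <- if (spec$pe_scaling) scaled_outcome_pe(u, q[ch], s[ch]) else delta
    a_eff <- effective_learning_rate(params, spec$rate_rule, delta, ch)
    if (delta_use != 0) q <- value_update(q, ch, a_eff, delta_use)
    if (gated) {
      s <- spread_update(s, ch, params$alpha_s, delta)
    } else if (spec$pe_scaling) {
      s <- spread_update(s, ch, params$alpha_s, delta_use, scaled = TRUE)
      s[ch] <- max(s[ch], s_floor)
    }

    choice[t] <- ch
    reward[t] <- r
    trace[t, 9:12] <- c(gate, delta, p[1], p[1 + (ch != pair[1])])
    prev_pe <- delta
  }

  trials <- data.frame(
    participant = participant_id,
    block = sched$block,
    trial = sched$trial,
    stim_first = sched$stim_first,
    stim_second = sched$stim_second,
    condition = sched$condition,
    choice = choice,
    reward = reward,
    stringsAsFactors = FALSE
  )
  structure(list(model = model, params = params, trials = trials,
                 trace = as.data.frame(trace), seed = seed),
            class = "peirs_session")
}

.validate_params <- function(spec, params) {
  for (p in spec$params) {
    v <- params[[p]]
    if (is.null(v) || !is.finite(v)) {
      stop("missing or non-finite parameter `", p, "` for ", spec$name,
           call. = FALSE)
    }
  }
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  for (p in intersect(names(params),
                      c("alpha", "alpha_pos", "alpha_neg", "alpha_risky",
                        "alpha_safe", "alpha_q", "alpha_s"))) {
    chk(params[[p]] >= 0 && params[[p]] <= 1,
        paste0("`", p, "` must be in [0,1]"))
  }
  if (!is.null(params$beta)) chk(params$beta >= 0, "`beta` must be >= 0")
  if (!is.null(params$s0) && "s0" %in% spec$params) {
    chk(params$s0 > 0, "`s0` must be > 0")
  }
  if (!is.null(params$k_concave)) chk(params$k_concave > 0, "`k_concave` must be > 0")
  if (!is.null(params$k_convex)) chk(params$k_convex < 0, "`k_convex` must be < 0")
  if (!is.null(params$k_s_shaped)) {
    chk(params$k_s_shaped >= 0 && params$k_s_shaped <= 1,
        "`k_s_shaped` must be in [0,1]")
  }
  if (!is.null(params$k_inverse_s)) {
    chk(params$k_inverse_s >= 1, "`k_inverse_s` must be >= 1")
  }
  invisible(TRUE)
}

#' Log-likelihood of recorded choices under a model
#'
#' Replays the model's deterministic latent recursion against the
#' recorded choices and rewards (block-wise latent resets as in
#' [simulate_session()]) and sums the log probability assigned to each
#' recorded choice.
#'
#' @param model Model name.
#' @param params Named natural-space parameter set.
#' @param trials A trial table (or `peirs_session`).
#' @param trace If `TRUE`, also return the per-trial latent trace.
#' @return The total log-likelihood (a single number), or, with
#'   `trace = TRUE`, a list with `loglik` and a per-trial data.frame.
#' @examples
#' sess <- simulate_session("RW", c(alpha = 0.3, beta = 0.2),
#'                          build_schedule(1, 2, seed = 1), seed = 1)
#' session_log_likelihood("RW", c(alpha = 0.3, beta = 0.2), sess)
#' @export
session_log_likelihood <- function(model, params, trials, trace = FALSE) {
  spec <- model_spec(model)
  params <- as.list(params)
  .validate_params(spec, params)
  tr <- .as_trials(trials)
  out <- replay_session_cpp(
    as.integer(tr$block), as.integer(tr$stim_first),
    as.integer(tr$stim_second), as.integer(tr$choice),
    as.numeric(tr$reward),
    .util_code[[spec$utility_family]], .rate_code[[spec$rate_rule]],
    spec$pe_scaling, .gate_code[[spec$risk_gate]],
    .pack_params(spec, params), trace)
  if (!trace) return(out$loglik)
  latents <- data.frame(out$Q, out$S, gate = out$gate,
                        delta_out = out$delta_out, p_first = out$p_first,
                        p_chosen = out$p_chosen)
  names(latents)[1:8] <- c(paste0("Q", 1:4), paste0("S", 1:4))
  list(loglik = out$loglik, latents = latents)
}

#' @export
print.peirs_session <- function(x, ...) {
  cat("<peirs_session> model:", x$model, "-", nrow(x$trials), "trials,",
      length(unique(x$trials$block)), "blocks\n")
  invisible(x)
}
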