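#' The twelve candidate learning/choice models
#'
#' All models are Rescorla-Wagner variants: a delta-rule update of the
#' value `Q` of the chosen stimulus driven by the outcome prediction
#' error, plus a softmax choice rule. The variants differ in one of four
#' dials: the utility transform applied to rewards, the learning-rate
#' rule, prediction-error scaling by a learned spread, or a risk gate by
#' which the learned spread `S` enters action values through
#' `tanh(omega * gate)`.
#'
#' @return `model_names()` returns the twelve model names;
#'   `model_spec(model)` a list describing one model: `name`, `params`
#'   (natural-space parameter names in canonical order), `k` (free
#'   parameter count), and the flags `utility_family`
#'   (`identity`/`concave`/`convex`/`s-shaped`/`inverse-s`), `rate_rule`
#'   (`fixed`/`valence`/`variance`/`attention`), `pe_scaling` (logical)
#'   and `risk_gate` (`none`/`stimulus-PE`/`prediction`/`prev-outcome-PE`).
#' @examples
#' model_names()
#' model_spec("PEIRS")$params
#' @export
model_names <- function() {
  c("RW", "concave-UTIL", "convex-UTIL", "s-shaped-UTIL", "inverse-s-UTIL",
    "pos-neg-RATES", "variance-RATES", "attention-RATES", "scaled-PE",
    "PEIRS", "PIRS", "OEIRS")
}

#' @rdname model_names
#' @param model A model name from [model_names()].
#' @export
model_spec <- function(model) {
  base <- list(utility_family = "identity", rate_rule = "fixed",
               pe_scaling = FALSE, risk_gate = "none")
  gated <- c("alpha_q", "alpha_s", "beta", "omega", "s0")
  spec <- switch(model,
    "RW" = c(base, list(params = c("alpha", "beta"))),
    "concave-UTIL" = c(modifyList(base, list(utility_family = "concave")),
                       list(params = c("alpha", "beta", "k_concave"))),
    "convex-UTIL" = c(modifyList(base, list(utility_family = "convex")),
                      list(params = c("alpha", "beta", "k_convex"))),
    "s-shaped-UTIL" = c(modifyList(base, list(utility_family = "s-shaped")),
                        list(params = c("alpha", "beta", "k_s_shaped"))),
    "inverse-s-UTIL" = c(modifyList(base, list(utility_family = "inverse-s")),
                         list(params = c("alpha", "beta", "k_inverse_s"))),
    "pos-neg-RATES" = c(modifyList(base, list(rate_rule = "valence")),
                        list(params = c("alpha_pos", "alpha_neg", "beta"))),
    "variance-RATES" = c(modifyList(base, list(rate_rule = "variance")),
                         list(params = c("alpha_risky", "alpha_safe", "beta"))),
    "attention-RATES" = c(modifyList(base, list(rate_rule = "attention")),
                          list(params = c("alpha", "k_attention", "beta"))),
    "scaled-PE" = c(modifyList(base, list(pe_scaling = TRUE)),
                    list(params = c("alpha_q", "alpha_s", "s0", "beta"))),
    "PEIRS" = c(modifyList(base, list(risk_gate = "stimulus-PE")),
                list(params = gated)),
    "PIRS" = c(modifyList(base, list(risk_gate = "prediction")),
               list(params = gated)),
    "OEIRS" = c(modifyList(base, list(risk_gate = "prev-outcome-PE")),
                list(params = gated)),
    stop("unknown model: ", model, call. = FALSE)
  )
  spec$name <- model
  spec$k <- length(spec$params)
  spec
}

# initial value estimate shared by all models; utility models additionally
# fix the utility scale and shift at the middle of the reward range
Q0_FIXED <- 50
UTILITY_SCALE <- 50
UTILITY_SHIFT <- 50

#' Softmax choice probabilities over two action activations
#'
#' `p_i = exp(beta * A_i) / sum_j exp(beta * A_j)`, computed with the
#' maximum subtracted for numerical stability.
#'
#' @param activations Numeric vector of action activations (length 2 in
#'   this task, but any length is accepted).
#' @param beta Inverse temperature, `>= 0`.
#' @return Probabilities in (0,1) summing to 1.
#' @examples
#' softmax_probabilities(c(60, 40), beta = 0.1)
#' @export
softmax_probabilities <- function(activations, beta) {
  if (any(!is.finite(activations))) {
    stop("activations must be finite", call. = FALSE)
  }
  if (length(beta) != 1 || !is.finite(beta) || beta < 0) {
    stop("`beta` must be a single non-negative number", call. = FALSE)
  }
  z <- beta * activations
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Outcome prediction error
#'
#' The reward prediction error at outcome time: received reward (or its
#' utility) minus the chosen stimulus's current value estimate.
#'
#' @param r Reward (or utility-transformed reward).
#' @param q_chosen Current value estimate of the chosen stimulus.
#' @return \code{r - q_chosen}.
#' @export
outcome_prediction_error <- function(r, q_chosen) {
  r - q_chosen
}

#' Stimulus prediction error at option presentation
#'
#' In `"stimulus-PE"` mode (PEIRS) this is the mean value of the two
#' shown options minus the mean value of all four options — the reward
#' prediction error caused by discovering which pair is on offer. In
#' `"prediction"` mode (PIRS) it is just the pair mean.
#'
#' @param q Numeric 4-vector of current value estimates.
#' @param pair Integer vector of length 2, the shown stimulus ids.
#' @param mode `"stimulus-PE"` or `"prediction"`.
#' @return A single number in points.
#' @examples
#' stimulus_prediction_error(c(60, 60, 40, 40), c(1, 2))  # +10
#' @export
stimulus_prediction_error <- function(q, pair, mode = c("stimulus-PE", "prediction")) {
  mode <- match.arg(mode)
  stopifnot(length(q) == 4, length(pair) == 2)
  pair_mean <- mean(q[pair])
  if (mode == "prediction") pair_mean else pair_mean - mean(q)
}

#' Utility transform of a reward
#'
#' Maps a reward in points onto a subjective utility scale centred on the
#' middle of the reward range: with `z = (r - m) / sigma`,
#' the exponential family gives `U = m + sigma * (1 - exp(-k z)) / k`
#' (concave for `k > 0`, convex for `k < 0`), and the sign-preserving
#' power family gives `U = m + sigma * sign(z) * |z|^k` (s-shaped for
#' `k` in (0,1], inverse-s-shaped for `k >= 1`). The identity family
#' returns `r` unchanged.
#'
#' @param r Reward(s) in points.
#' @param family One of `"identity"`, `"concave"`, `"convex"`,
#'   `"s-shaped"`, `"inverse-s"`.
#' @param k Curvature parameter; its admissible range depends on the
#'   family (`k_concave > 0`, `k_convex < 0`, `k_s_shaped` in `[0,1]`,
#'   `k_inverse_s >= 1`).
#' @param sigma,m Fixed scale and shift of the transform (both 50).
#' @return Utility value(s).
#' @examples
#' utility_transform(99, "concave", k = 0.1)
#' @export
utility_transform <- function(r, family = "identity", k = NULL,
                              sigma = UTILITY_SCALE, m = UTILITY_SHIFT) {
  if (family == "identity") return(r)
  if (is.null(k) || !is.finite(k)) stop("`k` required", call. = FALSE)
  bad <- switch(family,
    "concave" = k <= 0,
    "convex" = k >= 0,
    "s-shaped" = k < 0 || k > 1,
    "inverse-s" = k < 1,
    stop("unknown utility family: ", family, call. = FALSE))
  if (bad) stop("`k` outside the admissible range for ", family, call. = FALSE)
  z <- (r - m) / sigma
  if (family %in% c("concave", "convex")) {
    m + sigma * (1 - exp(-k * z)) / k
  } else {
    m + sigma * sign(z) * abs(z)^k
  }
}

#' Effective learning rate under the model's rate rule
#'
#' `fixed` uses a single rate; `valence` picks `alpha_pos`/`alpha_neg` by
#' the sign of the outcome prediction error; `variance` picks
#' `alpha_risky`/`alpha_safe` by the chosen stimulus (risky arms are 1
#' and 3); `attention` multiplies the base rate by `|delta|^k_attention`
#' (surprise-weighted learning, which may exceed 1 for large surprises —
#' no clamp is applied).
#'
#' @param params Named list/vector of natural-space parameters.
#' @param rate_rule One of `"fixed"`, `"valence"`, `"variance"`,
#'   `"attention"`.
#' @param delta Outcome prediction error of the current trial.
#' @param chosen Chosen stimulus id (1..4).
#' @return The effective learning rate.
#' @export
effective_learning_rate <- function(params, rate_rule, delta, chosen) {
  params <- as.list(params)
  switch(rate_rule,
    "fixed" = if (!is.null(params$alpha)) params$alpha else params$alpha_q,
    "valence" = if (delta >= 0) params$alpha_pos else params$alpha_neg,
    "variance" = if (chosen %in% c(1, 3)) params$alpha_risky else params$alpha_safe,
    "attention" = params$alpha * abs(delta)^params$k_attention,
    stop("unknown rate rule: ", rate_rule, call. = FALSE)
  )
}

#' Spread-scaled outcome prediction error
#'
#' Divides the outcome prediction error by the chosen stimulus's learned
#' spread, so that learning adapts to the perceived reward variability.
#'
#' @param r Reward.
#' @param q_chosen Value estimate of the chosen stimulus.
#' @param s_chosen Spread estimate of the chosen stimulus; must be
#'   strictly positive.
#' @return `(r - q_chosen) / s_chosen`.
#' @export
scaled_outcome_pe <- function(r, q_chosen, s_chosen) {
  if (s_chosen <= 0) stop("spread estimate must be positive", call. = FALSE)
  (r - q_chosen) / s_chosen
}

#' Delta-rule updates of value and spread
#'
#' `value_update()` moves the chosen stimulus's value by
#' `alpha_eff * delta` and leaves the other entries untouched.
#' `spread_update()` moves the chosen stimulus's spread towards the
#' absolute prediction error, `S <- S + alpha_s * (|delta| - S)`; with
#' `scaled = TRUE` (scaled-PE model) it instead tracks the calibration
#' residual `|delta_scaled| - 1`.
#'
#' @param q,s Numeric 4-vectors of value / spread estimates.
#' @param chosen Chosen stimulus id.
#' @param alpha_eff,alpha_s Learning rates.
#' @param delta Prediction error driving the update.
#' @param scaled Use the scaled-PE form of the spread update.
#' @return The updated 4-vector.
#' @export
value_update <- function(q, chosen, alpha_eff, delta) {
  q[chosen] <- q[chosen] + alpha_eff * delta
  q
}

#' @rdname value_update
#' @export
spread_update <- function(s, chosen, alpha_s, delta, scaled = FALSE) {
  if (alpha_s < 0 || alpha_s > 1) stop("`alpha_s` must be in [0,1]", call. = FALSE)
  s[chosen] <- if (scaled) {
    s[chosen] + alpha_s * (abs(delta) - 1)
  } else {
    s[chosen] + alpha_s * (abs(delta) - s[chosen])
  }
  s
}

#' Action activations for the shown pair
#'
#' Non-gated models act on the value estimates directly. Gated models
#' (PEIRS family) add the learned spread, weighted by `tanh(omega *
#' gate)` where `gate` is the model's dopaminergic gating signal: the
#' stimulus prediction error (PEIRS), the pair-mean prediction (PIRS) or
#' the previous trial's outcome prediction error (OEIRS). Positive gates
#' make the spread attractive (risk-seeking); negative gates make it
#' repulsive (risk-aversion).
#'
#' @param q,s Numeric 4-vectors of value / spread estimates (`s` ignored
#'   when `gated = FALSE`).
#' @param pair The two shown stimulus ids.
#' @param gated Whether the spread enters the activation.
#' @param omega Gating gain (unbounded).
#' @param gate The gating signal in points.
#' @return Numeric activations for the two shown options, in pair order.
#' @examples
#' action_activations(c(60, 60, 40, 40), c(16, 5, 16, 5), c(1, 2),
#'                    gated = TRUE, omega = 0.5, gate = 10)
#' @export
action_activations <- function(q, s = NULL, pair, gated = FALSE,
                               omega = 0, gate = 0) {
  if (!gated) return(q[pair])
  q[pair] + tanh(omega * gate) * s[pair]
}
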