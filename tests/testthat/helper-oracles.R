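# Independent reference implementations used as oracles. These are written
# directly from the model equations, without calling the package's
# simulation or likelihood code paths.

# naive trial-by-trial replay: returns the per-trial probability assigned
# to the recorded choice and the total log-likelihood
oracle_replay <- function(model, par, trials) {
  par <- as.list(par)
  n <- nrow(trials)
  p_chosen <- numeric(n)
  q <- s <- NULL
  prev <- 0
  blk <- NA
  for (t in seq_len(n)) {
    if (is.na(blk) || trials$block[t] != blk) {
      blk <- trials$block[t]
      q <- rep(50, 4)
      s <- rep(if (is.null(par$s0)) 1 else par$s0, 4)
      prev <- 0
    }
    o1 <- trials$stim_first[t]; o2 <- trials$stim_second[t]
    ch <- trials$choice[t]; r <- trials$reward[t]

    if (model %in% c("PEIRS", "PIRS", "OEIRS")) {
      d <- switch(model,
        "PEIRS" = (q[o1] + q[o2]) / 2 - sum(q) / 4,
        "PIRS" = (q[o1] + q[o2]) / 2,
        "OEIRS" = prev)
      w <- tanh(par$omega * d)
      a1 <- q[o1] + w * s[o1]
      a2 <- q[o2] + w * s[o2]
    } else {
      a1 <- q[o1]; a2 <- q[o2]
    }
    e1 <- exp(par$beta * (a1 - max(a1, a2)))
    e2 <- exp(par$beta * (a2 - max(a1, a2)))
    p1 <- e1 / (e1 + e2)
    p_chosen[t] <- if (ch == o1) p1 else 1 - p1

    u <- r
    if (model == "concave-UTIL") {
      z <- (r - 50) / 50; u <- 50 + 50 * (1 - exp(-par$k_concave * z)) / par$k_concave
    } else if (model == "convex-UTIL") {
      z <- (r - 50) / 50; u <- 50 + 50 * (1 - exp(-par$k_convex * z)) / par$k_convex
    } else if (model == "s-shaped-UTIL") {
      z <- (r - 50) / 50; u <- 50 + 50 * sign(z) * abs(z)^par$k_s_shaped
    } else if (model == "inverse-s-UTIL") {
      z <- (r - 50) / 50; u <- 50 + 50 * sign(z) * abs(z)^par$k_inverse_s
    }
    d_out <- u - q[ch]
    if (model == "scaled-PE") {
      d_sc <- d_out / s[ch]
      q[ch] <- q[ch] + par$alpha_q * d_sc
      s[ch] <- max(s[ch] + par$alpha_s * (abs(d_sc) - 1), 1e-3)
    } else {
      a_eff <- switch(model,
        "pos-neg-RATES" = if (d_out >= 0) par$alpha_pos else par$alpha_neg,
        "variance-RATES" = if (ch %in% c(1, 3)) par$alpha_risky else par$alpha_safe,
        "attention-RATES" = par$alpha * abs(d_out)^par$k_attention,
        "PEIRS" = , "PIRS" = , "OEIRS" = par$alpha_q,
        par$alpha)
      if (d_out != 0) q[ch] <- q[ch] + a_eff * d_out
      if (model %in% c("PEIRS", "PIRS", "OEIRS")) {
        s[ch] <- s[ch] + par$alpha_s * (abs(d_out) - s[ch])
      }
    }
    prev <- d_out
  }
  list(loglik = sum(log(p_chosen)), p_chosen = p_chosen)
}

# textbook one-sample t statistic
oracle_t <- function(x, mu = 0) {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1, p = p)
}

# mean and sd of a rounded, clipped Gaussian by direct enumeration over
# the integer support
oracle_clipped_moments <- function(mu, sigma) {
  v <- 1:99
  p <- numeric(99)
  for (k in 2:98) p[k] <- pnorm(k + 0.5, mu, sigma) - pnorm(k - 0.5, mu, sigma)
  p[1] <- pnorm(1.5, mu, sigma)
  p[99] <- 1 - pnorm(98.5, mu, sigma)
  m <- sum(v * p)
  list(mean = m, sd = sqrt(sum((v - m)^2 * p)))
}

# a small fast schedule for unit tests
quick_schedule <- function(n_blocks = 1, reps = 2, seed = 42) {
  build_schedule(n_blocks, reps, seed = seed)
}
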