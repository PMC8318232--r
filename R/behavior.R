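.high_value_ids <- c(1, 2)

#' Behavioural inclusion filter
#'
#' A participant is included when they chose the high-valued option in
#' strictly more than 65% of the different-condition trials of the
#' second half of the blocks (within-block trials 61 onwards, pooled
#' across blocks) — evidence that they understood and learned the task.
#'
#' @param trials A single participant's trial table or `peirs_session`.
#' @param threshold Inclusion threshold on the high-value choice
#'   proportion (strict inequality; default 0.65).
#' @return Logical; the measured proportion is attached as attribute
#'   `proportion`. No qualifying trials gives `FALSE` with a warning.
#' @export
inclusion_filter <- function(trials, threshold = 0.65) {
  tr <- .as_trials(trials)
  half <- max(tr$trial) / 2
  sel <- tr$condition == "different" & tr$trial > half
  if (!any(sel)) {
    warning("no late different-condition trials; treating as excluded")
    return(structure(FALSE, proportion = NA_real_))
  }
  prop <- mean(tr$choice[sel] %in% .high_value_ids)
  structure(prop > threshold, proportion = prop)
}

#' Binned accuracy trace in the different condition
#'
#' Probability of choosing the high-mean option as a function of
#' within-block trial number: choices are binned by trial number,
#' participant means are computed per bin first, then the cohort mean
#' and standard error of those means.
#'
#' @param trials A multi-participant trial table (or `peirs_cohort`).
#' @param bin_width Trials per bin; must divide the block length.
#' @return A data.frame with `bin`, `trial_mid`, `mean`, `se`, `n`.
#' @export
accuracy_trace <- function(trials, bin_width = 10) {
  tr <- if (inherits(trials, "peirs_cohort")) cohort_trials(trials)
        else .as_trials(trials)
  block_len <- max(tr$trial)
  if (block_len %% bin_width != 0) {
    stop("`bin_width` must divide the block length (", block_len, ")",
         call. = FALSE)
  }
  dd <- tr[tr$condition == "different", ]
  dd$bin <- ceiling(dd$trial / bin_width)
  dd$correct <- as.numeric(dd$choice %in% .high_value_ids)
  per_part <- stats::aggregate(correct ~ participant + bin, dd, mean)
  agg_mean <- stats::aggregate(correct ~ bin, per_part, mean)
  agg_sd <- stats::aggregate(correct ~ bin, per_part, stats::sd)
  agg_n <- stats::aggregate(correct ~ bin, per_part, length)
  data.frame(bin = agg_mean$bin,
             trial_mid = (agg_mean$bin - 0.5) * bin_width,
             mean = agg_mean$correct,
             se = agg_sd$correct / sqrt(agg_n$correct),
             n = agg_n$correct)
}

# t statistics robust to zero-variance input (constant data gives t = 0
# when the mean equals the null value)
.safe_t <- function(x, mu = 0, paired_with = NULL) {
  if (!is.null(paired_with)) x <- x - paired_with
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(list(t = NA_real_, df = NA_real_, p = NA_real_, n = n))
  s <- stats::sd(x)
  if (s == 0) {
    t <- if (mean(x) == mu) 0 else sign(mean(x) - mu) * Inf
    p <- if (t == 0) 1 else 0
    return(list(t = t, df = n - 1, p = p, n = n, mean = mean(x)))
  }
  tt <- stats::t.test(x, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = n, mean = mean(x))
}

#' Condition contrasts on risk preferences
#'
#' The cohort-level test battery on per-participant risk preferences
#' computed across all trials: a two-tailed paired t-test of both-high
#' versus both-low preference (the main condition-difference effect) and
#' two-tailed one-sample t-tests of each condition against indifference
#' (0.5). Participants with an undefined preference in a condition drop
#' out of the tests involving it.
#'
#' @param trials A multi-participant trial table or `peirs_cohort`.
#' @return A list of class `condition_tests` with elements `paired`,
#'   `both_high_vs_chance`, `both_low_vs_chance` (each `t`, `df`, `p`,
#'   `n`, `mean`) and the per-participant `summary` data.frame.
#' @export
condition_tests <- function(trials) {
  tr <- if (inherits(trials, "peirs_cohort")) cohort_trials(trials)
        else .as_trials(trials)
  rs <- risk_summary(tr)
  if (nrow(rs) < 2) stop("need at least 2 participants", call. = FALSE)
  out <- list(
    paired = .safe_t(rs$both_high, mu = 0, paired_with = rs$both_low),
    both_high_vs_chance = .safe_t(rs$both_high, mu = 0.5),
    both_low_vs_chance = .safe_t(rs$both_low, mu = 0.5),
    summary = rs
  )
  class(out) <- "condition_tests"
  out
}

#' @export
print.condition_tests <- function(x, ...) {
  fmt <- function(nm, r) {
    cat(sprintf("  %-22s t(%g) = %.3f, p = %.4g (n = %d)\n",
                nm, r$df, r$t, r$p, r$n))
  }
  cat("<condition_tests>\n")
  fmt("both-high vs both-low:", x$paired)
  fmt("both-high vs 0.5:", x$both_high_vs_chance)
  fmt("both-low vs 0.5:", x$both_low_vs_chance)
  invisible(x)
}

#' Emergence-speed test: value versus risk preferences
#'
#' Tests whether value preferences (choosing the high-mean option in
#' different-condition trials) emerge faster over a block than risk
#' preferences (choosing the asymptotically preferred option in the
#' matched-mean conditions: risky in both-high, safe in both-low). Per
#' participant and decision type, a logistic regression of the
#' preferred-choice indicator on within-block trial number yields a
#' slope; the cohort of per-participant slope differences (value minus
#' risk) is tested against zero with a two-tailed t-test. Logistic fits
#' with separation are clipped to `slope_cap` and flagged.
#'
#' @param trials A multi-participant trial table or `peirs_cohort`.
#' @param slope_cap Absolute cap on per-fit slopes (logit per trial).
#' @return A list of class `emergence_test`: `t`, `df`, `p`,
#'   `mean_diff`, `slopes` (per participant: value and risk slope,
#'   clipped flags).
#' @export
emergence_test <- function(trials, slope_cap = 1) {
  tr <- if (inherits(trials, "peirs_cohort")) cohort_trials(trials)
        else .as_trials(trials)
  preferred <- ifelse(tr$condition == "different",
                      tr$choice %in% .high_value_ids,
                      ifelse(tr$condition == "both-high",
                             tr$choice %in% .risky_ids,
                             !(tr$choice %in% .risky_ids)))
  tr$preferred <- as.numeric(preferred)
  tr$decision_type <- ifelse(tr$condition == "different", "value", "risk")

  slope_of <- function(sub) {
    if (length(unique(sub$preferred)) < 2) {
      return(list(slope = 0, clipped = TRUE))
    }
    fit <- suppressWarnings(
      stats::glm(preferred ~ trial, family = stats::binomial(), data = sub))
    sl <- unname(stats::coef(fit)["trial"])
    separated <- !fit$converged ||
      any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
    clipped <- FALSE
    if (!is.finite(sl) || (separated && abs(sl) > slope_cap) ||
        abs(sl) > slope_cap) {
      sl <- sign(sl) * slope_cap
      clipped <- TRUE
    }
    list(slope = sl, clipped = clipped)
  }

  parts <- unique(tr$participant)
  rows <- lapply(parts, function(p) {
    sub <- tr[tr$participant == p, ]
    v <- slope_of(sub[sub$decision_type == "value", ])
    r <- slope_of(sub[sub$decision_type == "risk", ])
    data.frame(participant = p, value_slope = v$slope, risk_slope = r$slope,
               value_clipped = v$clipped, risk_clipped = r$clipped)
  })
  slopes <- do.call(rbind, rows)
  tt <- .safe_t(slopes$value_slope - slopes$risk_slope, mu = 0)
  structure(list(t = tt$t, df = tt$df, p = tt$p,
                 mean_diff = mean(slopes$value_slope - slopes$risk_slope),
                 slopes = slopes),
            class = "emergence_test")
}

#' @export
print.emergence_test <- function(x, ...) {
  cat(sprintf("<emergence_test> value - risk slope: mean %.4g, t(%g) = %.3f, p = %.4g\n",
              x$mean_diff, x$df, x$t, x$p))
  invisible(x)
}

#' Full behavioural analysis of a cohort
#'
#' Applies the inclusion filter, then runs the accuracy trace, the
#' condition contrasts and the emergence-speed test on the included
#' participants — identically applicable to empirical or synthetic
#' cohorts in the package CSV dialect.
#'
#' @param trials A multi-participant trial table or `peirs_cohort`.
#' @param bin_width Bin width of the accuracy trace.
#' @param filter Apply the inclusion filter before analysis.
#' @return A list of class `cohort_analysis`: `included` (ids),
#'   `excluded`, `inclusion` (per-participant proportions), `accuracy`,
#'   `tests`, `emergence`.
#' @export
analyze_cohort <- function(trials, bin_width = 10, filter = TRUE) {
  tr <- if (inherits(trials, "peirs_cohort")) cohort_trials(trials)
        else .as_trials(trials)
  parts <- unique(tr$participant)
  incl <- vapply(parts, function(p) {
    f <- inclusion_filter(tr[tr$participant == p, ])
    c(isTRUE(f[1]), attr(f, "proportion"))
  }, numeric(2))
  included <- parts[incl[1, ] == 1]
  if (!filter) included <- parts
  if (length(included) < 2) {
    stop("fewer than 2 included participants", call. = FALSE)
  }
  sub <- tr[tr$participant %in% included, ]
  structure(list(
    included = included,
    excluded = setdiff(parts, included),
    inclusion = data.frame(participant = parts, proportion = incl[2, ],
                           included = incl[1, ] == 1),
    accuracy = accuracy_trace(sub, bin_width),
    tests = condition_tests(sub),
    emergence = emergence_test(sub)
  ), class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>", length(x$included), "included,",
      length(x$excluded), "excluded\n")
  print(x$tests)
  print(x$emergence)
  invisible(x)
}
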