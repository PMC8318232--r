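# Raw-space (unconstrained) parameterization used for fitting, and the
# Gaussian priors placed on it. Learning rates live on the logit scale,
# strictly positive parameters on the log scale, the convex curvature as
# log(-k), the inverse-s curvature as log(k - 1); omega and k_attention
# are unconstrained. Prior entries are (mean, variance) of the raw value;
# shared parameters share priors across models.

.param_table <- function() {
  rates <- c("alpha", "alpha_pos", "alpha_neg", "alpha_risky", "alpha_safe",
             "alpha_q", "alpha_s")
  tab <- list()
  for (p in rates) tab[[p]] <- list(transform = "logit", mean = -1, var = 2)
  tab$beta <- list(transform = "log", mean = -2, var = 2)
  tab$k_concave <- list(transform = "log", mean = -3, var = 4)
  tab$k_convex <- list(transform = "neglog", mean = -3, var = 4)
  tab$k_s_shaped <- list(transform = "logit", mean = 3, var = 4)
  tab$k_inverse_s <- list(transform = "log1p_shift", mean = -3, var = 4)
  tab$k_attention <- list(transform = "identity", mean = 0, var = 4)
  tab$omega <- list(transform = "identity", mean = 0, var = 20)
  tab$s0 <- list(transform = "log", mean = 2, var = 2)
  tab
}

#' Prior specification for a model's parameters
#'
#' Returns, for each free parameter of `model`, the raw-to-natural
#' transform and the mean and variance of the independent Gaussian prior
#' on the raw (untransformed) value.
#'
#' @param model A model name from [model_names()].
#' @return A data.frame with columns `param`, `transform`, `mean`, `var`.
#' @examples
#' prior_spec("PEIRS")
#' @export
prior_spec <- function(model) {
  spec <- model_spec(model)
  tab <- .param_table()
  rows <- lapply(spec$params, function(p) {
    e <- tab[[p]]
    if (is.null(e)) stop("no prior defined for parameter ", p, call. = FALSE)
    data.frame(param = p, transform = e$transform, mean = e$mean, var = e$var,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.apply_transform <- function(raw, transform) {
  switch(transform,
    "logit" = .sigmoid(raw),
    "log" = exp(raw),
    "neglog" = -exp(raw),
    "log1p_shift" = 1 + exp(raw),
    "identity" = raw,
    stop("unknown transform: ", transform, call. = FALSE))
}

.invert_transform <- function(natural, transform) {
  out <- switch(transform,
    "logit" = {
      if (any(natural <= 0 | natural >= 1)) {
        stop("logit inverse requires values strictly inside (0,1)", call. = FALSE)
      }
      log(natural / (1 - natural))
    },
    "log" = {
      if (any(natural <= 0)) stop("log inverse requires positive values", call. = FALSE)
      log(natural)
    },
    "neglog" = {
      if (any(natural >= 0)) stop("neglog inverse requires negative values", call. = FALSE)
      log(-natural)
    },
    "log1p_shift" = {
      if (any(natural <= 1)) stop("inverse requires values > 1", call. = FALSE)
      log(natural - 1)
    },
    "identity" = natural,
    stop("unknown transform: ", transform, call. = FALSE))
  out
}

#' Map parameters between raw (fitting) and natural space
#'
#' @param raw,natural Named or unnamed numeric vector in the model's
#'   canonical parameter order (see [model_spec()]).
#' @param model Model name.
#' @return A named numeric vector in the other space.
#' @examples
#' transform_parameters(c(-1, -2), "RW")  # alpha ~ 0.269, beta ~ 0.135
#' @export
transform_parameters <- function(raw, model) {
  ps <- prior_spec(model)
  if (length(raw) != nrow(ps)) stop("wrong parameter count", call. = FALSE)
  out <- vapply(seq_len(nrow(ps)), function(i) {
    .apply_transform(unname(raw[i]), ps$transform[i])
  }, numeric(1))
  names(out) <- ps$param
  out
}

#' @rdname transform_parameters
#' @export
untransform_parameters <- function(natural, model) {
  ps <- prior_spec(model)
  if (!is.null(names(natural))) natural <- natural[ps$param]
  if (length(natural) != nrow(ps) || any(is.na(natural))) {
    stop("wrong or incomplete parameter set", call. = FALSE)
  }
  out <- vapply(seq_len(nrow(ps)), function(i) {
    .invert_transform(unname(natural[i]), ps$transform[i])
  }, numeric(1))
  names(out) <- ps$param
  out
}

#' Log prior density of a raw-space parameter vector
#'
#' Sum of independent univariate Gaussian log-densities with the model's
#' prior means and variances.
#'
#' @param raw Raw-space parameter vector in canonical order.
#' @param model Model name.
#' @return A single number.
#' @export
log_prior <- function(raw, model) {
  ps <- prior_spec(model)
  if (length(raw) != nrow(ps)) stop("wrong parameter count", call. = FALSE)
  sum(stats::dnorm(raw, mean = ps$mean, sd = sqrt(ps$var), log = TRUE))
}
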