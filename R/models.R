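#' Model specifications
#'
#' The model menu maps learner predictions onto the mean of the shifted
#' log-normal RT likelihood:
#'
#' * `baseline` — trial slope and motor-target offsets only (no prediction
#'   of upcoming nodes).
#' * `recency` — adds `beta_A * W[s_t]` from the recency learner plus the
#'   recency nuisance regressors.
#' * `onestep` — `beta_A * T[s_prev, s_t]` from the one-step learner.
#' * `sr_td` — `beta_A * M[s_prev, s_t] / sum(M[s_prev, ])` from
#'   SR-TD(lambda).
#' * `sr_static` — same readout from the non-learning SR of the empirical
#'   transition matrix.
#' * `combined_*` — a higher-order predictor (`beta_A`, learning rate
#'   `alpha_A`) alongside an independent recency component (`beta_W`,
#'   `alpha_W`).
#' * `hebbian` / `combined_hebbian` — the trace-only Hebbian SR learner,
#'   used for simulation agents.
#'
#' Nuisance regressors (trials since the current node last occurred, and
#' log occurrences in the last 10 trials) enter every non-baseline model.
#'
#' @param model model name (see above).
#' @param fixed named list of learner parameters to clamp at fixed natural
#'   values instead of fitting (e.g. `list(lam = 1)` for SR-TD with the
#'   trace parameter pinned).
#' @param n_targets number of motor-target categories (default 15;
#'   category 1 is absorbed into the intercept).
#' @return A `model_spec` list with the model code shared with the compiled
#'   backend, predictor flags, and parameter bookkeeping.
#' @export
model_spec <- function(model, fixed = list(), n_targets = 15L) {
  defs <- list(
    baseline         = list(code = 0L, has_A = FALSE, has_W = FALSE,
                            nl = "shift_frac", static = FALSE),
    recency          = list(code = 1L, has_A = TRUE, has_W = FALSE,
                            nl = c("shift_frac", "alpha_A"), static = FALSE),
    onestep          = list(code = 2L, has_A = TRUE, has_W = FALSE,
                            nl = c("shift_frac", "alpha_A"), static = FALSE),
    sr_td            = list(code = 3L, has_A = TRUE, has_W = FALSE,
                            nl = c("shift_frac", "alpha_A", "gamma", "lam"),
                            static = FALSE),
    sr_static        = list(code = 4L, has_A = TRUE, has_W = FALSE,
                            nl = c("shift_frac", "gamma"), static = TRUE),
    combined_onestep = list(code = 5L, has_A = TRUE, has_W = TRUE,
                            nl = c("shift_frac", "alpha_A", "alpha_W"),
                            static = FALSE),
    combined_sr_td   = list(code = 6L, has_A = TRUE, has_W = TRUE,
                            nl = c("shift_frac", "alpha_A", "alpha_W",
                                   "gamma", "lam"),
                            static = FALSE),
    combined_sr_static = list(code = 7L, has_A = TRUE, has_W = TRUE,
                              nl = c("shift_frac", "gamma", "alpha_W"),
                              static = TRUE),
    hebbian          = list(code = 8L, has_A = TRUE, has_W = FALSE,
                            nl = c("shift_frac", "alpha_A", "gamma"),
                            static = FALSE),
    combined_hebbian = list(code = 9L, has_A = TRUE, has_W = TRUE,
                            nl = c("shift_frac", "alpha_A", "alpha_W",
                                   "gamma"),
                            static = FALSE))
  if (!model %in% names(defs)) {
    stop("unknown model '", model, "'; available: ",
         paste(names(defs), collapse = ", "))
  }
  d <- defs[[model]]
  if (length(fixed)) {
    bad <- setdiff(names(fixed), d$nl)
    if (length(bad)) stop("cannot fix parameter(s) not in model: ",
                          paste(bad, collapse = ", "))
  }
  lin <- c("mu0", "beta_trial", paste0("target", 2:n_targets))
  if (d$code != 0L) lin <- c(lin, "beta_ntrials", "beta_lag10")
  if (d$has_A) lin <- c(lin, "beta_A")
  if (d$has_W) lin <- c(lin, "beta_W")
  nl_free <- setdiff(d$nl, names(fixed))
  structure(list(model = model, code = d$code, has_A = d$has_A,
                 has_W = d$has_W, static = d$static,
                 linear = lin, nl = d$nl, nl_free = nl_free,
                 fixed = fixed, n_targets = as.integer(n_targets),
                 names = c(lin, "sigma", nl_free)),
            class = "model_spec")
}

# Transform type of each parameter: (0,1) quantities are logit-mapped,
# sigma is log-mapped, everything else (means, slopes, offsets) identity.
param_transform_type <- function(name) {
  if (name %in% c("shift_frac", "alpha_A", "alpha_W", "gamma", "lam"))
    "logit"
  else if (name == "sigma") "log"
  else "identity"
}

#' Map parameters between natural and unconstrained scales
#'
#' Rates, discount, trace parameter and shift fraction live in (0, 1) and
#' are logit-mapped; `sigma` is log-mapped; location/slope parameters are
#' untouched. The hierarchical prior is an identity-covariance Gaussian on
#' the unconstrained scale, so bounds are enforced by the transform rather
#' than box constraints.
#'
#' @param x named numeric vector of parameter values.
#' @return Named numeric vector on the other scale.
#' @export
to_unconstrained <- function(x) {
  out <- x
  for (nm in names(x)) {
    out[[nm]] <- switch(param_transform_type(nm),
                        logit = logit(x[[nm]]),
                        log = log(x[[nm]]),
                        identity = x[[nm]])
  }
  out
}

#' @rdname to_unconstrained
#' @export
from_unconstrained <- function(x) {
  out <- x
  for (nm in names(x)) {
    out[[nm]] <- switch(param_transform_type(nm),
                        logit = inv_logit(x[[nm]]),
                        log = exp(x[[nm]]),
                        identity = x[[nm]])
  }
  out
}

# Fill the 5-slot nonlinear parameter set used by the compiled backend from
# a named natural-scale list, honoring the model_spec's clamped values.
nl_values <- function(spec, natural) {
  full <- list(shift_frac = 0.5, alpha_A = 0.1, alpha_W = 0.1,
               gamma = 0, lam = 0)
  for (nm in spec$nl) {
    full[[nm]] <- if (nm %in% names(spec$fixed)) spec$fixed[[nm]]
                  else natural[[nm]]
  }
  full
}
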