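#' Fitting configuration
#'
#' Bundles the tunable knobs of the observation model and the optimizer.
#'
#' @param equilibrate number of initial trials per stage whose RTs are
#'   excluded from the likelihood (the learner still sees them); default
#'   500, matching a 1500-trial stage fit on its last 1000 trials.
#' @param z_score_nuisance z-score the recency nuisance regressors within
#'   session before they enter the likelihood (keeps their weights
#'   comparable across subjects); default `TRUE`.
#' @param n_targets number of motor-target categories.
#' @param n_nodes number of graph nodes.
#' @param n_restarts optimizer restarts per subject fit.
#' @param max_em_iter,em_tol EM stopping rule: stop when the largest change
#'   in any group-mean coordinate falls below `em_tol` or after
#'   `max_em_iter` iterations.
#' @param extra_restarts additional restarts granted to a session whose
#'   first round of starts failed to converge.
#' @param nm_maxit,nm_reltol Nelder-Mead budget for the profiled
#'   nonlinear-parameter search.
#' @return A `fit_config` list.
#' @export
fit_config <- function(equilibrate = 500L, z_score_nuisance = TRUE,
                       n_targets = 15L, n_nodes = 15L, n_restarts = 3L,
                       max_em_iter = 50L, em_tol = 1e-3,
                       extra_restarts = 5L, nm_maxit = 600L,
                       nm_reltol = 1e-9) {
  structure(list(equilibrate = as.integer(equilibrate),
                 z_score_nuisance = isTRUE(z_score_nuisance),
                 n_targets = as.integer(n_targets),
                 n_nodes = as.integer(n_nodes),
                 n_restarts = as.integer(n_restarts),
                 max_em_iter = as.integer(max_em_iter),
                 em_tol = em_tol,
                 extra_restarts = as.integer(extra_restarts),
                 nm_maxit = as.integer(nm_maxit),
                 nm_reltol = nm_reltol),
            class = "fit_config")
}

#' Preprocess a trial table
#'
#' Flags trials excluded from the likelihood (incorrect responses and
#' implausible RTs below 30 ms) and rescales the trial index to `[0, 1]`
#' within each subject-by-stage sequence. Excluded trials are retained in
#' the table — the learners advance over the full stimulus sequence; only
#' their RTs never contribute likelihood.
#'
#' @param raw trial table with columns `subject, graphset, stage, trial,
#'   node, target, rt_ms, correct`.
#' @param min_rt_ms implausibility threshold (default 30 ms).
#' @return The table with added logical `included` and numeric
#'   `trial_scaled` columns.
#' @export
preprocess <- function(raw, min_rt_ms = 30) {
  if (nrow(raw) == 0L) stop("empty trial table")
  needed <- c("subject", "graphset", "stage", "trial", "node", "target",
              "rt_ms", "correct")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) stop("missing column(s): ",
                            paste(missing, collapse = ", "))
  raw$included <- as.logical(raw$correct) & raw$rt_ms >= min_rt_ms
  key <- interaction(raw$subject, raw$graphset, raw$stage, drop = TRUE)
  raw$trial_scaled <- stats::ave(as.numeric(raw$trial), key, FUN = function(tr) {
    if (length(tr) == 1L) return(0)
    (tr - min(tr)) / (max(tr) - min(tr))
  })
  raw
}

#' Recency nuisance regressors
#'
#' For each trial: the number of trials elapsed since the current node last
#' occurred (`r_ntrials`; for a never-before-seen node, the trial index,
#' flagged), and the log of 1 plus the number of occurrences of the current
#' node within the preceding 10 trials (`r_lag10`; the +1 keeps the
#' regressor finite when the count is zero).
#'
#' @param nodes integer node sequence (1-based).
#' @return A data.frame with columns `r_ntrials`, `r_lag10`,
#'   `first_occurrence`.
#' @export
nuisance_regressors <- function(nodes) {
  T <- length(nodes)
  last_seen <- rep(NA_integer_, max(nodes))
  r_ntrials <- numeric(T)
  r_lag10 <- numeric(T)
  first <- logical(T)
  for (t in seq_len(T)) {
    v <- nodes[t]
    if (is.na(last_seen[v])) {
      r_ntrials[t] <- t
      first[t] <- TRUE
    } else {
      r_ntrials[t] <- t - last_seen[v]
    }
    lo <- max(1L, t - 10L)
    cnt <- if (t == 1L) 0L else sum(nodes[lo:(t - 1L)] == v)
    r_lag10[t] <- log(1 + cnt)
    last_seen[v] <- t
  }
  data.frame(r_ntrials = r_ntrials, r_lag10 = r_lag10,
             first_occurrence = first)
}

# Design matrix of the fixed (parameter-independent) regressors for one
# session: intercept, rescaled trial, motor-target dummies for categories
# 2..n_targets, and (non-baseline) the z-scored nuisance regressors.
session_design <- function(nodes, targets, trial_scaled, spec, config) {
  T <- length(nodes)
  X <- cbind(mu0 = rep(1, T), beta_trial = trial_scaled)
  tg <- matrix(0, T, spec$n_targets - 1L)
  colnames(tg) <- paste0("target", 2:spec$n_targets)
  for (k in 2:spec$n_targets) tg[targets == k, k - 1L] <- 1
  X <- cbind(X, tg)
  if (spec$code != 0L) {
    nu <- nuisance_regressors(nodes)
    zn <- nu$r_ntrials
    zl <- nu$r_lag10
    if (config$z_score_nuisance) {
      zn <- if (stats::sd(zn) > 0) (zn - mean(zn)) / stats::sd(zn) else zn * 0
      zl <- if (stats::sd(zl) > 0) (zl - mean(zl)) / stats::sd(zl) else zl * 0
    }
    X <- cbind(X, beta_ntrials = zn, beta_lag10 = zl)
  }
  X
}

# Assemble everything the likelihood needs for one subject-by-stage session.
prepare_session <- function(table, spec, config) {
  if (is.null(table$included)) table <- preprocess(table)
  stopifnot(length(unique(table$subject)) == 1L,
            length(unique(paste(table$graphset, table$stage))) == 1L)
  table <- table[order(table$trial), ]
  T <- nrow(table)
  if (T <= config$equilibrate)
    stop("session has ", T, " trials but the equilibration window is ",
         config$equilibrate)
  nodes <- as.integer(table$node)
  include <- table$included & seq_len(T) > config$equilibrate
  if (!any(include)) stop("no includable trials after equilibration")
  Xfixed <- session_design(nodes, as.integer(table$target),
                           table$trial_scaled, spec, config)
  Tstatic <- if (spec$static) {
    suppressWarnings(empirical_transition_matrix(nodes, n_nodes = config$n_nodes))
  } else empty_matrix()
  list(nodes = nodes, nodes0 = nodes - 1L, rt = as.numeric(table$rt_ms),
       include = include, Xfixed = Xfixed, Tstatic = Tstatic,
       rt_min = min(table$rt_ms[include]), n_nodes = config$n_nodes,
       subject = table$subject[1L], graphset = table$graphset[1L],
       stage = table$stage[1L], n_included = sum(include))
}

#' Negative log density of the shifted log-normal
#'
#' `log(rt - shift) ~ N(mu, sigma^2)`; the NLL of one observation is
#' `log(sigma) + log(2 pi)/2 + log(rt - shift) + (log(rt - shift) - mu)^2 /
#' (2 sigma^2)`. RTs at or below the shift get `+Inf` (optimizer-rejecting).
#'
#' @param rt reaction time(s) in ms.
#' @param mu mean on the log scale.
#' @param sigma SD on the log scale (> 0).
#' @param shift shift in ms.
#' @return Vector of negative log densities.
#' @export
shifted_lognormal_nll <- function(rt, mu, sigma, shift) {
  stopifnot(sigma > 0)
  out <- rep(Inf, length(rt))
  ok <- rt > shift
  y <- log(rt[ok] - shift)
  out[ok] <- log(sigma) + 0.5 * log(2 * pi) + y + (y - mu[ok])^2 / (2 * sigma^2)
  out
}

#' Per-trial predicted mean log RT for a model
#'
#' Runs the specified learner(s) forward over the full node sequence and
#' assembles `mu_t = mu0 + beta_trial t + target offsets + beta_A A_t +
#' beta_W W_t + beta_ntrials r_ntrials + beta_lag10 r_lag10` (terms present
#' as the model demands; the baseline model has no node-dependent terms).
#'
#' @param model model name (see [model_spec]).
#' @param nodes node sequence (1-based), or an [sr_walk].
#' @param params named list of natural-scale parameters (`mu0`,
#'   `beta_trial`, `target_offsets` vector of length `n_targets - 1`,
#'   `beta_A`, `beta_W`, `beta_ntrials`, `beta_lag10`, `alpha_A`, `alpha_W`,
#'   `gamma`, `lam` as applicable).
#' @param targets per-trial motor-target categories (1-based); defaults to
#'   the node identities.
#' @param config a [fit_config].
#' @return Numeric vector of per-trial mu values.
#' @export
mu_series <- function(model, nodes, params, targets = NULL,
                      config = fit_config()) {
  if (inherits(nodes, "sr_walk")) nodes <- nodes$nodes
  spec <- model_spec(model, n_targets = config$n_targets)
  targets <- targets %||% nodes
  T <- length(nodes)
  trial_scaled <- if (T == 1L) 0 else (seq_len(T) - 1) / (T - 1)
  X <- session_design(nodes, targets, trial_scaled, spec, config)
  b <- c(params$mu0, params$beta_trial,
         params$target_offsets %||% rep(0, spec$n_targets - 1L))
  if (spec$code != 0L) b <- c(b, params$beta_ntrials %||% 0,
                              params$beta_lag10 %||% 0)
  mu <- drop(X %*% b)
  if (spec$has_A || spec$has_W) {
    Tstatic <- if (spec$static) {
      suppressWarnings(empirical_transition_matrix(nodes,
                                                   n_nodes = config$n_nodes))
    } else empty_matrix()
    nl <- nl_values(spec, params)
    pred <- cpp_predictor_series(nodes - 1L, config$n_nodes, spec$code,
                                 nl$alpha_A, nl$alpha_W, nl$gamma, nl$lam,
                                 Tstatic)
    if (isTRUE(pred$diverged)) stop("learner diverged at these parameters")
    if (spec$has_A) mu <- mu + (params$beta_A %||% 0) * pred$A
    if (spec$has_W) mu <- mu + (params$beta_W %||% 0) * pred$W
  }
  mu
}

#' Sequence negative log likelihood for one session
#'
#' Advances the learner over all trials of a subject-by-stage session and
#' sums the shifted log-normal NLL over includable trials beyond the
#' equilibration window. The shift is `shift_frac` times the session's
#' minimum included RT.
#'
#' @param model model name.
#' @param table trial table for one subject and stage.
#' @param params named natural-scale parameter list; additionally
#'   `shift_frac` and `sigma`.
#' @param config a [fit_config].
#' @return Scalar NLL.
#' @export
sequence_nll <- function(model, table, params, config = fit_config()) {
  spec <- model_spec(model, n_targets = config$n_targets)
  ses <- prepare_session(table, spec, config)
  b <- c(params$mu0, params$beta_trial,
         params$target_offsets %||% rep(0, spec$n_targets - 1L))
  if (spec$code != 0L) b <- c(b, params$beta_ntrials %||% 0,
                              params$beta_lag10 %||% 0)
  nl <- nl_values(spec, params)
  cpp_seq_nll(ses$nodes0, ses$rt, ses$include, ses$Xfixed, spec$code,
              ses$n_nodes, b,
              params$beta_A %||% 0, params$beta_W %||% 0,
              nl$alpha_A, nl$alpha_W, nl$gamma, nl$lam,
              nl$shift_frac, params$sigma, ses$rt_min, ses$Tstatic)
}
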