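#' Specify a generative agent
#'
#' An agent is a learner plus the shifted log-normal RT parameters and the
#' contamination process. Defaults describe a plausible serial reaction
#' time performer: median RT around half a second over a 200 ms
#' non-decision floor, modest practice speed-up, facilitation from both
#' predictive components, discount and trace parameters in the range
#' typically estimated for such tasks, with rare errors and fast guesses.
#'
#' @param learner one of `"recency"`, `"onestep"`, `"sr_td"`,
#'   `"sr_static"`, `"hebbian"`, `"combined_sr_td"`, `"combined_onestep"`,
#'   `"combined_sr_static"`, `"combined_hebbian"`, `"baseline"`.
#' @param mu0 baseline mean log shifted RT (`exp(5.7)` is about 300 ms).
#' @param beta_trial slope on the rescaled (0..1) trial index.
#' @param target_offsets length-14 offsets for motor categories 2..15.
#' @param beta_A,beta_W weights of the higher-order and recency predictors
#'   (negative = expected nodes are answered faster).
#' @param beta_ntrials,beta_lag10 weights of the z-scored recency nuisance
#'   regressors.
#' @param alpha_A,alpha_W learning rates; `gamma` discount; `lam` trace
#'   parameter.
#' @param shift_ms absolute non-decision shift used when sampling.
#' @param sigma log-scale SD.
#' @param error_rate probability a trial is marked incorrect.
#' @param fastguess_rate probability a trial's RT is replaced by a uniform
#'   1..30 ms fast guess (kept marked correct).
#' @return An `agent_spec` list.
#' @export
agent_spec <- function(learner = "combined_sr_td",
                       mu0 = 5.7, beta_trial = -0.1,
                       target_offsets = seq(-0.09, 0.09, length.out = 14),
                       beta_A = -1.0, beta_W = -0.6,
                       beta_ntrials = 0.02, beta_lag10 = -0.02,
                       alpha_A = 0.1, alpha_W = 0.2,
                       gamma = 0.8, lam = 0.75,
                       shift_ms = 200, sigma = 0.25,
                       error_rate = 0.03, fastguess_rate = 0.005) {
  structure(list(learner = learner, mu0 = mu0, beta_trial = beta_trial,
                 target_offsets = target_offsets, beta_A = beta_A,
                 beta_W = beta_W, beta_ntrials = beta_ntrials,
                 beta_lag10 = beta_lag10, alpha_A = alpha_A,
                 alpha_W = alpha_W, gamma = gamma, lam = lam,
                 shift_ms = shift_ms, sigma = sigma,
                 error_rate = error_rate, fastguess_rate = fastguess_rate),
            class = "agent_spec")
}

#' Simulate one subject-by-stage session
#'
#' Walks the graph, advances the agent's learner, assembles the per-trial
#' mean per the agent's model equation and samples
#' `rt = shift + exp(N(mu_t, sigma^2))`. Incorrect trials and sub-30 ms
#' fast guesses are injected at the agent's rates; the motor-target map is
#' a seeded random bijection of nodes onto key-combination categories.
#'
#' @param agent an [agent_spec].
#' @param graph an [sr_graph].
#' @param n_trials trials in the session.
#' @param stage stage label (1 or 2).
#' @param seed integer seed; the session is bitwise-deterministic given it.
#' @param subject,graphset identifier labels.
#' @param config a [fit_config] (controls nuisance z-scoring in mu).
#' @return A trial table (`subject, graphset, stage, trial, node, target,
#'   rt_ms, correct`).
#' @export
simulate_subject <- function(agent, graph, n_trials = 1500L, stage = 1L,
                             seed = 1L, subject = "s01",
                             graphset = NULL, config = fit_config()) {
  stopifnot(inherits(agent, "agent_spec"))
  graphset <- graphset %||% paste0(graph$family, "_", stage)
  walk <- random_walk(graph, n_trials, derive_seed(seed, "walk"),
                      stage = stage)
  nodes <- walk$nodes
  target_map <- with_seed(derive_seed(seed, "targets"),
                          sample.int(graph$n_nodes))
  targets <- target_map[nodes]
  params <- unclass(agent)
  mu <- mu_series(agent$learner, nodes, params, targets = targets,
                  config = config)
  with_seed(derive_seed(seed, "noise"), {
    rt <- agent$shift_ms + exp(stats::rnorm(n_trials, mu, agent$sigma))
    correct <- stats::runif(n_trials) >= agent$error_rate
    fast <- stats::runif(n_trials) < agent$fastguess_rate
    rt[fast] <- stats::runif(sum(fast), 1, 30)
    correct[fast] <- TRUE
    data.frame(subject = subject, graphset = graphset,
               stage = as.integer(stage), trial = seq_len(n_trials),
               node = nodes, target = targets, rt_ms = rt,
               correct = correct)
  })
}

#' Specify a synthetic cohort
#'
#' Per-subject parameters are drawn on the unconstrained scale from a
#' Gaussian around the group means (stage differences applied through the
#' -1/+1 covariate), then pushed through the inverse transforms. Two-stage
#' designs counterbalance the graph-family order across subjects to within
#' one subject.
#'
#' @param n_subjects number of subjects.
#' @param graphs character vector of graph families for a subject's stages
#'   (length 1 or 2 from `"modular"`, `"lattice"`, `"random"`).
#' @param n_trials trials per stage.
#' @param agent an [agent_spec] holding the group-mean natural-scale
#'   parameters.
#' @param between_sd named numeric vector of between-subject SDs on the
#'   unconstrained scale; defaults: 0.5 for rates/discount/trace, 0.3 for
#'   `beta_A`/`beta_W`, 0.1 for the remaining location terms, 0 for target
#'   offsets.
#' @param stage_coef named numeric vector of stage-difference coefficients
#'   on the unconstrained scale (default none).
#' @param seed master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 40L, graphs = "modular",
                        n_trials = 1500L, agent = agent_spec(),
                        between_sd = NULL, stage_coef = NULL, seed = 1L) {
  structure(list(n_subjects = as.integer(n_subjects), graphs = graphs,
                 n_trials = as.integer(n_trials), agent = agent,
                 between_sd = between_sd, stage_coef = stage_coef,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Parameters that vary across subjects, with their default unconstrained
# between-subject SDs.
default_between_sd <- function() {
  c(mu0 = 0.1, beta_trial = 0.1, beta_A = 0.3, beta_W = 0.3,
    beta_ntrials = 0.05, beta_lag10 = 0.05, alpha_A = 0.5, alpha_W = 0.5,
    gamma = 0.5, lam = 0.5, sigma = 0.1)
}

#' Simulate a cohort with a truth record
#'
#' @param spec a [cohort_spec].
#' @return List with `trials` (stacked trial table), `truth` (per-subject
#'   natural- and unconstrained-scale parameters) and `group_truth`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  agent <- spec$agent
  sds <- default_between_sd()
  if (!is.null(spec$between_sd)) sds[names(spec$between_sd)] <- spec$between_sd
  varying <- names(sds)[sds > 0]
  mean_u <- to_unconstrained(setNames(
    vapply(names(sds), function(nm) agent[[nm]], 0), names(sds)))
  n_stages <- length(spec$graphs)
  stage_coef <- setNames(rep(0, length(sds)), names(sds))
  if (!is.null(spec$stage_coef))
    stage_coef[names(spec$stage_coef)] <- spec$stage_coef

  trials <- list()
  truth <- list()
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("s%03d", i)
    draw <- with_seed(derive_seed(spec$seed, paste0("params_", sid)),
                      mean_u + stats::rnorm(length(sds)) * sds)
    # counterbalanced graph order: odd subjects as given, even reversed
    fams <- if (n_stages == 2L && i %% 2L == 0L) rev(spec$graphs)
            else spec$graphs
    for (st in seq_len(n_stages)) {
      cvar <- if (n_stages == 2L) c(-1, 1)[st] else 0
      th_u <- draw + cvar * stage_coef
      th_nat <- from_unconstrained(th_u)
      ag <- agent
      for (nm in names(sds)) ag[[nm]] <- th_nat[[nm]]
      fam <- fams[st]
      g <- switch(fam,
                  modular = make_modular_graph(),
                  lattice = make_lattice_graph(),
                  random = make_random_graph(
                    derive_seed(spec$seed, paste0("graph_", sid, "_", st))),
                  stop("unknown graph family: ", fam))
      tb <- simulate_subject(ag, g, n_trials = spec$n_trials, stage = st,
                             seed = derive_seed(spec$seed,
                                                paste0("sess_", sid, "_", st)),
                             subject = sid,
                             graphset = paste0(fam, "_", st))
      trials[[length(trials) + 1L]] <- tb
      truth[[length(truth) + 1L]] <- data.frame(
        subject = sid, stage = st, graph = fam, covariate = cvar,
        parameter = names(sds), natural = unname(unlist(th_nat)),
        unconstrained = unname(th_u))
    }
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth),
       group_truth = list(mean_unconstrained = mean_u,
                          stage_coef = stage_coef,
                          mean_natural = from_unconstrained(mean_u),
                          between_sd = sds, varying = varying))
}

#' Truth-versus-estimate recovery report
#'
#' Joins a cohort truth record with an [em_fit] result and reports, per
#' parameter, the subject-level Pearson correlation, bias and RMSE of the
#' natural-scale MAP estimates, plus a group-level coverage flag (is the
#' true group mean inside the estimate's 95% interval across subjects).
#'
#' @param truth the `truth` data.frame from [simulate_cohort].
#' @param fit an `sr_em_fit` on the same cohort.
#' @param parameters which parameters to report (default: all shared).
#' @return A data.frame with one row per parameter.
#' @export
recovery_report <- function(truth, fit, parameters = NULL) {
  stopifnot(inherits(fit, "sr_em_fit"))
  est <- do.call(rbind, lapply(fit$fits, function(f) {
    data.frame(subject = f$subject, stage = f$stage,
               parameter = names(f$theta_natural),
               estimate = unname(f$theta_natural),
               estimate_u = unname(f$theta_map))
  }))
  shared <- intersect(unique(truth$parameter), unique(est$parameter))
  parameters <- parameters %||% shared
  parameters <- intersect(parameters, shared)
  merged <- merge(truth, est, by = c("subject", "stage", "parameter"))
  if (nrow(merged) == 0L) stop("no matching subject/stage/parameter rows")
  out <- lapply(parameters, function(p) {
    m <- merged[merged$parameter == p, ]
    r <- if (stats::sd(m$natural) > 0 && stats::sd(m$estimate) > 0)
      stats::cor(m$natural, m$estimate) else NA_real_
    n <- nrow(m)
    grp_est <- mean(m$estimate_u)
    grp_se <- stats::sd(m$estimate_u) / sqrt(n)
    grp_true <- mean(m$unconstrained)
    data.frame(parameter = p, n = n, r = r,
               bias = mean(m$estimate - m$natural),
               rmse = sqrt(mean((m$estimate - m$natural)^2)),
               group_true_u = grp_true, group_est_u = grp_est,
               covered = abs(grp_est - grp_true) <= 1.96 * grp_se)
  })
  do.call(rbind, out)
}
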