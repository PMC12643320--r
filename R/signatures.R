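#' Model-agnostic sequence-pattern signatures
#'
#' Trace and bootstrap learning rules leave distinct fingerprints on which
#' recent subsequences facilitate the current response:
#'
#' * **Trace signature** — 5-element windows `S,X,T,S,T` (all of `S,X,T`
#'   distinct). A trace learner strengthens the S->T expectancy during the
#'   initial `S,X,T`, so the final `S->T` response should be faster than in
#'   the recency-matched control `X1,X2,T,S,T` (where `S` was not recently
#'   visited before `T`; `X1`, `X2` just not in `{S, T}`, possibly equal).
#' * **Bootstrap signature** — 6-element windows `B,T,S,B,S,T` (`B,T,S`
#'   distinct). A bootstrapping learner chains the `B->T` expectancy to `S`
#'   through the `S->B` transition, facilitating the final `S->T`; the
#'   control `X,T,S,B,S,T` (`X` outside `{B,T,S}`) lacks the initial `B->T`
#'   boost.
#'
#' A test-template window is never also counted as control (the templates
#' are mutually exclusive on the first element). Matching runs over the raw
#' node sequence including likelihood-excluded trials; a match whose final
#' RT was excluded is dropped at analysis time.
#'
#' @param nodes integer node sequence (1-based).
#' @return A data.frame with columns `end_trial` (index of the final
#'   element) and `kind` (`*_test` / `*_control`).
#' @name pattern_finders
NULL

#' @rdname pattern_finders
#' @export
find_trace_patterns <- function(nodes) {
  T <- length(nodes)
  if (T < 5L) return(data.frame(end_trial = integer(0), kind = character(0)))
  w1 <- nodes[1:(T - 4)]; w2 <- nodes[2:(T - 3)]; w3 <- nodes[3:(T - 2)]
  w4 <- nodes[4:(T - 1)]; w5 <- nodes[5:T]
  # test S,X,T,S,T: w1==w4 (S), w3==w5 (T), S,X,T pairwise distinct
  is_test <- w1 == w4 & w3 == w5 & w1 != w2 & w1 != w3 & w2 != w3
  # control X1,X2,T,S,T: w3==w5 (T), S=w4 != T, X1,X2 not in {S,T}
  is_ctrl <- w3 == w5 & w4 != w3 &
    w1 != w4 & w1 != w3 & w2 != w4 & w2 != w3
  end <- seq_len(T - 4L) + 4L
  rbind(
    data.frame(end_trial = end[is_test],
               kind = rep("trace_test", sum(is_test))),
    data.frame(end_trial = end[is_ctrl],
               kind = rep("trace_control", sum(is_ctrl))))
}

#' @rdname pattern_finders
#' @export
find_bootstrap_patterns <- function(nodes) {
  T <- length(nodes)
  if (T < 6L) return(data.frame(end_trial = integer(0), kind = character(0)))
  w1 <- nodes[1:(T - 5)]; w2 <- nodes[2:(T - 4)]; w3 <- nodes[3:(T - 3)]
  w4 <- nodes[4:(T - 2)]; w5 <- nodes[5:(T - 1)]; w6 <- nodes[6:T]
  shared <- w2 == w6 & w3 == w5 &             # T and S repeats
    w4 != w2 & w4 != w3 & w2 != w3            # B,T,S pairwise distinct
  is_test <- shared & w1 == w4                # B,T,S,B,S,T
  is_ctrl <- shared & w1 != w4 & w1 != w2 & w1 != w3  # X,T,S,B,S,T
  end <- seq_len(T - 5L) + 5L
  rbind(
    data.frame(end_trial = end[is_test],
               kind = rep("bootstrap_test", sum(is_test))),
    data.frame(end_trial = end[is_ctrl],
               kind = rep("bootstrap_control", sum(is_ctrl))))
}

#' Collect pattern matches with RTs across a trial table
#'
#' Runs a pattern finder within every subject-by-graphset-by-stage sequence
#' and attaches the RT, motor target and inclusion flag of each match's
#' final element.
#'
#' @param table trial table (preprocessed or raw).
#' @param contrast `"trace"` or `"bootstrap"`.
#' @param drop_excluded drop matches whose final-element RT is excluded
#'   from likelihood (default `TRUE`).
#' @return A data.frame of `PatternMatch` rows: `subject, graphset, stage,
#'   end_trial, kind, rt_ms, target, is_test`.
#' @export
find_patterns <- function(table, contrast = c("trace", "bootstrap"),
                          drop_excluded = TRUE) {
  contrast <- match.arg(contrast)
  if (is.null(table$included)) table <- preprocess(table)
  finder <- if (contrast == "trace") find_trace_patterns
            else find_bootstrap_patterns
  out <- lapply(split_sessions(table), function(tb) {
    tb <- tb[order(tb$trial), ]
    m <- finder(as.integer(tb$node))
    if (nrow(m) == 0L) return(NULL)
    data.frame(subject = tb$subject[1L], graphset = tb$graphset[1L],
               stage = tb$stage[1L], end_trial = m$end_trial, kind = m$kind,
               rt_ms = tb$rt_ms[m$end_trial], target = tb$target[m$end_trial],
               included = tb$included[m$end_trial])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  if (drop_excluded) out <- out[out$included, ]
  out$is_test <- as.integer(grepl("_test$", out$kind))
  out
}

#' Mixed-effects contrast of test versus control pattern RTs
#'
#' Fits `rt ~ is_test + target + (1 + is_test | graphset) +
#' (1 + is_test | subject)` on the matched-pattern RTs (ms scale) and
#' returns the `is_test` fixed effect: a negative estimate means the test
#' pattern's final response is faster (facilitation). If the random-slopes
#' fit is singular or fails, falls back to random intercepts only
#' (flagged).
#'
#' @param matches data.frame from [find_patterns].
#' @param contrast `"trace"` or `"bootstrap"` (label only).
#' @return A `ContrastResult` list: `effect_estimate` (ms), `se`, `z`, `p`,
#'   `n_obs`, `fallback`.
#' @export
signature_contrast <- function(matches, contrast = c("trace", "bootstrap")) {
  contrast <- match.arg(contrast)
  stopifnot(nrow(matches) > 0)
  if (length(unique(matches$subject)) < 2L)
    stop("need matches from at least 2 subjects")
  matches$target <- factor(matches$target)
  # random-effects groupings need > 1 level; single-graphset data (e.g. one
  # simulated condition) drops that term rather than failing
  groups <- c("graphset", "subject")
  groups <- groups[vapply(groups, function(g)
    length(unique(matches[[g]])) > 1L, TRUE)]
  form <- function(slopes) {
    re <- paste(sprintf("(1 %s| %s)", if (slopes) "+ is_test " else "",
                        groups), collapse = " + ")
    stats::as.formula(paste("rt_ms ~ is_test + target +", re))
  }
  if (!length(groups)) stop("no grouping factor with > 1 level")
  fallback <- FALSE
  fit <- tryCatch({
    f <- lme4::lmer(form(TRUE), data = matches, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore", calc.derivs = FALSE))
    if (lme4::isSingular(f, tol = 1e-4)) { fallback <- TRUE; NULL } else f
  }, error = function(e) { fallback <<- TRUE; NULL })
  if (is.null(fit)) {
    fit <- lme4::lmer(form(FALSE), data = matches, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        calc.derivs = FALSE))
  }
  co <- summary(fit)$coefficients
  est <- co["is_test", "Estimate"]
  se <- co["is_test", "Std. Error"]
  z <- est / se
  structure(list(contrast = contrast, effect_estimate = est, se = se,
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 n_obs = nrow(matches), fallback = fallback),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast> %s: effect %.2f (SE %.2f), z = %.2f, p = %.3g, n = %d%s\n",
              x$contrast, x$effect_estimate, x$se, x$z, x$p, x$n_obs,
              if (isTRUE(x$fallback)) " [random intercepts only]" else ""))
  invisible(x)
}

#' Residual log RTs after trial and motor-response effects
#'
#' Fits the baseline observation model (intercept, trial slope, motor-target
#' offsets, shift, sigma — no prediction of upcoming nodes) to one session
#' by MAP and returns observed-minus-predicted log shifted RTs for the
#' included trials (NA elsewhere).
#'
#' @param table trial table for one subject and stage.
#' @param config a [fit_config].
#' @return Numeric vector of residuals, one per trial row.
#' @export
residualize_rts <- function(table, config = fit_config()) {
  fit <- subject_map_fit("baseline", table, config = config,
                         n_restarts = 1L, compute_hessian = FALSE)
  spec <- model_spec("baseline", n_targets = config$n_targets)
  ses <- prepare_session(table, spec, config)
  nat <- fit$theta_natural
  b <- unname(nat[setdiff(spec$linear, c("beta_A", "beta_W"))])
  mu <- drop(ses$Xfixed %*% b)
  shift <- nat[["shift_frac"]] * ses$rt_min
  res <- rep(NA_real_, length(ses$rt))
  res[ses$include] <- log(ses$rt[ses$include] - shift) - mu[ses$include]
  res
}

#' First- versus second-entry RT contrast on the modular graph
#'
#' The converged SR predicts the first node after a cross-cluster
#' transition poorly but is already biased toward the new cluster by the
#' second node, so the second entry should be faster — a prediction a pure
#' recency learner does not share. Residual log RTs (trial and motor
#' effects removed) on first/second-entry trials are modeled as
#' `resid ~ time_since_node + cluster_step + (1 + cluster_step | subject)`
#' with `cluster_step` 0 for the first and 1 for the second entry and
#' `time_since_node` (trials since the current node last occurred, capped
#' at 100) entering as an effects-coded categorical recency control.
#'
#' @param tables multi-subject trial table or list of session tables (walks
#'   on the modular graph).
#' @param graph the modular [sr_graph] (needs `cluster_of`).
#' @param config a [fit_config].
#' @param max_lag recency cap in trials (default 100).
#' @return A `ContrastResult` for the `cluster_step` effect (negative =
#'   second entry faster).
#' @export
cluster_entry_analysis <- function(tables, graph, config = fit_config(),
                                   max_lag = 100L) {
  stopifnot(inherits(graph, "sr_graph"), !is.null(graph$cluster_of))
  cl <- graph$cluster_of
  rows <- lapply(split_sessions(tables), function(tb) {
    tb <- tb[order(tb$trial), ]
    nodes <- as.integer(tb$node)
    res <- residualize_rts(tb, config)
    nu <- nuisance_regressors(nodes)
    Tn <- length(nodes)
    cross <- c(FALSE, cl[nodes[-1L]] != cl[nodes[-Tn]])
    first_entry <- which(cross)
    second_entry <- first_entry + 1L
    keep2 <- second_entry <= Tn & !cross[pmin(second_entry, Tn)]
    idx <- c(first_entry, second_entry[keep2])
    step <- c(rep(0L, length(first_entry)), rep(1L, sum(keep2)))
    ok <- !is.na(res[idx])
    if (!any(ok)) return(NULL)
    data.frame(subject = tb$subject[1L],
               resid = res[idx[ok]], cluster_step = step[ok],
               lag = pmin(nu$r_ntrials[idx[ok]], max_lag))
  })
  dat <- do.call(rbind, rows)
  if (is.null(dat) || !any(dat$cluster_step == 1L))
    stop("no cross-cluster entry events found")
  dat$lag <- factor(dat$lag)
  stats::contrasts(dat$lag) <- stats::contr.sum(nlevels(dat$lag))
  fallback <- FALSE
  fit <- tryCatch({
    f <- lme4::lmer(resid ~ lag + cluster_step + (1 + cluster_step | subject),
                    data = dat, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore", calc.derivs = FALSE))
    if (lme4::isSingular(f, tol = 1e-4)) { fallback <- TRUE; NULL } else f
  }, error = function(e) { fallback <<- TRUE; NULL })
  if (is.null(fit)) {
    fit <- lme4::lmer(resid ~ lag + cluster_step + (1 | subject),
                      data = dat, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore", calc.derivs = FALSE))
  }
  co <- summary(fit)$coefficients
  est <- co["cluster_step", "Estimate"]
  se <- co["cluster_step", "Std. Error"]
  z <- est / se
  structure(list(contrast = "cluster_step", effect_estimate = est, se = se,
                 z = z, p = 2 * stats::pnorm(-abs(z)), n_obs = nrow(dat),
                 fallback = fallback),
            class = "contrast_result")
}
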