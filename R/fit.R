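#' Group-level model for hierarchical fitting
#'
#' Subject-level parameters (on the unconstrained scale) are modeled as
#' Gaussian around a group mean, optionally offset by stage-difference
#' coefficients through a covariate coded -1 for the first task stage and
#' +1 for the second. The group-level covariance is fixed at the identity
#' and never updated.
#'
#' @param group_mean named numeric vector of unconstrained group means.
#' @param stage_coef named numeric vector of stage-difference coefficients
#'   (defaults to zeros).
#' @return A `group_model` list.
#' @export
group_model <- function(group_mean, stage_coef = NULL) {
  if (is.null(stage_coef)) stage_coef <- setNames(rep(0, length(group_mean)),
                                                  names(group_mean))
  stopifnot(identical(names(group_mean), names(stage_coef)))
  structure(list(group_mean = group_mean, stage_coef = stage_coef),
            class = "group_model")
}

# Data-driven default prior: centers the baseline log-RT terms on sample
# moments and the bounded learner parameters on mid-range values.
default_prior <- function(spec, sessions) {
  m <- setNames(rep(0, length(spec$names)), spec$names)
  mu0s <- vapply(sessions, function(s) {
    shift <- 0.5 * s$rt_min
    mean(log(s$rt[s$include] - shift))
  }, 0)
  sds <- vapply(sessions, function(s) {
    shift <- 0.5 * s$rt_min
    stats::sd(log(s$rt[s$include] - shift))
  }, 0)
  m["mu0"] <- mean(mu0s)
  m["sigma"] <- log(max(mean(sds), 1e-2))
  for (nm in intersect(c("alpha_A", "alpha_W"), names(m))) m[nm] <- logit(0.1)
  if ("gamma" %in% names(m)) m["gamma"] <- logit(0.8)
  if ("lam" %in% names(m)) m["lam"] <- logit(0.5)
  if ("shift_frac" %in% names(m)) m["shift_frac"] <- 0
  group_model(m)
}

# Profiled MAP objective over the free nonlinear coordinates (unconstrained
# scale) for one prepared session; returns the closure plus an extractor for
# the profiled linear block.
make_profile_objective <- function(spec, ses, m_full) {
  m_b <- unname(m_full[spec$linear])
  m_ls <- unname(m_full["sigma"])
  m_nl <- unname(m_full[spec$nl_free])
  profile_raw <- function(th_nl_u) {
    nat <- as.list(from_unconstrained(setNames(th_nl_u, spec$nl_free)))
    nlv <- nl_values(spec, nat)
    cpp_profile_map(ses$nodes0, ses$rt, ses$include, ses$Xfixed, spec$code,
                    ses$n_nodes, nlv$shift_frac, nlv$alpha_A, nlv$alpha_W,
                    nlv$gamma, nlv$lam, m_b, m_ls, ses$rt_min, ses$Tstatic)
  }
  fn <- function(th_nl_u) {
    r <- profile_raw(th_nl_u)
    if (!is.finite(r$obj)) return(1e10)
    r$obj + 0.5 * sum((th_nl_u - m_nl)^2)
  }
  list(fn = fn, raw = profile_raw, m_nl = m_nl)
}

# Full negative log posterior (likelihood + identity Gaussian prior,
# including the prior normalizing constant) over the complete unconstrained
# parameter vector of one session. Used for the Laplace Hessian.
make_negpost <- function(spec, ses, m_full) {
  d <- length(spec$names)
  const <- 0.5 * d * log(2 * pi)
  bnames <- setdiff(spec$linear, c("beta_A", "beta_W"))
  function(th) {
    th <- setNames(th, spec$names)
    nat <- as.list(from_unconstrained(th))
    nlv <- nl_values(spec, nat)
    b <- unname(unlist(nat[bnames]))
    nll <- cpp_seq_nll(ses$nodes0, ses$rt, ses$include, ses$Xfixed,
                       spec$code, ses$n_nodes, b,
                       nat$beta_A %||% 0, nat$beta_W %||% 0,
                       nlv$alpha_A, nlv$alpha_W, nlv$gamma, nlv$lam,
                       nlv$shift_frac, nat$sigma, ses$rt_min, ses$Tstatic)
    if (!is.finite(nll)) return(1e10)
    nll + 0.5 * sum((th - m_full)^2) + const
  }
}

# Analytic gradient of the negative log posterior for the coordinates with
# closed forms (linear coefficients, log sigma, logit shift fraction);
# checked against finite differences in the tests.
negpost_grad_closed <- function(spec, ses, m_full, theta) {
  theta <- setNames(theta, spec$names)
  nat <- as.list(from_unconstrained(theta))
  nlv <- nl_values(spec, nat)
  pred <- cpp_predictor_series(ses$nodes0, ses$n_nodes, spec$code,
                               nlv$alpha_A, nlv$alpha_W, nlv$gamma, nlv$lam,
                               ses$Tstatic)
  X <- ses$Xfixed
  if (spec$has_A) X <- cbind(X, pred$A)
  if (spec$has_W) X <- cbind(X, pred$W)
  inc <- ses$include
  b <- unname(theta[spec$linear])
  sigma <- nat$sigma
  shift <- nlv$shift_frac * ses$rt_min
  r <- ses$rt[inc] - shift
  y <- log(r)
  mu <- drop(X[inc, , drop = FALSE] %*% b)
  z <- y - mu
  g_b <- -drop(crossprod(X[inc, , drop = FALSE], z)) / sigma^2 +
    (b - unname(m_full[spec$linear]))
  g_ls <- sum(1 - z^2 / sigma^2) + (theta[["sigma"]] - m_full[["sigma"]])
  out <- c(setNames(g_b, spec$linear), sigma = unname(g_ls))
  if ("shift_frac" %in% spec$nl_free) {
    dshift_du <- ses$rt_min * nlv$shift_frac * (1 - nlv$shift_frac)
    g_sh <- sum(-(1 + z / sigma^2) / r) * dshift_du +
      (theta[["shift_frac"]] - m_full[["shift_frac"]])
    out["shift_frac"] <- unname(g_sh)
  }
  out
}

numeric_hessian <- function(f, x, h = 1e-3) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
  }
  if (d > 1L) {
    for (i in seq_len(d - 1L)) {
      for (j in (i + 1L):d) {
        ei <- replace(numeric(d), i, h)
        ej <- replace(numeric(d), j, h)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h^2)
      }
    }
  }
  H
}

#' MAP fit of one subject-by-stage session
#'
#' Minimizes `sequence_nll(theta) + 0.5 ||theta - (mean + c * stage_coef)||^2`
#' over the unconstrained parameter vector. The linear coefficients and
#' `log(sigma)` are profiled out in closed form (ridge / 1-d Newton), so the
#' optimizer searches only the nonlinear learner coordinates, multi-start
#' Nelder-Mead with jittered starts derived from `seed`.
#'
#' @param model model name (see [model_spec]).
#' @param table preprocessed trial table for one subject and stage.
#' @param prior a [group_model]; a data-driven default is built if `NULL`.
#' @param stage_covariate -1 / +1 stage code (0 for single-stage designs).
#' @param n_restarts number of optimizer starts.
#' @param seed integer seed for start jitter.
#' @param config a [fit_config].
#' @param fixed named list of learner parameters clamped at fixed values.
#' @param init optional named unconstrained vector of nonlinear coordinates
#'   used as an additional (warm) start.
#' @param compute_hessian compute the Laplace Hessian and NLML (skippable
#'   inside EM iterations, where only the MAP is needed).
#' @return A `subject_fit` list: `theta_map` (unconstrained, named),
#'   `theta_natural`, `hessian`, `neg_log_post`, `nll`, `nlml`, `converged`.
#' @export
subject_map_fit <- function(model, table, prior = NULL, stage_covariate = 0,
                            n_restarts = 3L, seed = 1L,
                            config = fit_config(), fixed = list(),
                            init = NULL, compute_hessian = TRUE) {
  spec <- model_spec(model, fixed = fixed, n_targets = config$n_targets)
  ses <- prepare_session(table, spec, config)
  if (is.null(prior)) prior <- default_prior(spec, list(ses))
  m_full <- prior$group_mean + stage_covariate * prior$stage_coef
  stopifnot(identical(names(m_full), spec$names))
  obj <- make_profile_objective(spec, ses, m_full)
  k <- length(spec$nl_free)

  starts <- list(obj$m_nl)
  if (!is.null(init)) starts <- c(starts, list(unname(init[spec$nl_free])))
  if (n_restarts > length(starts)) {
    jit <- with_seed(seed, lapply(seq_len(n_restarts - length(starts)),
                                  function(i) obj$m_nl + stats::rnorm(k)))
    starts <- c(starts, jit)
  }

  best <- NULL
  opt_ok <- FALSE
  if (k == 0L) {
    best <- list(par = numeric(0), value = obj$fn(numeric(0)))
    opt_ok <- TRUE
  } else {
    for (st in starts) {
      o <- if (k == 1L) {
        stats::optim(st, obj$fn, method = "Brent", lower = -12, upper = 12)
      } else {
        stats::optim(st, obj$fn, method = "Nelder-Mead",
                     control = list(maxit = config$nm_maxit %||% 600L,
                                    reltol = config$nm_reltol %||% 1e-9))
      }
      if (is.null(best) || o$value < best$value) {
        best <- o
        opt_ok <- o$convergence == 0L
      }
    }
  }

  raw <- obj$raw(best$par)
  theta_map <- setNames(numeric(length(spec$names)), spec$names)
  theta_map[spec$linear] <- as.numeric(raw$b)
  theta_map["sigma"] <- raw$logsigma
  if (k > 0L) theta_map[spec$nl_free] <- best$par

  negpost <- make_negpost(spec, ses, m_full)
  d <- length(theta_map)
  nlp <- negpost(theta_map)
  nat <- from_unconstrained(theta_map)
  nll <- nlp - 0.5 * sum((theta_map - m_full)^2) - 0.5 * d * log(2 * pi)

  H <- NULL
  nlml <- NA_real_
  pd <- NA
  if (compute_hessian) {
    H <- numeric_hessian(negpost, theta_map)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    pd <- all(ev > 0)
    if (pd) {
      nlml <- nlp - 0.5 * d * log(2 * pi) +
        0.5 * as.numeric(determinant(H, logarithm = TRUE)$modulus)
    }
  }

  structure(list(model = model, subject = ses$subject,
                 graphset = ses$graphset, stage = ses$stage,
                 stage_covariate = stage_covariate,
                 theta_map = theta_map, theta_natural = nat,
                 hessian = H, neg_log_post = nlp, nll = nll, nlml = nlml,
                 n_obs = ses$n_included, dim = d,
                 converged = opt_ok && (is.na(pd) || isTRUE(pd)),
                 prior_mean = m_full),
            class = "subject_fit")
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf("<subject_fit> %s: subject %s stage %d, NLL %.2f, NLML %.2f, %s\n",
              x$model, x$subject, x$stage, x$nll, x$nlml,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Laplace-approximated negative log marginal likelihood
#'
#' `NLML = negLogPost(theta_map) - (dim/2) log(2 pi) + 0.5 log det(H)`,
#' where `negLogPost` is the negative log of likelihood times prior density
#' at the MAP and `H` its Hessian there. With `dim = 0` (no free
#' parameters) this degenerates to the plain NLL.
#'
#' @param fit a `subject_fit` with a Hessian.
#' @param dim number of free parameters (defaults to the fit's dimension).
#' @return Scalar approximate NLML.
#' @export
laplace_nlml <- function(fit, dim = fit$dim) {
  if (dim == 0L) return(fit$nll)
  if (is.null(fit$hessian)) stop("fit has no Hessian")
  ev <- eigen(fit$hessian, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Hessian is not positive definite")
  fit$neg_log_post - 0.5 * dim * log(2 * pi) +
    0.5 * as.numeric(determinant(fit$hessian, logarithm = TRUE)$modulus)
}

# Split a multi-subject trial table into per-session tables.
split_sessions <- function(tables) {
  if (is.data.frame(tables)) {
    key <- interaction(tables$subject, tables$graphset, tables$stage,
                       drop = TRUE)
    tables <- split(tables, key)
  }
  tables
}

#' Hierarchical EM fit over sessions
#'
#' Alternates MAP fits of every session under the current group prior
#' (E-step) with a regression of the per-session MAP estimates on the stage
#' covariate to update the group mean and stage coefficients (M-step); the
#' group covariance stays the identity. Stops when the largest group-mean
#' change drops below `config$em_tol` or after `config$max_em_iter`
#' iterations. Laplace Hessians and NLMLs are computed at the final
#' iterate.
#'
#' @param model model name.
#' @param tables a multi-subject trial table, or a list of per-session
#'   tables (>= 2 sessions).
#' @param config a [fit_config].
#' @param seed master seed; per-session optimizer seeds are derived from
#'   it.
#' @param fixed named list of clamped learner parameters.
#' @param compute_nlml_trace also compute NLMLs at every EM iteration
#'   (costly; used to monitor the EM objective).
#' @param final_hessians compute Laplace Hessians and NLMLs at the final
#'   iterate (needed for model comparison; skippable for pure parameter
#'   recovery).
#' @return An `sr_em_fit`: group mean and stage coefficients, per-session
#'   `subject_fit`s, iteration trace.
#' @export
em_fit <- function(model, tables, config = fit_config(), seed = 1L,
                   fixed = list(), compute_nlml_trace = FALSE,
                   final_hessians = TRUE) {
  tables <- split_sessions(tables)
  if (length(tables) < 2L) stop("em_fit needs at least 2 sessions")
  spec <- model_spec(model, fixed = fixed, n_targets = config$n_targets)
  sessions_meta <- lapply(tables, function(tb) {
    if (is.null(tb$included)) tb <- preprocess(tb)
    tb
  })
  stages <- vapply(sessions_meta, function(tb) as.integer(tb$stage[1L]), 0L)
  covar <- if (length(unique(stages)) > 1L) ifelse(stages == 1L, -1, 1)
           else rep(0, length(stages))
  estimate_stage <- length(unique(covar)) > 1L

  prep <- lapply(sessions_meta, function(tb) prepare_session(tb, spec, config))
  prior <- default_prior(spec, prep)
  d <- length(spec$names)

  fits <- vector("list", length(tables))
  trace <- list()
  warm <- vector("list", length(tables))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_em_iter)) {
    nrs <- if (iter == 1L) config$n_restarts else 1L
    for (i in seq_along(tables)) {
      fits[[i]] <- subject_map_fit(
        model, sessions_meta[[i]], prior = prior,
        stage_covariate = covar[i], n_restarts = nrs,
        seed = derive_seed(seed, paste0("map_", names(tables)[i] %||% i,
                                        "_it", iter)),
        config = config, fixed = fixed, init = warm[[i]],
        compute_hessian = FALSE)
      warm[[i]] <- fits[[i]]$theta_map
    }
    Theta <- do.call(rbind, lapply(fits, `[[`, "theta_map"))
    old_mean <- prior$group_mean
    if (estimate_stage) {
      Xg <- cbind(1, covar)
      coefs <- qr.solve(Xg, Theta)
      new_mean <- setNames(coefs[1L, ], spec$names)
      new_stage <- setNames(coefs[2L, ], spec$names)
    } else {
      new_mean <- setNames(colMeans(Theta), spec$names)
      new_stage <- setNames(rep(0, d), spec$names)
    }
    prior <- group_model(new_mean, new_stage)
    delta <- max(abs(new_mean - old_mean))
    step <- list(iter = iter, delta = delta)
    if (compute_nlml_trace) {
      nlmls <- vapply(seq_along(tables), function(i) {
        f <- subject_map_fit(model, sessions_meta[[i]], prior = prior,
                             stage_covariate = covar[i], n_restarts = 1L,
                             seed = derive_seed(seed, paste0("tr_", i, "_", iter)),
                             config = config, fixed = fixed,
                             init = warm[[i]], compute_hessian = TRUE)
        f$nlml
      }, 0)
      step$total_nlml <- sum(nlmls)
    }
    trace[[iter]] <- step
    if (delta < config$em_tol) { converged <- TRUE; break }
  }

  # final pass: multi-start refit under the final prior (the nonlinear
  # learner coordinates have local optima, so warm single-start E-step fits
  # are polished with jittered restarts), plus Hessians/NLMLs if requested
  for (i in seq_along(tables)) {
    fits[[i]] <- subject_map_fit(
      model, sessions_meta[[i]], prior = prior, stage_covariate = covar[i],
      n_restarts = max(3L, config$n_restarts),
      seed = derive_seed(seed, paste0("final_", names(tables)[i] %||% i)),
      config = config, fixed = fixed, init = warm[[i]],
      compute_hessian = final_hessians)
    if (!fits[[i]]$converged && config$extra_restarts > 0L) {
      refit <- subject_map_fit(
        model, sessions_meta[[i]], prior = prior, stage_covariate = covar[i],
        n_restarts = config$extra_restarts,
        seed = derive_seed(seed, paste0("rescue_", i)),
        config = config, fixed = fixed, init = fits[[i]]$theta_map,
        compute_hessian = TRUE)
      if (refit$converged || refit$neg_log_post < fits[[i]]$neg_log_post)
        fits[[i]] <- refit
    }
  }

  n_group <- d * (1L + as.integer(estimate_stage))
  structure(list(model = model, spec = spec, group_mean = prior$group_mean,
                 stage_coef = prior$stage_coef, fits = fits,
                 covariates = covar, n_iter = iter, converged = converged,
                 n_group_params = n_group, trace = trace, seed = seed),
            class = "sr_em_fit")
}

#' @export
print.sr_em_fit <- function(x, ...) {
  cat(sprintf("<sr_em_fit> %s: %d sessions, %d EM iterations (%s)\n",
              x$model, length(x$fits), x$n_iter,
              if (x$converged) "converged" else "max iterations"))
  nat <- from_unconstrained(x$group_mean)
  cat("  group means (natural scale):\n")
  show <- intersect(c("mu0", "sigma", "beta_A", "beta_W", "alpha_A",
                      "alpha_W", "gamma", "lam", "shift_frac"), names(nat))
  print(round(nat[show], 4))
  invisible(x)
}

#' Per-session model comparison scores
#'
#' Each session's score is its Laplace NLML plus an equal share of an AIC
#' penalty of one NLL unit per group-level parameter. Lower is better.
#'
#' @param fits an `sr_em_fit`, or a list of `subject_fit`s.
#' @param n_group_params number of group-level parameters (taken from the
#'   `sr_em_fit` if not given).
#' @return A `model_score`: scores vector (one per session), model id.
#' @export
model_score <- function(fits, n_group_params = NULL) {
  if (inherits(fits, "sr_em_fit")) {
    n_group_params <- n_group_params %||% fits$n_group_params
    model_id <- fits$model
    fits <- fits$fits
  } else {
    model_id <- fits[[1L]]$model
    n_group_params <- n_group_params %||% 0L
  }
  n <- length(fits)
  scores <- vapply(fits, `[[`, 0, "nlml") + n_group_params / n
  names(scores) <- vapply(fits, function(f)
    paste(f$subject, f$graphset, f$stage, sep = "_"), "")
  ok <- vapply(fits, `[[`, TRUE, "converged")
  structure(list(scores = scores, model_id = model_id,
                 n_group_params = n_group_params, converged = ok),
            class = "model_score")
}

#' Paired comparison of two models' scores
#'
#' One-sided paired t-test on per-session score differences
#' `scores_a - scores_b` (positive differences mean model `b` fits better,
#' since scores are penalized NLMLs). Sessions non-converged under either
#' model are dropped pairwise.
#'
#' @param scores_a,scores_b `model_score` objects (or bare numeric vectors)
#'   for the same sessions; `a` is the reference.
#' @return List with `t`, `p` (one-sided, improvement of b over a),
#'   `mean_diff`, `ci95`, `df`, `n`.
#' @export
compare_models <- function(scores_a, scores_b) {
  keep <- TRUE
  if (inherits(scores_a, "model_score") && inherits(scores_b, "model_score"))
    keep <- scores_a$converged & scores_b$converged
  a <- if (inherits(scores_a, "model_score")) scores_a$scores else scores_a
  b <- if (inherits(scores_b, "model_score")) scores_b$scores else scores_b
  stopifnot(length(a) == length(b))
  d <- (a - b)[keep]
  n <- length(d)
  if (n < 3L) stop("need at least 3 paired sessions")
  md <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  tval <- if (se == 0) { if (md == 0) 0 else sign(md) * Inf } else md / se
  p <- stats::pt(tval, df = n - 1L, lower.tail = FALSE)
  ci <- md + c(-1, 1) * stats::qt(0.975, n - 1L) * se
  list(t = tval, p = p, mean_diff = md, ci95 = ci, df = n - 1L, n = n)
}
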