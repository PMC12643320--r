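sim_session <- function(seed = 1, n_trials = 600, agent = clean_agent(),
                        subject = "s1") {
  simulate_subject(agent, make_modular_graph(), n_trials = n_trials,
                   seed = seed, subject = subject)
}

test_that("parameter transforms round-trip on both scales", {
  set.seed(1)
  for (i in 1:20) {
    x <- c(mu0 = rnorm(1), beta_A = rnorm(1), sigma = runif(1, 0.05, 2),
           alpha_A = runif(1), gamma = runif(1), lam = runif(1),
           shift_frac = runif(1))
    u <- to_unconstrained(x)
    expect_equal(from_unconstrained(u), x, tolerance = 1e-10)
    expect_equal(to_unconstrained(from_unconstrained(u)), u,
                 tolerance = 1e-10)
  }
})

test_that("closed-form posterior gradient matches finite differences", {
  tb <- sim_session(seed = 3, n_trials = 400)
  cfg <- quick_config()
  spec <- model_spec("sr_td")
  ses <- srtraces:::prepare_session(preprocess(tb), spec, cfg)
  prior <- srtraces:::default_prior(spec, list(ses))
  m <- prior$group_mean
  negpost <- srtraces:::make_negpost(spec, ses, m)
  set.seed(7)
  for (rep in 1:5) {
    th <- m + rnorm(length(m), sd = 0.1)
    names(th) <- spec$names
    ga <- srtraces:::negpost_grad_closed(spec, ses, m, th)
    h <- 1e-5
    for (nm in names(ga)) {
      ei <- setNames(numeric(length(th)), names(th))
      ei[nm] <- h
      gn <- (negpost(th + ei) - negpost(th - ei)) / (2 * h)
      expect_equal(unname(ga[[nm]]), gn,
                   tolerance = 1e-4 * max(1, abs(gn)),
                   label = paste("grad", nm, "rep", rep))
    }
  }
})

test_that("profiled MAP is a stationary point of the full posterior", {
  tb <- sim_session(seed = 5, n_trials = 500)
  cfg <- quick_config()
  fit <- subject_map_fit("recency", tb, config = cfg, n_restarts = 2,
                         seed = 1, compute_hessian = FALSE)
  spec <- model_spec("recency")
  ses <- srtraces:::prepare_session(preprocess(tb), spec, cfg)
  negpost <- srtraces:::make_negpost(spec, ses, fit$prior_mean)
  th <- fit$theta_map
  h <- 1e-4
  grads <- vapply(seq_along(th), function(i) {
    ei <- replace(numeric(length(th)), i, h)
    (negpost(th + ei) - negpost(th - ei)) / (2 * h)
  }, 0)
  expect_lt(max(abs(grads)), 0.05)
})

test_that("MAP shrinks toward the prior mean for small data", {
  tb <- sim_session(seed = 11, n_trials = 160)
  cfg <- quick_config(equilibrate = 20L)
  spec <- model_spec("baseline")
  ses <- srtraces:::prepare_session(preprocess(tb), spec, cfg)
  prior <- srtraces:::default_prior(spec, list(ses))
  far <- prior
  far$group_mean["mu0"] <- prior$group_mean["mu0"] + 2
  fit_near <- subject_map_fit("baseline", tb, prior = prior, config = cfg,
                              n_restarts = 1, compute_hessian = FALSE)
  fit_far <- subject_map_fit("baseline", tb, prior = far, config = cfg,
                             n_restarts = 1, compute_hessian = FALSE)
  # moving the prior up pulls the MAP up, and the far MAP sits between the
  # near-prior MAP and the far prior mean
  expect_gt(fit_far$theta_map["mu0"], fit_near$theta_map["mu0"])
  expect_lt(fit_far$theta_map["mu0"], far$group_mean["mu0"])
})

test_that("Laplace NLML matches the exact conjugate Gaussian marginal", {
  # y_i ~ N(theta, s2) with prior theta ~ N(m, 1): exact marginal available
  set.seed(2)
  y <- rnorm(20, 1.4, 0.7)
  s2 <- 0.49
  m <- 0.5
  n <- length(y)
  post_prec <- n / s2 + 1
  theta_map <- (sum(y) / s2 + m) / post_prec
  nll <- function(th) sum((y - th)^2) / (2 * s2) + n / 2 * log(2 * pi * s2)
  nlp <- nll(theta_map) + 0.5 * (theta_map - m)^2 + 0.5 * log(2 * pi)
  fake <- structure(list(neg_log_post = nlp,
                         hessian = matrix(post_prec, 1, 1),
                         nll = nll(theta_map), dim = 1L),
                    class = "subject_fit")
  got <- laplace_nlml(fake)
  # exact marginal via the joint Gaussian: y = theta + eps, theta shared
  Sigma <- matrix(1, n, n) + diag(s2, n)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  quad <- drop(t(y - m) %*% solve(Sigma, y - m))
  exact <- 0.5 * (n * log(2 * pi) + as.numeric(ld) + quad)
  expect_equal(got, exact, tolerance = 1e-8)
  # a parameter with no likelihood influence leaves the marginal unchanged
  fake2 <- fake
  fake2$dim <- 2L
  fake2$neg_log_post <- nlp + 0.5 * log(2 * pi)  # extra prior coordinate at its mean
  fake2$hessian <- diag(c(post_prec, 1))
  expect_equal(laplace_nlml(fake2), exact, tolerance = 1e-8)
  # dim = 0 degenerates to the plain NLL
  expect_equal(laplace_nlml(fake, dim = 0L), fake$nll)
})

test_that("EM with no stage variation averages posterior means and is deterministic", {
  tabs <- lapply(1:3, function(i) sim_session(seed = 30 + i, n_trials = 400,
                                              subject = paste0("s", i)))
  cfg <- quick_config(max_em_iter = 1L, n_restarts = 1L)
  f <- em_fit("baseline", do.call(rbind, tabs), config = cfg, seed = 9,
              final_hessians = FALSE)
  Theta <- do.call(rbind, lapply(seq_along(f$fits), function(i)
    subject_map_fit("baseline", tabs[[i]],
                    prior = srtraces:::default_prior(
                      model_spec("baseline"),
                      lapply(tabs, function(tb) srtraces:::prepare_session(
                        preprocess(tb), model_spec("baseline"), cfg))),
                    config = cfg, n_restarts = 1L,
                    seed = derive_seed(9, paste0("map_",
                      paste("s", i, ".g1.1", sep = ""), "_it1")),
                    compute_hessian = FALSE)$theta_map))
  expect_equal(unname(f$group_mean), unname(colMeans(Theta)),
               tolerance = 1e-6)
  expect_equal(f$stage_coef, setNames(rep(0, length(f$stage_coef)),
                                      names(f$stage_coef)))
})

test_that("stage coefficients vanish when both stages carry identical data", {
  base <- sim_session(seed = 77, n_trials = 400)
  tabs <- list()
  for (i in 1:2) {
    for (st in 1:2) {
      tb <- base
      tb$subject <- paste0("s", i)
      tb$stage <- st
      tb$graphset <- paste0("g", st)
      tabs[[length(tabs) + 1L]] <- tb
    }
  }
  cfg <- quick_config(max_em_iter = 3L, n_restarts = 1L)
  f <- em_fit("baseline", do.call(rbind, tabs), config = cfg, seed = 2,
              final_hessians = FALSE)
  expect_lt(max(abs(f$stage_coef)), 1e-2)
})

test_that("paired model comparison follows the t-test arithmetic", {
  same <- compare_models(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  d <- compare_models(c(11, 12, 13), c(10, 10, 10))  # differences 1,2,3
  expect_equal(d$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(d$p, stats::pt(d$t, 2, lower.tail = FALSE))
  expect_equal(d$mean_diff, 2)
  set.seed(3)
  sep <- compare_models(10 + rnorm(30, sd = 1e-4), rep(5, 30))
  expect_lt(sep$p, 1e-20)
  expect_error(compare_models(1:2, 3:4), "at least 3")
})

test_that("model scores add the shared AIC penalty per group parameter", {
  fits <- lapply(1:100, function(i)
    structure(list(nlml = 100 + i * 0.01, converged = TRUE, subject = i,
                   graphset = "g", stage = 1, model = "m"),
              class = "subject_fit"))
  s0 <- model_score(fits, n_group_params = 0)
  expect_equal(unname(s0$scores), vapply(fits, `[[`, 0, "nlml"))
  s2 <- model_score(fits, n_group_params = 2)
  expect_equal(unname(s2$scores - s0$scores), rep(0.02, 100))
})

test_that("the EM objective is non-increasing across iterations", {
  tabs <- do.call(rbind, lapply(1:4, function(i)
    sim_session(seed = 50 + i, n_trials = 400, subject = paste0("s", i),
                agent = clean_agent(learner = "recency"))))
  cfg <- quick_config(max_em_iter = 6L, n_restarts = 1L)
  f <- em_fit("recency", tabs, config = cfg, seed = 4,
              compute_nlml_trace = TRUE, final_hessians = FALSE)
  nlml <- vapply(f$trace, `[[`, 0, "total_nlml")
  diffs <- diff(nlml)
  # early iterations descend decisively; near convergence the Laplace
  # approximation and optimizer tolerance allow wobbles of order 0.01 NLL
  # units on totals of thousands, which do not count as increases
  expect_lt(diffs[1], 0)
  expect_true(all(diffs <= 0.05))
})
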