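make_table <- function(nodes, rt, correct = NULL, subject = "s1",
                       stage = 1L, targets = NULL) {
  n <- length(nodes)
  data.frame(subject = subject, graphset = "g1", stage = stage,
             trial = seq_len(n), node = nodes,
             target = targets %||% nodes, rt_ms = rt,
             correct = correct %||% rep(TRUE, n))
}

test_that("preprocessing flags exclusions but keeps rows, and rescales trial", {
  tb <- make_table(nodes = c(1, 2, 3, 2, 1), rt = c(500, 10, 480, 510, 490),
                   correct = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  pp <- preprocess(tb)
  expect_equal(nrow(pp), 5L)              # nothing dropped
  expect_equal(pp$included, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(pp$trial_scaled, (0:4) / 4)
  expect_equal(pp$trial_scaled[5], 1.0)
  expect_error(preprocess(tb[0, ]), "empty")
  expect_error(preprocess(tb[, -3]), "missing column")
})

test_that("nuisance regressors follow the stated conventions", {
  nu <- nuisance_regressors(c(1, 2, 1))
  expect_equal(nu$r_ntrials[3], 2)          # trials since last occurrence
  expect_equal(nu$r_lag10[3], log(2))       # one occurrence in last 10, +1
  expect_true(nu$first_occurrence[1])
  expect_equal(nu$r_ntrials[1], 1)          # never seen: the trial index
  # node unseen in the previous 10 trials contributes log(1) = 0
  nu2 <- nuisance_regressors(c(1, rep(2, 11), 1))
  expect_equal(nu2$r_lag10[13], 0)
})

test_that("mu assembly matches the model equations and nests correctly", {
  nodes <- random_walk(make_modular_graph(), 120, seed = 2)$nodes
  base <- list(mu0 = 6, beta_trial = 0, target_offsets = rep(0, 14),
               sigma = 0.2, shift_frac = 0.5)
  mu_b <- mu_series("baseline", nodes, base, targets = rep(1, 120))
  expect_equal(mu_b, rep(6, 120))
  # recency predictor at t = 1 is the uniform 1/15
  rec <- c(base, list(beta_A = -0.9, alpha_A = 0.2, beta_ntrials = 0,
                      beta_lag10 = 0))
  mu_r <- mu_series("recency", nodes, rec, targets = rep(1, 120))
  expect_equal(mu_r[1], 6 - 0.9 / 15)
  # combined with beta_W = 0 collapses to the pure SR-TD model
  srp <- c(base, list(beta_A = -0.8, alpha_A = 0.1, gamma = 0.7, lam = 0.5,
                      beta_ntrials = 0.1, beta_lag10 = -0.1))
  comb <- c(srp, list(beta_W = 0, alpha_W = 0.3))
  expect_equal(mu_series("combined_sr_td", nodes, comb),
               mu_series("sr_td", nodes, srp), tolerance = 1e-12)
  # and with beta_A = 0 collapses to recency (matching rates)
  comb0 <- c(base, list(beta_A = 0, alpha_A = 0.1, gamma = 0.7, lam = 0.5,
                        beta_W = -0.5, alpha_W = 0.25,
                        beta_ntrials = 0.1, beta_lag10 = -0.1))
  rec0 <- c(base, list(beta_A = -0.5, alpha_A = 0.25,
                       beta_ntrials = 0.1, beta_lag10 = -0.1))
  expect_equal(mu_series("combined_sr_td", nodes, comb0),
               mu_series("recency", nodes, rec0), tolerance = 1e-12)
})

test_that("shifted log-normal NLL has the right density, mode and shift-zero limit", {
  expect_equal(shifted_lognormal_nll(exp(5.5), mu = 5.5, sigma = 1, shift = 0),
               0.5 * log(2 * pi) + 5.5)
  dens <- function(rt) exp(-shifted_lognormal_nll(rt, rep(6, length(rt)),
                                                  0.4, 150))
  expect_equal(stats::integrate(dens, 150, Inf)$value, 1, tolerance = 1e-6)
  mode <- 150 + exp(6 - 0.4^2)
  eps <- 0.5
  expect_lt(shifted_lognormal_nll(mode, 6, 0.4, 150),
            min(shifted_lognormal_nll(mode + eps, 6, 0.4, 150),
                shifted_lognormal_nll(mode - eps, 6, 0.4, 150)))
  expect_equal(shifted_lognormal_nll(300, 5.7, 0.3, shift = 0),
               -stats::dlnorm(300, 5.7, 0.3, log = TRUE))
  expect_equal(shifted_lognormal_nll(100, 5, 0.3, shift = 120), Inf)
})

test_that("sequence NLL reduces to iid shifted log-normal when betas vanish", {
  set.seed(8)
  nodes <- random_walk(make_modular_graph(), 300, seed = 4)$nodes
  rt <- 200 + exp(rnorm(300, 5.8, 0.3))
  tb <- make_table(nodes, rt)
  params <- list(mu0 = 5.8, beta_trial = 0, target_offsets = rep(0, 14),
                 beta_A = 0, beta_W = 0, beta_ntrials = 0, beta_lag10 = 0,
                 alpha_A = 0.1, alpha_W = 0.1, gamma = 0.5, lam = 0.5,
                 shift_frac = 0.4, sigma = 0.3)
  cfg <- quick_config()
  got <- sequence_nll("combined_sr_td", tb, params, cfg)
  shift <- 0.4 * min(rt[101:300])
  want <- sum(shifted_lognormal_nll(rt[101:300], rep(5.8, 200), 0.3, shift))
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(sequence_nll("combined_sr_td", tb, params,
                            fit_config(equilibrate = 300)), "equilibration")
})

test_that("excluded trials advance learner state but carry no likelihood", {
  nodes <- random_walk(make_modular_graph(), 200, seed = 6)$nodes
  rt <- rep(500, 200)
  correct <- rep(TRUE, 200)
  correct[150] <- FALSE
  tb_all <- make_table(nodes, rt)
  tb_exc <- make_table(nodes, rt, correct = correct)
  params <- list(mu0 = 6, beta_trial = -0.1, target_offsets = rep(0, 14),
                 beta_A = -1, beta_W = 0, beta_ntrials = 0.05,
                 beta_lag10 = -0.05, alpha_A = 0.2, alpha_W = 0.1,
                 gamma = 0.6, lam = 0.8, shift_frac = 0.3, sigma = 0.25)
  cfg <- quick_config()
  # learner trajectories identical: mu depends only on the node sequence
  expect_identical(mu_series("sr_td", nodes, params),
                   mu_series("sr_td", nodes, params))
  nll_all <- sequence_nll("sr_td", tb_all, params, cfg)
  nll_exc <- sequence_nll("sr_td", tb_exc, params, cfg)
  # exclusion drops exactly that trial's own likelihood contribution
  mu <- mu_series("sr_td", nodes, params)
  shift_all <- params$shift_frac * min(rt)
  contrib <- shifted_lognormal_nll(rt[150], mu[150], params$sigma, shift_all)
  expect_equal(nll_all - nll_exc, contrib, tolerance = 1e-8)
})

test_that("the shift-zero limit recovers the unshifted log-normal NLL", {
  nodes <- c(1, 2, 3, 2, 1, 2, 3, 2, 1, 2)
  rt <- seq(400, 490, by = 10)
  tb <- make_table(nodes, rt)
  cfg <- fit_config(equilibrate = 2L)
  base <- list(mu0 = 6, beta_trial = 0, target_offsets = rep(0, 14),
               sigma = 0.3)
  nll_eps <- sequence_nll("baseline", tb, c(base, shift_frac = 1e-9), cfg)
  want <- sum(-stats::dlnorm(rt[3:10], 6, 0.3, log = TRUE))
  expect_equal(nll_eps, want, tolerance = 1e-5)
})
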