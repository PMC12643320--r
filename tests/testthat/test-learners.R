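test_that("recency learner initializes uniform and follows the convex update", {
  st <- recency_init(15, 0.1)
  expect_equal(st$W, rep(1 / 15, 15))
  expect_equal(sum(st$W), 1)
  expect_equal(recency_init(2, 0.5)$W, c(0.5, 0.5))
  # alpha = 1 replaces W with the one-hot; alpha = 0 leaves it untouched
  full <- structure(list(W = runif(15), alpha = 1), class = "recency_state")
  expect_equal(recency_update(full, 3)$W, replace(rep(0, 15), 3, 1))
  frozen <- structure(list(W = rep(1 / 15, 15), alpha = 0),
                      class = "recency_state")
  expect_equal(recency_update(frozen, 3)$W, rep(1 / 15, 15))
  # direct arithmetic at alpha = 0.5 from uniform
  st <- recency_update(recency_init(15, 0.5), 3)
  expect_equal(st$W[3], 0.5 + 0.5 / 15)
  expect_equal(st$W[1], 0.5 / 15)
})

test_that("recency W and one-step T rows stay exactly unit-sum under random updates", {
  set.seed(42)
  rs <- recency_init(15, 0.17)
  os <- onestep_init(15, 0.23)
  prev <- sample.int(15, 1)
  for (i in 1:1e4) {
    cur <- sample.int(15, 1)
    rs <- recency_update(rs, cur)
    os <- onestep_update(os, prev, cur)
    prev <- cur
  }
  expect_lt(abs(sum(rs$W) - 1), 1e-12)
  expect_lt(max(abs(rowSums(os$T) - 1)), 1e-12)
})

test_that("one-step update decays the predecessor row then increments the observed entry", {
  full <- onestep_init(15, 0.5)
  full$alpha <- 1
  expect_equal(onestep_update(full, 2, 7)$T[2, ],
               replace(rep(0, 15), 7, 1))
  st <- onestep_update(onestep_init(15, 0.2), 1, 2)
  expect_equal(st$T[1, 2], 0.8 / 15 + 0.2)
  expect_equal(st$T[1, 3], 0.8 / 15)
  expect_equal(st$T[4, ], rep(1 / 15, 15))  # other rows untouched
})

test_that("SR initialization is the uniform-kernel SR", {
  st <- sr_init(15, 0.5, 0.1, 0.5)
  expect_equal(st$M, matrix(2 / 15, 15, 15))  # (I - g Tu)^-1 Tu collapses
  expect_equal(st$e, rep(0, 15))
  expect_equal(sr_init(4, 0, 0.1, 0)$M, matrix(1 / 4, 4, 4))
  expect_equal(rowSums(sr_init(15, 0.7, 0.1, 1)$M), rep(1 / 0.3, 15))
})

test_that("sr_td_update applies trace increment, TD error and decay in order", {
  st <- sr_init(15, 0.5, 0.1, 1)
  st2 <- sr_td_update(st, 4, 9)
  # dutch increment from zero gives e[s_prev] = 1, then decays by gamma*lam
  expect_equal(st2$e[4], 0.5)
  expect_equal(sum(st2$e > 0), 1L)
  # delta = onehot(s_t) + gamma M[s_t,] - M[s_prev,] against the pre-update M
  expect_equal(st2$delta,
               replace(0.5 * st$M[9, ] - st$M[4, ], 9,
                       1 + 0.5 * st$M[9, 9] - st$M[4, 9]))
  # lambda = 0 zeroes the trace after the update (TD(0))
  st0 <- sr_td_update(sr_init(15, 0.5, 0.1, 0), 4, 9)
  expect_equal(st0$e, rep(0, 15))
})

test_that("SR-TD on the deterministic 2-cycle reaches the closed-form SR", {
  # closed form for the alternating walk: M = (T + gamma I) / (1 - gamma^2)
  Mstar <- matrix(c(2 / 3, 4 / 3, 4 / 3, 2 / 3), 2, 2)
  nodes <- rep(c(1L, 2L), length.out = 1e4)
  r <- srtraces:::cpp_run_sr_td(nodes - 1L, 2L, 0.1, 0.5, 0, NULL, 0L)
  expect_lt(max(abs(r$M - Mstar)), 1e-2)
  # R-level reference reaches the same matrix
  st <- sr_init(2, 0.5, 0.1, 0)
  for (t in 2:200) st <- sr_td_update(st, nodes[t - 1], nodes[t])
  r200 <- srtraces:::cpp_run_sr_td(nodes[1:200] - 1L, 2L, 0.1, 0.5, 0, NULL, 0L)
  expect_equal(st$M, r200$M, tolerance = 1e-12)
})

test_that("analytic SR agrees with the brute-force truncated power series", {
  Tm <- transition_matrix(make_modular_graph())
  for (gam in c(0, 0.5, 0.9)) {
    Mser <- matrix(0, 15, 15)
    P <- diag(15)
    for (k in 0:200) {
      P <- P %*% Tm
      Mser <- Mser + gam^k * P
    }
    expect_lt(max(abs(analytic_sr(Tm, gam) - Mser)), 1e-8)
  }
  expect_equal(rowSums(analytic_sr(Tm, 0.7)), rep(1 / 0.3, 15))
  expect_equal(analytic_sr(Tm, 0), Tm)
})

test_that("static SR matches the closed form and commutes", {
  nodes <- rep(c(1L, 2L), length.out = 50)
  expect_equal(static_sr(nodes, 0.5, n_nodes = 2),
               matrix(c(2 / 3, 4 / 3, 4 / 3, 2 / 3), 2, 2))
  That <- empirical_transition_matrix(random_walk(make_modular_graph(),
                                                  2000, seed = 3))
  expect_equal(static_sr(random_walk(make_modular_graph(), 2000, seed = 3), 0),
               That)
  A <- That %*% solve(diag(15) - 0.6 * That)
  B <- solve(diag(15) - 0.6 * That) %*% That
  expect_lt(max(abs(A - B)), 1e-10)
})

test_that("sr_predictor is a normalized expectancy that rejects diverged rows", {
  st <- sr_init(15, 0.5, 0.1, 0.5)
  expect_equal(sr_predictor(st, 1, 2), 1 / 15)
  expect_equal(sum(vapply(1:15, function(j) sr_predictor(st, 3, j), 0)), 1)
  st$M[3, ] <- 0
  expect_error(sr_predictor(st, 3, 1), "diverged")
})

test_that("converged SR prefers within-cluster over cross-cluster transitions", {
  g <- make_modular_graph()
  Tm <- transition_matrix(g)
  idx <- which(g$adjacency > 0, arr.ind = TRUE)
  cross <- g$cluster_of[idx[, 1]] != g$cluster_of[idx[, 2]]
  for (gam in c(0.3, 0.5, 0.7, 0.9)) {
    M <- analytic_sr(Tm, gam)
    pred <- (M / rowSums(M))[idx]
    expect_gt(mean(pred[!cross]), mean(pred[cross]))
  }
})

test_that("hebbian trace update books eligibility-weighted one-hot targets", {
  n <- 5
  up <- hebbian_trace_update(matrix(0, n, n), rep(0, n), 1, 2, 0.1, 0.5)
  expect_equal(up$M[1, 2], 0.1)
  expect_equal(sum(up$M != 0), 1L)
  # A,B,C with gamma = 0.5: M[A,C] receives alpha*gamma on the C step
  st <- hebbian_trace_update(matrix(0, n, n), rep(0, n), 1, 2, 0.1, 0.5)
  st <- hebbian_trace_update(st$M, st$e, 2, 3, 0.1, 0.5)
  expect_equal(st$M[1, 3], 0.1 * 0.5)
})

test_that("long-run hebbian M approximates the analytic SR after row rescaling", {
  g <- make_modular_graph()
  Tm <- transition_matrix(g)
  w <- random_walk(g, 1e5, seed = 21)
  r <- srtraces:::cpp_run_hebbian(w$nodes - 1L, 15L, 0.01, 0.5)
  Mn <- r$M / rowSums(r$M)
  Sn <- analytic_sr(Tm, 0.5)
  Sn <- Sn / rowSums(Sn)
  expect_lt(max(abs(Mn - Sn)), 0.05)
})

test_that("horizon is the geometric-series mass of the discount", {
  expect_equal(round(horizon(0.717), 1), 3.5)
  expect_equal(round(horizon(0.894), 1), 9.4)
  expect_equal(horizon(0), 1.0)
  expect_error(horizon(1), "gamma")
})

test_that("learner trajectories export per-trial predictors as TSV", {
  nodes <- random_walk(make_modular_graph(), 60, seed = 12)$nodes
  path <- tempfile(fileext = ".tsv")
  tr <- learner_trajectory("recency", nodes, list(alpha_A = 0.2), path = path)
  expect_equal(tr$A, r_predictor_series("recency", nodes, 15, 0.2))
  expect_equal(tr$s_prev[-1], nodes[-60])
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$A, tr$A, tolerance = 1e-9)
  unlink(path)
})

test_that("compiled predictor series match the R-level update operations", {
  g <- make_modular_graph()
  nodes <- random_walk(g, 300, seed = 17)$nodes
  for (case in list(list(model = "recency", code = 1L),
                    list(model = "onestep", code = 2L),
                    list(model = "sr_td", code = 3L))) {
    for (lam in c(0, 0.5, 1)) {
      Ar <- r_predictor_series(case$model, nodes, 15, alpha_A = 0.15,
                               gamma = 0.6, lam = lam)
      Ac <- srtraces:::cpp_predictor_series(nodes - 1L, 15L, case$code,
                                            0.15, 0.1, 0.6, lam,
                                            srtraces:::empty_matrix())$A
      expect_equal(Ac, Ar, tolerance = 1e-12,
                   label = paste(case$model, "lam", lam))
      if (case$model != "sr_td") break
    }
  }
})
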