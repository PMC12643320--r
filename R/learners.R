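#' Trial-by-trial predictive learners
#'
#' Four learners map the stimulus stream onto expectancies that drive
#' reaction times:
#'
#' * **Recency** — an unconditional exponentially-weighted running average
#'   `W` over node occurrences (no conditioning on the predecessor state).
#' * **One-step** — a learned conditional transition matrix `T` (decay row,
#'   increment observed entry).
#' * **SR-TD(lambda)** — temporal-difference learning of the successor
#'   representation `M` with dutch eligibility traces; `lambda = 0` is pure
#'   bootstrapping, `lambda = 1` is trace/Monte-Carlo-like learning.
#' * **Static SR** — the SR computed in closed form from the empirical
#'   transition matrix of the whole walk (no trial-by-trial learning).
#'
#' The SR here uses the one-step-ahead convention
#' `M = T + gamma T^2 + gamma^2 T^3 + ... = T (I - gamma T)^{-1}`,
#' so `M[i, j]` is the discounted expected future occupancy of `j` starting
#' from the step after `i`.
#'
#' These R-level single-step operations are the reference semantics; the
#' compiled forward passes used during fitting are tested against them.
#'
#' @name learners
NULL

#' @describeIn learners Initialize a recency learner; `W` uniform `1/n`.
#' @param n number of states.
#' @param alpha learning rate in (0, 1).
#' @export
recency_init <- function(n, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(W = rep(1 / n, n), alpha = alpha), class = "recency_state")
}

#' @describeIn learners Recency update `W <- (1 - alpha) W + alpha I(s_t)`.
#' @param state a learner state.
#' @param s_t observed node (1-based).
#' @export
recency_update <- function(state, s_t) {
  W <- (1 - state$alpha) * state$W
  W[s_t] <- W[s_t] + state$alpha
  state$W <- W
  state
}

#' @describeIn learners Initialize a one-step transition learner; `T`
#'   uniform `1/n`.
#' @export
onestep_init <- function(n, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(T = matrix(1 / n, n, n), alpha = alpha),
            class = "onestep_state")
}

#' @describeIn learners One-step update: row `s_prev` decays by
#'   `(1 - alpha)`, then entry `(s_prev, s_t)` is incremented by `alpha`
#'   (row sums stay exactly 1).
#' @param s_prev predecessor node (1-based).
#' @export
onestep_update <- function(state, s_prev, s_t) {
  state$T[s_prev, ] <- (1 - state$alpha) * state$T[s_prev, ]
  state$T[s_prev, s_t] <- state$T[s_prev, s_t] + state$alpha
  state
}

#' @describeIn learners Initialize an SR-TD(lambda) learner at the SR of the
#'   uniform transition matrix, `M = (I - gamma T_u)^{-1} T_u` (every entry
#'   `1 / (n (1 - gamma))`), with a zero eligibility trace.
#' @param gamma discount in `[0, 1)`.
#' @param lam trace parameter lambda in `[0, 1]`.
#' @export
sr_init <- function(n, gamma, alpha, lam) {
  stopifnot(gamma >= 0, gamma < 1, alpha > 0, alpha < 1, lam >= 0, lam <= 1)
  Tu <- matrix(1 / n, n, n)
  M <- solve(diag(n) - gamma * Tu, Tu)
  structure(list(M = M, e = rep(0, n), alpha = alpha, gamma = gamma,
                 lam = lam),
            class = "sr_state")
}

#' @describeIn learners One SR-TD(lambda) transition update, in the order:
#'   dutch trace increment `e[s_prev] <- (1 - alpha) e[s_prev] + 1`; TD error
#'   `delta = I(s_t) + gamma M[s_t, ] - M[s_prev, ]`; broadcast
#'   `M[s', ] <- M[s', ] + alpha e[s'] delta` for every state; trace decay
#'   `e <- gamma lambda e`. Returns the updated state with the `delta`
#'   vector attached as `$delta`.
#' @export
sr_td_update <- function(state, s_prev, s_t) {
  e <- state$e
  e[s_prev] <- (1 - state$alpha) * e[s_prev] + 1
  delta <- state$gamma * state$M[s_t, ] - state$M[s_prev, ]
  delta[s_t] <- delta[s_t] + 1
  state$M <- state$M + state$alpha * outer(e, delta)
  state$e <- state$gamma * state$lam * e
  state$delta <- delta
  state
}

#' @describeIn learners SR expectancy readout: `M[s_prev, s_t]` normalized
#'   by the row sum of `M[s_prev, ]`.
#' @export
sr_predictor <- function(state, s_prev, s_t) {
  rs <- sum(state$M[s_prev, ])
  if (rs <= 0) stop("nonpositive SR row sum: learning has diverged")
  state$M[s_prev, s_t] / rs
}

#' @describeIn learners Static (non-learning) SR of a walk:
#'   `M = That (I - gamma That)^{-1}` from the empirical transition matrix
#'   over the entire sequence.
#' @param walk an [sr_walk] or node sequence.
#' @export
static_sr <- function(walk, gamma, n_nodes = NULL) {
  That <- empirical_transition_matrix(walk, n_nodes = n_nodes)
  analytic_sr(That, gamma)
}

#' @describeIn learners Closed-form one-step-ahead SR of a transition
#'   matrix: `T (I - gamma T)^{-1}`; the convergence oracle for
#'   [sr_td_update].
#' @param T row-stochastic transition matrix.
#' @export
analytic_sr <- function(T, gamma) {
  stopifnot(gamma >= 0, gamma < 1)
  n <- nrow(T)
  T %*% solve(diag(n) - gamma * T)
}

#' @describeIn learners One transition of the trace-only Hebbian SR learner
#'   (the bootstrap-free lambda = 1 reference): refresh the predecessor's
#'   dutch trace, apply the local forgetting term
#'   `M[s_prev, ] <- M[s_prev, ] - alpha u M[s_prev, ]` (where `u` is the
#'   fresh trace increment), add the one-hot target
#'   `M[s', s_t] <- M[s', s_t] + alpha e[s']` for every state, then decay
#'   `e <- gamma e`. Operates on a bare `(M, e)` pair.
#' @param M SR estimate matrix.
#' @param e eligibility vector.
#' @export
hebbian_trace_update <- function(M, e, s_prev, s_t, alpha, gamma) {
  v <- e[s_prev]
  u <- 1 - alpha * v
  e[s_prev] <- (1 - alpha) * v + 1
  M[s_prev, ] <- M[s_prev, ] - alpha * u * M[s_prev, ]
  M[, s_t] <- M[, s_t] + alpha * e
  e <- gamma * e
  list(M = M, e = e)
}

#' Per-trial learner trajectory
#'
#' Runs a model's learner(s) over a node sequence and returns the per-trial
#' predictor values, optionally written as TSV.
#'
#' @param model model name (see [model_spec]).
#' @param nodes node sequence (1-based) or an [sr_walk].
#' @param params named list of natural-scale learner parameters
#'   (`alpha_A`, `alpha_W`, `gamma`, `lam` as applicable).
#' @param path optional TSV output path.
#' @param n_nodes number of nodes.
#' @return A data.frame with `trial`, `s_prev`, `s_t` and the predictor
#'   column(s) `A` / `W`, invisibly written to `path` if given.
#' @export
learner_trajectory <- function(model, nodes, params, path = NULL,
                               n_nodes = 15L) {
  if (inherits(nodes, "sr_walk")) nodes <- nodes$nodes
  spec <- model_spec(model)
  Tstatic <- if (spec$static) {
    suppressWarnings(empirical_transition_matrix(nodes, n_nodes = n_nodes))
  } else empty_matrix()
  nl <- nl_values(spec, params)
  pred <- cpp_predictor_series(nodes - 1L, n_nodes, spec$code, nl$alpha_A,
                               nl$alpha_W, nl$gamma, nl$lam, Tstatic)
  out <- data.frame(trial = seq_along(nodes),
                    s_prev = c(NA, nodes[-length(nodes)]), s_t = nodes)
  if (!is.null(pred$A)) out$A <- pred$A
  if (!is.null(pred$W)) out$W <- pred$W
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Temporal horizon implied by a discount factor
#'
#' The effective number of future timesteps aggregated by an SR with
#' discount `gamma` is the geometric-series mass `1 / (1 - gamma)`.
#'
#' @param gamma discount in `[0, 1)`.
#' @return Horizon in timesteps.
#' @export
horizon <- function(gamma) {
  if (any(gamma >= 1)) stop("gamma must be < 1")
  1 / (1 - gamma)
}
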