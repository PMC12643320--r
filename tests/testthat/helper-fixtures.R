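# Shared fixtures: everything is generated in code at test time.

# A fast config for short synthetic sessions.
quick_config <- function(equilibrate = 100L, ...) {
  fit_config(equilibrate = equilibrate, ...)
}

# Small two-node path graph (the degenerate alternating-walk case).
path2_graph <- function() {
  A <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  srtraces:::new_sr_graph(A, family = "custom")
}

# A clean (no contamination) agent for deterministic-leaning tests.
clean_agent <- function(...) {
  agent_spec(error_rate = 0, fastguess_rate = 0, ...)
}

# Independent brute-force pattern scanners: explicit per-window checks, kept
# deliberately separate from the vectorized finders they oracle.
brute_trace_scan <- function(nodes) {
  out <- list()
  for (i in seq_len(max(0L, length(nodes) - 4L))) {
    w <- nodes[i:(i + 4L)]
    s <- w[4L]; x <- NA; tt <- w[5L]
    test <- w[1L] == w[4L] && w[3L] == w[5L] &&
      length(unique(c(w[1L], w[2L], w[3L]))) == 3L
    ctrl <- w[3L] == w[5L] && w[4L] != w[5L] &&
      !(w[1L] %in% c(s, tt)) && !(w[2L] %in% c(s, tt))
    if (test) out[[length(out) + 1L]] <- c(i + 4L, 1L)
    else if (ctrl) out[[length(out) + 1L]] <- c(i + 4L, 0L)
  }
  if (!length(out)) return(data.frame(end_trial = integer(0),
                                      is_test = integer(0)))
  m <- do.call(rbind, out)
  data.frame(end_trial = m[, 1L], is_test = m[, 2L])
}

brute_bootstrap_scan <- function(nodes) {
  out <- list()
  for (i in seq_len(max(0L, length(nodes) - 5L))) {
    w <- nodes[i:(i + 5L)]
    bts_distinct <- length(unique(c(w[4L], w[2L], w[3L]))) == 3L
    shared <- w[2L] == w[6L] && w[3L] == w[5L] && bts_distinct
    test <- shared && w[1L] == w[4L]
    ctrl <- shared && !(w[1L] %in% c(w[2L], w[3L], w[4L]))
    if (test) out[[length(out) + 1L]] <- c(i + 5L, 1L)
    else if (ctrl) out[[length(out) + 1L]] <- c(i + 5L, 0L)
  }
  if (!length(out)) return(data.frame(end_trial = integer(0),
                                      is_test = integer(0)))
  m <- do.call(rbind, out)
  data.frame(end_trial = m[, 1L], is_test = m[, 2L])
}

# R-level learner forward passes built from the exported single-step update
# operations; the independent oracle for the compiled predictor series.
r_predictor_series <- function(model, nodes, n, alpha_A, alpha_W = 0.1,
                               gamma = 0, lam = 0) {
  T <- length(nodes)
  A <- rep(NA_real_, T)
  if (model == "recency") {
    st <- recency_init(n, alpha_A)
    for (t in seq_len(T)) {
      A[t] <- st$W[nodes[t]]
      st <- recency_update(st, nodes[t])
    }
  } else if (model == "onestep") {
    st <- onestep_init(n, alpha_A)
    A[1L] <- 1 / n
    for (t in 2:T) {
      A[t] <- st$T[nodes[t - 1L], nodes[t]]
      st <- onestep_update(st, nodes[t - 1L], nodes[t])
    }
  } else if (model == "sr_td") {
    st <- sr_init(n, gamma, alpha_A, lam)
    A[1L] <- 1 / n
    for (t in 2:T) {
      A[t] <- sr_predictor(st, nodes[t - 1L], nodes[t])
      st <- sr_td_update(st, nodes[t - 1L], nodes[t])
    }
  } else stop("unsupported model in helper")
  A
}
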