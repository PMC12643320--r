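#' Read a trial table with strict validation
#'
#' Expects a delimited text file with header
#' `subject,graphset,stage,trial,node,target,rt_ms,correct`; nodes and
#' targets 1-based, RTs in ms. Malformed rows are rejected with
#' line-numbered messages, never silently dropped.
#'
#' @param path CSV/TSV path (delimiter sniffed from the header line).
#' @param n_nodes,n_targets valid ranges for node and target codes.
#' @return A trial table data.frame.
#' @export
read_trials <- function(path, n_nodes = 15L, n_targets = 15L) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("subject", "graphset", "stage", "trial", "node", "target",
              "rt_ms", "correct")
  missing <- setdiff(needed, names(tb))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  line_of <- function(i) i + 1L  # header offset
  bad <- function(cond, what) {
    if (any(cond))
      stop(what, " at line(s) ",
           paste(utils::head(line_of(which(cond)), 5L), collapse = ", "),
           if (sum(cond) > 5L) sprintf(" (+%d more)", sum(cond) - 5L) else "")
  }
  bad(!is.finite(suppressWarnings(as.numeric(tb$rt_ms))), "non-numeric rt_ms")
  tb$rt_ms <- as.numeric(tb$rt_ms)
  bad(tb$rt_ms <= 0, "non-positive rt_ms")
  bad(!tb$node %in% seq_len(n_nodes),
      sprintf("node outside 1..%d", n_nodes))
  bad(!tb$target %in% seq_len(n_targets),
      sprintf("target outside 1..%d", n_targets))
  bad(!tb$stage %in% c(1L, 2L), "stage outside {1, 2}")
  if (!is.logical(tb$correct)) {
    bad(!tb$correct %in% c(0L, 1L, "TRUE", "FALSE", "true", "false"),
        "non-boolean correct")
    tb$correct <- tb$correct %in% c(1L, "TRUE", "true", TRUE)
  }
  tb
}

#' Write a trial table
#'
#' @param table trial table.
#' @param path output path (`.tsv` writes tab-separated, else comma).
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  cols <- c("subject", "graphset", "stage", "trial", "node", "target",
            "rt_ms", "correct")
  utils::write.table(table[, cols], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param data path to a trial table, or a trial table data.frame.
#' @param out_dir output directory for the report bundle.
#' @param models character vector of models to fit (see [model_spec]).
#' @param reference model whose score the others are compared against
#'   (must be in `models`).
#' @param signatures run the trace/bootstrap signature contrasts.
#' @param cluster_analysis run the first/second cluster-entry analysis
#'   (needs walks on the modular graph).
#' @param seed master seed.
#' @param fit a [fit_config].
#' @return A `run_config` list.
#' @export
run_config <- function(data, out_dir = tempfile("srtraces_run_"),
                       models = c("baseline", "recency"),
                       reference = models[[1L]],
                       signatures = FALSE, cluster_analysis = FALSE,
                       seed = 1L, fit = fit_config()) {
  stopifnot(reference %in% models)
  structure(list(data = data, out_dir = out_dir, models = models,
                 reference = reference, signatures = signatures,
                 cluster_analysis = cluster_analysis,
                 seed = as.integer(seed), fit = fit),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config]; `fit:` holds
#' [fit_config] fields.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fit <- do.call(fit_config, y$fit %||% list())
  run_config(data = y$data,
             out_dir = y$out_dir %||% tempfile("srtraces_run_"),
             models = unlist(y$models %||% c("baseline", "recency")),
             reference = y$reference %||% unlist(y$models)[[1L]],
             signatures = isTRUE(y$signatures),
             cluster_analysis = isTRUE(y$cluster_analysis),
             seed = y$seed %||% 1L, fit = fit)
}

#' Run the full analysis pipeline
#'
#' Preprocess, fit every requested model hierarchically, score and compare
#' against the reference model, optionally run the signature analyses, and
#' write a report bundle (JSON report, TSV tables, plain-text log). A
#' failing model fit is recorded in the report, not fatal. Idempotent given
#' identical inputs and seed.
#'
#' @param config a [run_config].
#' @return The report bundle (list), invisibly; written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  trials <- if (is.character(config$data)) read_trials(config$data)
            else config$data
  trials <- preprocess(trials)
  logf("loaded %d trials, %d sessions", nrow(trials),
       length(split_sessions(trials)))
  logf("excluded from likelihood: %d incorrect, %d fast (<30 ms)",
       sum(!trials$correct), sum(trials$correct & trials$rt_ms < 30))

  fits <- list()
  scores <- list()
  for (m in config$models) {
    res <- tryCatch(
      em_fit(m, trials, config = config$fit,
             seed = derive_seed(config$seed, paste0("fit_", m))),
      error = function(e) e)
    if (inherits(res, "error")) {
      logf("model %s FAILED: %s", m, conditionMessage(res))
      fits[[m]] <- NULL
    } else {
      fits[[m]] <- res
      scores[[m]] <- model_score(res)
      nc <- sum(!scores[[m]]$converged)
      logf("model %s: %d EM iterations, mean score %.3f, %d non-converged",
           m, res$n_iter, mean(scores[[m]]$scores), nc)
    }
  }

  score_table <- do.call(rbind, lapply(names(scores), function(m) {
    data.frame(model = m, mean_score = mean(scores[[m]]$scores),
               n_sessions = length(scores[[m]]$scores),
               n_group_params = scores[[m]]$n_group_params)
  }))
  if (!is.null(score_table))
    score_table <- score_table[order(score_table$mean_score), ]

  comparisons <- list()
  ref <- config$reference
  if (!is.null(scores[[ref]])) {
    for (m in setdiff(names(scores), ref)) {
      cmp <- compare_models(scores[[ref]], scores[[m]])
      comparisons[[m]] <- c(list(reference = ref, model = m), cmp)
    }
  }

  signature_results <- list()
  if (isTRUE(config$signatures)) {
    for (kind in c("trace", "bootstrap")) {
      matches <- find_patterns(trials, kind)
      signature_results[[kind]] <-
        unclass(signature_contrast(matches, kind))
      logf("%s contrast: %d matches, effect %.2f ms (z = %.2f)", kind,
           signature_results[[kind]]$n_obs,
           signature_results[[kind]]$effect_estimate,
           signature_results[[kind]]$z)
    }
  }
  if (isTRUE(config$cluster_analysis)) {
    ce <- cluster_entry_analysis(trials, make_modular_graph(),
                                 config = config$fit)
    signature_results$cluster_entry <- unclass(ce)
    logf("cluster-entry effect %.4f (z = %.2f)", ce$effect_estimate, ce$z)
  }

  bundle <- list(
    seed = config$seed,
    models = config$models,
    score_table = score_table,
    comparisons = comparisons,
    signatures = signature_results,
    group_estimates = lapply(fits, function(f)
      as.list(signif(from_unconstrained(f$group_mean), 10))))
  write_report(bundle, config$out_dir, log_lines = log_lines,
               scores = scores)
  invisible(bundle)
}

#' Write a report bundle to disk
#'
#' Emits `report.json`, `scores.tsv`, `comparisons.tsv` and `run.log`.
#'
#' @param bundle report list (as built by [run_pipeline]).
#' @param dir output directory.
#' @param log_lines character vector for `run.log`.
#' @param scores named list of `model_score` objects.
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir, log_lines = character(0),
                         scores = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  if (!is.null(bundle$score_table))
    utils::write.table(bundle$score_table, file.path(dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(bundle$comparisons)) {
    cmp <- do.call(rbind, lapply(bundle$comparisons, function(x)
      data.frame(reference = x$reference, model = x$model, t = x$t,
                 p = x$p, mean_diff = x$mean_diff,
                 ci_lo = x$ci95[1L], ci_hi = x$ci95[2L])))
    utils::write.table(cmp, file.path(dir, "comparisons.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(scores)) {
    per <- do.call(rbind, lapply(names(scores), function(m)
      data.frame(model = m, session = names(scores[[m]]$scores),
                 score = unname(scores[[m]]$scores))))
    utils::write.table(per, file.path(dir, "session_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
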