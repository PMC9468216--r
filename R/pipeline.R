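#' Stratified baseline summary table
#'
#' Per variable and category, the count and within-stratum column percentage
#' (rounded half-up to one decimal) for subjects with and without
#' multimorbidity — the layout of a survey baseline-characteristics table.
#'
#' @param data Complete integer-coded data frame including `mmd`.
#' @param variables Variables to tabulate; default the ten predictors.
#' @return A tibble `(variable, code, label, mmd, n, pct)`.
#' @export
#' @examples
#' d <- ancestral_sample(charls_like_network(), 5000, seed = 2)
#' table1_summary(d)
table1_summary <- function(data, variables = NULL) {
  data <- tibble::as_tibble(data)
  if (!"mmd" %in% names(data)) {
    stop_contract("`mmd` column required", "mmdbn_structure_error")
  }
  variables <- variables %||% setdiff(intersect(mmd_variables(), names(data)), "mmd")
  cb <- mmd_codebook()
  strata <- sort(unique(cb$code[cb$variable == "mmd"]))
  stratum_n <- vapply(strata, function(s) sum(data$mmd == s), numeric(1))
  if (any(stratum_n == 0)) {
    warn(sprintf("empty outcome stratum (mmd = %s); its percentages reported as 0",
                 paste(strata[stratum_n == 0], collapse = ", ")))
  }
  purrr::map_dfr(variables, function(v) {
    codes <- cb[cb$variable == v, ]
    purrr::map_dfr(seq_along(strata), function(i) {
      s <- strata[i]
      n <- vapply(codes$code, function(k) sum(data$mmd == s & data[[v]] == k), numeric(1))
      tibble::tibble(
        variable = v, code = codes$code, label = codes$label, mmd = s, n = n,
        pct = if (stratum_n[i] == 0) 0 else round_half_up(100 * n / stratum_n[i], 1)
      )
    })
  })
}

#' Configuration object for a full pipeline run
#'
#' Collects every knob of [run_pipeline()] into one serializable list: the
#' input (a CSV path, or a synthetic-cohort specification), the analysis
#' settings, and a single master seed from which each random stage derives
#' a named sub-stream. The configuration is persisted as JSON next to a
#' run's outputs so a run can be reproduced exactly.
#'
#' @param input Optional path to an integer-coded CSV with the 11 study
#'   columns (missing cells empty or `NA`).
#' @param synthetic_n Rows to simulate from [charls_like_network()] when no
#'   `input` is given (default 20000).
#' @param missing_rate MCAR missingness injected into the simulated cohort
#'   (default 0.05; ignored for file input).
#' @param alpha Significance level for structure learning (default 0.05).
#' @param pseudo_count Laplace constant for parameter learning (default 0).
#' @param impute_trees,impute_max_iter Random-forest imputation settings.
#' @param queries List of posterior queries, each
#'   `list(target =, evidence = c(...))`; default a sequential
#'   multimorbidity risk chain (light activity, then short sleep, then age
#'   65-75).
#' @param seed Master seed (default 1).
#' @param out_dir Output directory.
#' @return A list of class `mmd_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic_n = 20000, missing_rate = 0.05,
                            alpha = 0.05, pseudo_count = 0,
                            impute_trees = 100, impute_max_iter = 10,
                            queries = default_queries(), seed = 1,
                            out_dir = tempfile("mmdbn_run_")) {
  structure(list(
    input = input, synthetic_n = synthetic_n, missing_rate = missing_rate,
    alpha = alpha, pseudo_count = pseudo_count,
    impute_trees = impute_trees, impute_max_iter = impute_max_iter,
    queries = queries, seed = seed, out_dir = out_dir
  ), class = "mmd_pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_queries <- function() {
  list(
    list(target = "mmd", evidence = c()),
    list(target = "mmd", evidence = c(physical_activity = 1)),
    list(target = "mmd", evidence = c(physical_activity = 1, sleep_duration = 1)),
    list(target = "mmd", evidence = c(physical_activity = 1, sleep_duration = 1, age = 3))
  )
}

#' Run the complete multimorbidity analysis pipeline
#'
#' Executes the study stages in order — load or simulate the cohort,
#' validate, impute missing values, write the stratified baseline summary,
#' fit the logistic baseline (odds-ratio table and forest-plot data), learn
#' the network structure with MMHC, estimate CPTs by maximum likelihood,
#' compute prior marginals, and answer the configured posterior queries —
#' writing each artifact as CSV (plus DOT/BIF for the network and a JSON
#' manifest of the configuration) into `config$out_dir`. Outputs are
#' deterministic for a fixed configuration. A stage failure aborts with an
#' error naming the stage, after persisting the partial log.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list with the run's tibbles (`data`, `summary`,
#'   `or_table`, `forest`, `structure`, `fit`, `marginals`, `queries`) and
#'   `paths` of the written files.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "mmd_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("INFO %s", sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      log_lines <<- c(log_lines, sprintf("ERROR stage %s: %s", name, conditionMessage(e)))
      writeLines(log_lines, log_path)
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = c("mmdbn_stage_error", "mmdbn_error"))
    })
    say("stage %-9s done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  paths <- list()
  out_csv <- function(tab, name) {
    p <- file.path(config$out_dir, name)
    readr::write_csv(tab, p)
    paths[[name]] <<- p
    tab
  }

  raw <- stage("load", {
    if (!is.null(config$input)) {
      d <- readr::read_csv(config$input, col_types = readr::cols(.default = "d"),
                           na = c("", "NA"))
      validate_dataset(d)
      d
    } else {
      d <- ancestral_sample(charls_like_network(), config$synthetic_n,
                            seed = sub_seed(config$seed, "sample"))
      if (config$missing_rate > 0) {
        d <- inject_missingness(d, rate = config$missing_rate,
                                seed = sub_seed(config$seed, "mask"))$data
      }
      d
    }
  })
  completed <- stage("impute", {
    if (anyNA(raw)) {
      res <- rf_impute(raw, max_iter = config$impute_max_iter,
                       trees = config$impute_trees,
                       seed = sub_seed(config$seed, "impute"))
      out_csv(tibble::tibble(iteration = seq_along(res$disagreement),
                             disagreement = res$disagreement),
              "imputation_convergence.csv")
      res$completed
    } else raw
  })
  out_csv(completed, "dataset_completed.csv")
  summary_tab <- stage("summarize", out_csv(table1_summary(completed), "table1_summary.csv"))
  logit <- stage("logit", fit_logistic_irls(completed))
  or_tab <- out_csv(odds_ratio_table(logit), "odds_ratios.csv")
  forest <- out_csv(forest_plot_data(or_tab), "forest_plot_data.csv")
  learned <- stage("learn", mmhc(completed, alpha = config$alpha))
  out_csv(learned$trace, "search_trace.csv")
  out_csv(learned$dag$edges, "structure_edges.csv")
  paths[["structure.dot"]] <- write_dot(learned$dag, file.path(config$out_dir, "structure.dot"))
  fit <- stage("fit", fit_mle(learned$dag, completed, pseudo_count = config$pseudo_count))
  paths[["network.bif"]] <- write_bif(fit, file.path(config$out_dir, "network.bif"))
  out_csv(tidy(fit), "cpts.csv")
  marginals <- stage("marginals", out_csv(prior_marginals(fit), "prior_marginals.csv"))
  queries <- if (length(config$queries)) {
    stage("infer", out_csv(query_report(fit, config$queries), "query_report.csv"))
  } else NULL
  manifest <- config
  manifest$out_dir <- NULL
  jsonlite::write_json(unclass(manifest), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths[["config.json"]] <- file.path(config$out_dir, "config.json")
  say("run complete: %d artifact(s) in %s", length(paths), config$out_dir)
  invisible(list(data = completed, summary = summary_tab, or_table = or_tab,
                 forest = forest, structure = learned, fit = fit,
                 marginals = marginals, queries = queries, paths = paths))
}
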