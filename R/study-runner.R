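#' Configuration of a simulation study run
#'
#' Selects the cells of the scenario grid (scenarios x outcomes x sample
#' sizes), the selectors to compare, and the replicate count. The full study
#' design is 5 scenarios x 2 outcomes x 2 sample sizes with 1000 replicates;
#' the default replicate count here is 100, which already stabilizes medians
#' of the selection counts and AUC.
#'
#' @param scenarios subset of 1:5.
#' @param outcomes subset of `c("overweight", "obese")`.
#' @param sample_sizes subset of `c(1000, 500)` (training = validation size).
#' @param methods subset of [selection_methods()].
#' @param n_replicates replicates per cell.
#' @param master_seed master integer seed; every replicate derives its own
#'   streams from it.
#' @param n_boot bootstrap count for the bootstrap-enhanced LASSO.
#' @param plan a [tuning_plan()]; its fold seed is re-derived per replicate.
#' @param p number of predictors.
#' @param out_dir directory for incremental replicate records (enables
#'   crash-resumable runs); `NULL` keeps everything in memory.
#' @return an object of class `study_config`.
#' @export
study_config <- function(scenarios = 1:5,
                         outcomes = c("overweight", "obese"),
                         sample_sizes = c(1000L, 500L),
                         methods = selection_methods(),
                         n_replicates = 100L, master_seed = 1L,
                         n_boot = 100L, plan = tuning_plan(),
                         p = 100L, out_dir = NULL) {
  stopifnot(length(scenarios) >= 1, all(scenarios %in% 1:5),
            length(outcomes) >= 1,
            all(outcomes %in% c("overweight", "obese")),
            length(sample_sizes) >= 1, length(methods) >= 1,
            all(methods %in% selection_methods()), n_replicates >= 1)
  structure(list(scenarios = as.integer(scenarios), outcomes = outcomes,
                 sample_sizes = as.integer(sample_sizes), methods = methods,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 n_boot = as.integer(n_boot), plan = plan, p = as.integer(p),
                 out_dir = out_dir),
            class = "study_config")
}

record_columns <- c("scenario", "outcome", "n_train", "replicate", "method",
                    "n_selected", "correct_nonzero", "correct_zero", "auc")

#' Run the simulation study
#'
#' For every (scenario, outcome, sample size, replicate) generates a
#' train/validation pair, fits each requested selector, and evaluates it.
#' When `out_dir` is set, records are appended to
#' `<out_dir>/replicates.csv` as they complete and a restarted run skips
#' work already on disk, so killing and restarting yields identical final
#' tables. A replicate whose fit fails is recorded as failed and skipped;
#' more than 5% failures aborts the run.
#'
#' @param config a [study_config()].
#' @param verbose print per-cell progress.
#' @return list with `records` (per-replicate metrics), `summary` (median /
#'   min / max per cell and metric, see [summarize_records()]), and
#'   `failures`.
#' @export
run_study <- function(config, verbose = FALSE) {
  rec_file <- NULL
  done <- character(0)
  records <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    rec_file <- file.path(config$out_dir, "replicates.csv")
    if (file.exists(rec_file)) {
      prev <- utils::read.csv(rec_file, stringsAsFactors = FALSE)
      records <- list(prev)
      done <- with(prev, paste(scenario, outcome, n_train, replicate, method))
    }
  }
  failures <- list()
  total <- 0L
  for (sc in config$scenarios) for (oc in config$outcomes)
    for (n in config$sample_sizes) {
      spec <- scenario_spec(sc, oc, n_train = n, p = config$p)
      for (r in seq_len(config$n_replicates)) {
        todo <- setdiff(config$methods,
                        sub(".* ", "",
                            done[startsWith(done, paste(sc, oc, n, r, ""))]))
        if (!length(todo)) next
        pair <- make_scenario_replicate(spec, r, config$master_seed)
        for (m in todo) {
          total <- total + 1L
          plan <- config$plan
          plan$fold_seed <- mix_seed(config$master_seed, "fold", sc, oc, n, r, m)
          rec <- tryCatch({
            fit <- fit_method(m, pair$train$X, pair$train$y, plan,
                              n_boot = config$n_boot)
            evaluate_replicate(fit, pair$train, pair$validation,
                               meta = list(scenario = sc, outcome = oc,
                                           n_train = n, replicate = r))
          }, error = function(e) {
            failures[[length(failures) + 1L]] <<-
              list(scenario = sc, outcome = oc, n = n, replicate = r,
                   method = m, message = conditionMessage(e))
            NULL
          })
          if (is.null(rec)) next
          rec <- rec[record_columns]
          records[[length(records) + 1L]] <- rec
          if (!is.null(rec_file)) {
            utils::write.table(rec, rec_file, sep = ",", append = file.exists(rec_file),
                               col.names = !file.exists(rec_file),
                               row.names = FALSE)
          }
        }
        if (verbose)
          message(sprintf("scenario %d %s n=%d replicate %d done", sc, oc, n, r))
      }
    }
  if (total > 0 && length(failures) / total > 0.05)
    stop(sprintf("%d of %d fits failed (> 5%%)", length(failures), total))
  records <- do.call(rbind, records)
  if (!is.null(records)) {
    ord <- with(records, order(scenario, outcome, n_train, method, replicate))
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  list(records = records,
       summary = if (!is.null(records)) summarize_records(records) else NULL,
       failures = failures)
}

#' Side-by-side method comparison tables
#'
#' Renders one wide table per metric (methods as rows, scenario/outcome/n
#' cells as columns) with `median (min, max)` entries, mirroring the layout
#' of the study's result tables; optionally writes one CSV per metric.
#'
#' @param summary a summary `data.frame` from [run_study()] or
#'   [summarize_records()].
#' @param out_dir optional directory for `table_<metric>.csv` files.
#' @return named list of wide `data.frame`s, one per metric.
#' @export
compare_report <- function(summary, out_dir = NULL) {
  if (is.null(summary) || nrow(summary) == 0) return(list())
  tabs <- list()
  for (m in unique(summary$metric)) {
    s <- summary[summary$metric == m, , drop = FALSE]
    s$cell <- paste0("s", s$scenario, "_", substr(s$outcome, 1, 2), "_n",
                     s$n_train)
    s$value <- sprintf("%g (%g,%g)", s$median, s$min, s$max)
    wide <- stats::reshape(s[, c("method", "cell", "value")],
                           idvar = "method", timevar = "cell",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    rownames(wide) <- NULL
    tabs[[m]] <- wide
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(wide, file.path(out_dir, paste0("table_", m, ".csv")),
                       row.names = FALSE)
    }
  }
  tabs
}
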