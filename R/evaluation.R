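#' Selection-accuracy counts against the true model
#'
#' @param fit a `fit_result` (or any list with a `support` index vector).
#' @param truth true model with a `support` index vector.
#' @param p total number of predictors.
#' @return list with `n_selected`, `correct_nonzero` (true signals with a
#'   non-zero fitted coefficient), and `correct_zero` (true noise variables
#'   with a fitted coefficient of exactly zero).
#' @export
selection_metrics <- function(fit, truth, p) {
  sel <- fit$support
  tru <- truth$support
  list(n_selected = length(sel),
       correct_nonzero = length(intersect(sel, tru)),
       correct_zero = p - length(tru) - length(setdiff(sel, tru)))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, with half credit for ties; computed from midranks.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes required")
  r <- rank(scores) # midranks give ties half credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate one fitted replicate
#'
#' Scores the validation rows with the fitted linear predictor and collects
#' the per-replicate record used by the summary tables: sparsity, selection
#' accuracy against the generating model, and validation AUC.
#'
#' @param fit a `fit_result` produced from `train`.
#' @param train,validation datasets from [make_scenario_replicate()];
#'   `validation` must share the training set's true model.
#' @param meta optional named list of identifiers (scenario, outcome, ...)
#'   prepended to the record.
#' @return one-row `data.frame` with `method`, `n_selected`,
#'   `correct_nonzero`, `correct_zero`, and `auc`.
#' @export
evaluate_replicate <- function(fit, train, validation, meta = list()) {
  p <- ncol(train$X)
  m <- selection_metrics(fit, train$truth, p)
  scores <- drop(fit$beta0 + validation$X %*% fit$beta)
  rec <- c(meta, list(method = fit$method, n_selected = m$n_selected,
                      correct_nonzero = m$correct_nonzero,
                      correct_zero = m$correct_zero,
                      auc = auc(scores, validation$y)))
  as.data.frame(rec, stringsAsFactors = FALSE)
}

#' Median (minimum, maximum) summaries of replicate records
#'
#' Groups records and summarizes each metric as the study's tables do:
#' median with the (min, max) range. The median of an even count is the
#' midpoint mean, so half-integer medians occur.
#'
#' @param records `data.frame` of replicate records.
#' @param metrics metric column names to summarize.
#' @param by grouping column names present in `records`.
#' @return long-format `data.frame` with columns `by`, `metric`, `median`,
#'   `min`, `max`, `n_replicates`.
#' @export
summarize_records <- function(records,
                              metrics = c("n_selected", "correct_nonzero",
                                          "correct_zero", "auc"),
                              by = intersect(c("scenario", "outcome", "n_train",
                                               "method"), names(records))) {
  stopifnot(nrow(records) > 0, all(metrics %in% names(records)))
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- lapply(levels(key), function(k) {
    grp <- records[key == k, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(m) {
      v <- grp[[m]]
      cbind(grp[1, by, drop = FALSE],
            data.frame(metric = m, median = stats::median(v), min = min(v),
                       max = max(v), n_replicates = length(v)))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
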