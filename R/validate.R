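#' Hold-out evaluation of a classifier factory
#'
#' Splits the cohort into estimation / validation / test partitions, hands the
#' factory the two training partitions only, and reports the full metrics
#' battery on the untouched test partition.
#'
#' @param factory `function(estimation, validation) -> function(cohort)`:
#'   trains a classifier and returns a predictor closure mapping a cohort to
#'   0/1 labels. [gmdh_factory()] builds one for the GMDH model.
#' @param x a `cohort`.
#' @param fractions (estimation, validation, test) fractions, default
#'   40/10/50.
#' @param seed split seed.
#' @return A `metrics_report` for the test partition, with the predicted test
#'   labels attached as attribute `"labels"` and the split as `"split"`.
#' @export
evaluate_holdout <- function(factory, x, fractions = c(0.40, 0.10, 0.50),
                             seed = 1L) {
  parts <- split_holdout(x, fractions = fractions, seed = seed)
  predictor <- factory(parts$estimation, parts$validation)
  labels <- predictor(parts$test)
  rep <- compute_metrics(confusion(labels, class_labels(parts$test)))
  attr(rep, "labels") <- labels
  attr(rep, "split") <- parts
  rep
}

#' k-fold cross-validated evaluation
#'
#' Runs the factory on every fold of [make_cv_folds()] (default 4 folds with
#' the 60/15/25 estimation/validation/test design) and aggregates the
#' per-fold test metrics as mean and standard deviation.
#'
#' @inheritParams evaluate_holdout
#' @param k number of folds.
#' @param fractions full-table (estimation, validation, test) proportions per
#'   fold.
#' @return List: `folds` (per-fold `metrics_report`s), `mean` and `sd`
#'   (named vectors over the scalar indices).
#' @export
evaluate_cv <- function(factory, x, k = 4L, fractions = c(0.60, 0.15, 0.25),
                        seed = 1L) {
  folds <- make_cv_folds(x, k = k, fractions = fractions, seed = seed)
  reports <- lapply(folds, function(f) {
    predictor <- factory(f$estimation, f$validation)
    compute_metrics(confusion(predictor(f$test), class_labels(f$test)))
  })
  keys <- c("Se", "Sp", "Acc", "Pr", "F1S", "AUC", "MCC", "DOR", "DP", "Kappa")
  vals <- sapply(keys, function(k2) vapply(reports, `[[`, 0, k2))
  list(folds = reports,
       mean = apply(vals, 2L, mean),
       sd = apply(vals, 2L, stats::sd))
}

#' GMDH classifier factory for the evaluation harnesses
#'
#' @param control,pso,... passed to [gmdh_fit()].
#' @param seed fit seed.
#' @return A factory function suitable for [evaluate_holdout()] /
#'   [evaluate_cv()].
#' @export
gmdh_factory <- function(control = gmdh_control(), pso = pso_control(),
                         seed = 1L, ...) {
  function(estimation, validation) {
    fit <- gmdh_fit(estimation, validation = validation, control = control,
                    pso = pso, seed = seed, ...)
    function(newdata) predict(fit, newdata)
  }
}
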