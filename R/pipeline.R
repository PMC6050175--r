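#' Run the full training pipeline from a configuration
#'
#' Executes cohort loading, 40/10/50 hold-out splitting, preprocessing,
#' I-RELIEF, PSS, GMDH fitting and test-set evaluation from a single
#' configuration, and persists the artifacts: `model.json`,
#' `metrics.json`, `metrics.md` and `run.log` (every effective parameter).
#'
#' @param config a list, or the path of a YAML/JSON file, with fields:
#'   \describe{
#'     \item{cohort}{path of the cohort CSV/TSV.}
#'     \item{schema}{path of the schema file.}
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{split}{optional: `fractions` (default 0.40/0.10/0.50), `seed`.}
#'     \item{gmdh}{optional [gmdh_control()] fields.}
#'     \item{pso}{optional [pso_control()] fields.}
#'     \item{seed}{master seed (default 1).}
#'   }
#' @return Invisibly, a list with `model`, `report` and the output paths.
#' @export
run_train <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config) else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  for (field in c("cohort", "schema", "out_dir")) {
    if (is.null(config[[field]]))
      stop("config is missing required field '", field, "'")
  }
  seed <- as.integer(config$seed %||% 1L)
  fractions <- as.numeric(config$split$fractions %||% c(0.40, 0.10, 0.50))
  split_seed <- as.integer(config$split$seed %||% seed)
  control <- do.call(gmdh_control, config$gmdh %||% list())
  pso <- do.call(pso_control, config$pso %||% list())

  x <- read_cohort(config$cohort, config$schema)
  parts <- split_holdout(x, fractions = fractions, seed = split_seed)
  fit <- gmdh_fit(parts$estimation, validation = parts$validation,
                  control = control, pso = pso, seed = seed)
  report <- compute_metrics(confusion(predict(fit, parts$test),
                                      class_labels(parts$test)))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(model = file.path(config$out_dir, "model.json"),
                metrics_json = file.path(config$out_dir, "metrics.json"),
                metrics_md = file.path(config$out_dir, "metrics.md"),
                log = file.path(config$out_dir, "run.log"))
  write_gmdh(fit, paths$model)
  write_metrics(list(gmdh = report), paths$metrics_json)
  write_metrics(list(gmdh = report), paths$metrics_md)
  writeLines(c(
    paste0("cohort: ", config$cohort),
    paste0("schema: ", config$schema),
    paste0("n: ", nrow(x$data)),
    paste0("split fractions: ", paste(fractions, collapse = "/")),
    paste0("split seed: ", split_seed),
    paste0("fit seed: ", seed),
    paste0("gmdh: ", paste(names(unclass(control)), unlist(control),
                           sep = "=", collapse = ", ")),
    paste0("pso: ", paste(names(unclass(pso)), unlist(pso),
                          sep = "=", collapse = ", ")),
    paste0("selected predictors: ", paste(fit$feature_names, collapse = ", ")),
    sprintf("test fitness (mean Se/Sp/Pr): %.4f",
            mean(c(report$Se, report$Sp, report$Pr)))),
    paths$log)
  invisible(list(model = fit, report = report, paths = paths))
}

# --- baseline learners (library implementations, predictor-matrix interface) --

baseline_fit <- function(name, Xtr, ytr, Xval, yval, seed = 1L) {
  dtr <- data.frame(Xtr, y = factor(ytr, levels = c(0, 1)))
  switch(name,
    mlr = {
      fit <- suppressWarnings(stats::glm(y ~ ., data = dtr, family = stats::binomial()))
      function(X) as.integer(stats::predict(fit, data.frame(X),
                                            type = "response") >= 0.5)
    },
    dt = {
      if (!requireNamespace("rpart", quietly = TRUE)) stop("rpart not available")
      fit <- rpart::rpart(y ~ ., data = dtr, method = "class",
                          parms = list(split = "information"))
      cp_tab <- fit$cptable
      fit <- rpart::prune(fit, cp = cp_tab[which.min(cp_tab[, "xerror"]), "CP"])
      function(X) as.integer(as.character(
        stats::predict(fit, data.frame(X), type = "class")))
    },
    mlp = {
      if (!requireNamespace("nnet", quietly = TRUE)) stop("nnet not available")
      fit <- with_seed(seed,
        nnet::nnet(y ~ ., data = dtr, size = 10L, decay = 1e-3,
                   maxit = 200L, trace = FALSE))
      function(X) as.integer(stats::predict(fit, data.frame(X)) >= 0.5)
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) stop("e1071 not available")
      # soft margin / kernel width tuned on the validation partition
      grid <- expand.grid(cost = c(0.1, 1, 10), gamma = c(0.05, 0.2, 1))
      best <- NULL; best_fit <- -Inf
      for (r in seq_len(nrow(grid))) {
        m <- e1071::svm(y ~ ., data = dtr, kernel = "radial",
                        cost = grid$cost[r], gamma = grid$gamma[r])
        lab <- as.integer(as.character(stats::predict(m, data.frame(Xval))))
        f <- fitness_mean_se_sp_pr(lab, yval)
        if (f > best_fit) { best_fit <- f; best <- m }
      }
      function(X) as.integer(as.character(stats::predict(best, data.frame(X))))
    },
    stop("unknown baseline '", name, "'"))
}

#' Compare the GMDH classifier with standard baseline learners
#'
#' Trains the proposed model and a set of baseline classifiers — pruned
#' decision tree (`"dt"`), single-hidden-layer perceptron with 10 sigmoid
#' units (`"mlp"`), RBF support vector machine with validation-tuned soft
#' margin and kernel width (`"svm"`) and logistic regression at the 0.5
#' cutoff (`"mlr"`) — on the identical training partition, evaluates all on
#' the identical test partition, and compares each baseline with the
#' proposed model by McNemar's test. Sequential forward selection is applied
#' to the MLP and SVM inputs (tree and logistic models select internally).
#' Baselines come from library implementations; only the GMDH model is this
#' package's own.
#'
#' @param x a `cohort`.
#' @param baselines subset of `c("dt", "mlp", "svm", "mlr")`.
#' @param fractions hold-out (estimation, validation, test) fractions.
#' @param control,pso GMDH settings.
#' @param seed split + fit seed.
#' @return List: `table` (one metrics row per classifier, proposed first),
#'   `mcnemar` (p-value per baseline vs the proposed model), `reports`.
#' @export
run_compare <- function(x, baselines = c("dt", "mlp", "svm", "mlr"),
                        fractions = c(0.40, 0.10, 0.50),
                        control = gmdh_control(), pso = pso_control(),
                        seed = 1L) {
  baselines <- match.arg(baselines, several.ok = TRUE)
  parts <- split_holdout(x, fractions = fractions, seed = seed)
  ytest <- class_labels(parts$test)

  fit <- gmdh_fit(parts$estimation, validation = parts$validation,
                  control = control, pso = pso, seed = seed)
  labels <- list(proposed = predict(fit, parts$test))

  # identical mapped training data for every baseline
  map <- fit$map
  Xe <- build_predictors(map, parts$estimation)
  Xv <- build_predictors(map, parts$validation)
  Xt <- build_predictors(map, parts$test)
  ye <- class_labels(parts$estimation)
  yv <- class_labels(parts$validation)
  Xtr <- rbind(Xe, Xv); ytr <- c(ye, yv)
  n_e <- nrow(Xe)

  for (b in baselines) {
    feat <- seq_len(ncol(Xtr))
    if (b %in% c("mlp", "svm")) {
      feat <- sfs(Xtr, ytr, fitness = function(Xsub, y) {
        pred <- baseline_fit(b, Xsub[seq_len(n_e), , drop = FALSE], ye,
                             Xsub[-seq_len(n_e), , drop = FALSE], yv,
                             seed = seed)
        fitness_mean_se_sp_pr(pred(Xsub[-seq_len(n_e), , drop = FALSE]), yv)
      }, max_features = min(10L, ncol(Xtr)))
    }
    pred <- baseline_fit(b, Xtr[, feat, drop = FALSE], ytr,
                         Xv[, feat, drop = FALSE], yv, seed = seed)
    labels[[b]] <- pred(Xt[, feat, drop = FALSE])
  }

  reports <- lapply(labels, function(l) compute_metrics(confusion(l, ytest)))
  mcn <- vapply(baselines, function(b)
    mcnemar_test(labels$proposed, labels[[b]], ytest)$p_value, numeric(1))
  list(table = metrics_table(reports), mcnemar = mcn, reports = reports)
}
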