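#' GMDH network settings
#'
#' @param lambda ridge penalty of the per-unit regularized least-squares
#'   solve (default 0.1).
#' @param selection_pressure fraction of best pair-units retained at each
#'   layer, in (0,1\] (default 0.7; `ceiling(selection_pressure * P)` units
#'   survive out of P candidates).
#' @param cutoff classification threshold on the unit score (default 0.5).
#' @param n_layers `"auto"` (see [n_layers_auto()]) or a positive integer.
#' @param max_pairs_per_layer cap on candidate pairs trained per layer; pairs
#'   of the most important features (by RELIEF weight at the first layer, by
#'   unit fitness later) are enumerated first.
#' @param val_fraction fraction of the training table held out as the
#'   internal validation partition when none is supplied (default 0.2, i.e.
#'   the 10%-of-total validation share of a 40/10/50 design).
#' @return A `gmdh_control` list.
#' @export
gmdh_control <- function(lambda = 0.1, selection_pressure = 0.7, cutoff = 0.5,
                         n_layers = "auto", max_pairs_per_layer = 200L,
                         val_fraction = 0.2) {
  stopifnot(lambda > 0, selection_pressure > 0, selection_pressure <= 1,
            max_pairs_per_layer >= 1L, val_fraction > 0, val_fraction < 1)
  if (!identical(n_layers, "auto")) stopifnot(n_layers >= 1L)
  structure(list(lambda = lambda, selection_pressure = selection_pressure,
                 cutoff = cutoff, n_layers = n_layers,
                 max_pairs_per_layer = as.integer(max_pairs_per_layer),
                 val_fraction = val_fraction),
            class = "gmdh_control")
}

#' Automatic layer-count rule
#'
#' The network depth is tied to the number of available inputs:
#' `1 + round(log2(Ni + Nd))` with round-half-to-even, where `Ni` is the
#' interval-feature count and `Nd` the indicator count of the predictor
#' matrix.
#'
#' @param Ni,Nd non-negative integer counts, `Ni + Nd >= 1`.
#' @return Integer number of layers (>= 1).
#' @export
n_layers_auto <- function(Ni, Nd) {
  np <- Ni + Nd
  if (np < 1) stop("Ni + Nd must be at least 1")
  max(1L, as.integer(1 + round(log2(np))))
}

#' Imbalance-aware unit fitness
#'
#' Mean of sensitivity, specificity and precision of the predicted labels —
#' the selection criterion of every network unit, chosen so that majority-
#' class collapse scores poorly even on imbalanced validation data. Precision
#' is defined as 0 when nothing is predicted positive.
#'
#' @param predicted,truth 0/1 label vectors of equal length; `truth` must
#'   contain both classes.
#' @return Fitness in \[0,1\].
#' @export
fitness_mean_se_sp_pr <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (length(unique(truth)) < 2L) stop("truth must contain both classes")
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
  mean(c(se, sp, pr))
}

#' Train one pair-unit
#'
#' Tunes the 14 nonlinear basis coefficients of the pair `(i, j)` by particle
#' swarm optimization. For every candidate coefficient vector the unit
#' weights `W` are solved in closed form by ridge regression on the
#' estimation partition, and the fitness (mean of Se, Sp, Pr at the cutoff)
#' is measured on the disjoint validation partition — the convex inner solve
#' inside the stochastic outer search.
#'
#' @param i,j predictor column indices, `i != j`.
#' @param Xe,ye estimation feature matrix (entries in \[0,1\]) and 0/1
#'   labels.
#' @param Xv,yv validation features and labels.
#' @param control a [gmdh_control()].
#' @param pso a [pso_control()].
#' @param seed integer seed for the swarm (fixed seed gives an identical
#'   unit).
#' @return A `pair_unit`: `i`, `j`, `a` (basis coefficients), `W` (ridge
#'   weights), `fitness` (validation), `layer`.
#' @export
train_pair <- function(i, j, Xe, ye, Xv, yv, control = gmdh_control(),
                       pso = pso_control(), seed = NULL) {
  stopifnot(i != j, max(i, j) <= ncol(Xe), ncol(Xe) == ncol(Xv))
  bb <- basis_bounds()
  xe_i <- Xe[, i]; xe_j <- Xe[, j]
  xv_i <- Xv[, i]; xv_j <- Xv[, j]
  obj <- function(a) {
    W <- rls_solve(basis_matrix(xe_i, xe_j, a), ye, control$lambda)
    sv <- clip01(drop(crossprod(basis_matrix(xv_i, xv_j, a), W)))
    fitness_mean_se_sp_pr(as.integer(sv >= control$cutoff), yv)
  }
  res <- pso_maximize(obj, bb$lower, bb$upper, pso, seed)
  a <- res$par
  W <- rls_solve(basis_matrix(xe_i, xe_j, a), ye, control$lambda)
  structure(list(i = as.integer(i), j = as.integer(j), a = a, W = W,
                 fitness = res$value, layer = NA_integer_),
            class = "pair_unit")
}

#' Score a pair-unit on a feature matrix
#'
#' Evaluates `X' W` for the unit's basis on the given features and clips the
#' score to \[0,1\] (so unit outputs can be reused as inputs of the next
#' layer). Class labels follow from `score >= cutoff`.
#'
#' @param unit a `pair_unit`.
#' @param features numeric matrix whose columns the unit's `(i, j)` index.
#' @return Numeric score vector in \[0,1\].
#' @export
unit_output <- function(unit, features) {
  stopifnot(inherits(unit, "pair_unit"))
  if (max(unit$i, unit$j) > ncol(features)) stop("pair indices out of range")
  clip01(drop(crossprod(
    basis_matrix(features[, unit$i], features[, unit$j], unit$a), unit$W)))
}

# enumerate pairs of 1..P in lexicographic order, capped
pair_grid <- function(P, cap) {
  pr <- utils::combn(P, 2L)
  if (ncol(pr) > cap) pr <- pr[, seq_len(cap), drop = FALSE]
  pr
}

#' Fit the optimized GMDH classifier
#'
#' The full pipeline on a mixed-type cohort:
#' \enumerate{
#'   \item split the training table into estimation and validation partitions
#'     (stratified; skipped when `validation` is supplied);
#'   \item fit the predictor mapping (robust Z + indicator/logit) on the
#'     training data and map both partitions into \[0,1\];
#'   \item weight predictors by I-RELIEF and keep those above the mean weight
#'     (at least two);
#'   \item reduce the estimation-partition majority class by PSS (the
#'     validation partition keeps its natural imbalance so the fitness stays
#'     representative);
#'   \item grow the layered network: every feature pair of a layer is trained
#'     by [train_pair()], the best `ceiling(selection_pressure * P)` units
#'     survive, and their clipped outputs become the next layer's features;
#'   \item the best unit of the final layer is the output unit.
#' }
#' If a layer is left with a single feature before the target depth is
#' reached, the network stops growing at that point (its single unit is
#' already the layer's best); the first layer must offer at least one pair.
#'
#' @param x a `cohort`: the training table (or the estimation partition when
#'   `validation` is given).
#' @param validation optional `cohort` used as the validation partition.
#' @param control a [gmdh_control()].
#' @param pso a [pso_control()] for the per-unit coefficient search.
#' @param kernel_width I-RELIEF kernel width.
#' @param use_pss logical: apply majority-class selective sampling to the
#'   estimation partition.
#' @param distance_quantile PSS keep quantile.
#' @param seed integer master seed: drives the internal split, feature
#'   weighting order and every per-unit swarm. The same seed reproduces the
#'   fit exactly.
#' @return A `gmdh` model object with `print`, `summary`, `coef`, `predict`,
#'   `plot` and `residuals` methods.
#' @examples
#' coh <- generate_separable(n = 120, imbalance_ratio = 2, n_informative = 2,
#'                           n_noise = 1, seed = 7)
#' fit <- gmdh_fit(coh, control = gmdh_control(n_layers = 1),
#'                 pso = pso_control(swarm_size = 8, max_iter = 3), seed = 7)
#' predict(fit, coh)[1:5]
#' @export
gmdh_fit <- function(x, validation = NULL, control = gmdh_control(),
                     pso = pso_control(), kernel_width = 2, use_pss = TRUE,
                     distance_quantile = 0.75, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  cl <- match.call()

  if (is.null(validation)) {
    y <- class_labels(x)
    idx <- stratified_partition(y, c(1 - control$val_fraction, control$val_fraction),
                                seed, TRUE)
    est <- x[idx[[1L]]]; val <- x[idx[[2L]]]
    train <- x
  } else {
    est <- x; val <- validation
    train <- x
    train$data <- rbind(est$data, val$data)
  }
  ye <- class_labels(est); yv <- class_labels(val)
  if (length(unique(ye)) < 2L || length(unique(yv)) < 2L)
    stop("both classes must be present in the estimation and validation partitions")

  map <- predictor_map(train)
  Fe <- build_predictors(map, est)
  Fv <- build_predictors(map, val)
  if (ncol(Fe) < 2L) stop("need at least 2 predictors after mapping")

  Ft <- rbind(Fe, Fv)
  yt <- c(ye, yv)
  weights <- irelief(Ft, yt, kernel_width = kernel_width)
  sel <- select_by_weight(weights)              # descending weight order
  if (length(sel) < 2L) sel <- select_by_weight(weights, "top_k", k = 2L)

  pss_result <- NULL
  Xe <- Fe[, sel, drop = FALSE]
  if (use_pss && length(unique(ye)) == 2L) {
    pss_result <- pss(Xe, ye, distance_quantile = distance_quantile, seed = seed)
    Xe <- Xe[pss_result$index, , drop = FALSE]
    ye_fit <- ye[pss_result$index]
  } else {
    ye_fit <- ye
  }
  Xv <- Fv[, sel, drop = FALSE]

  L <- if (identical(control$n_layers, "auto"))
    n_layers_auto(attr(Fe, "Ni"), attr(Fe, "Nd")) else as.integer(control$n_layers)

  layers <- list()
  layer_best <- numeric()
  cur_e <- Xe; cur_v <- Xv
  for (layer in seq_len(L)) {
    P <- ncol(cur_e)
    if (P < 2L) {
      if (layer == 1L) stop("fewer than 2 features at the first layer")
      break  # single surviving unit: network cannot deepen further
    }
    pairs <- pair_grid(P, control$max_pairs_per_layer)
    units <- vector("list", ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      u <- train_pair(pairs[1L, k], pairs[2L, k], cur_e, ye_fit, cur_v, yv,
                      control, pso,
                      seed = (seed * 1009L + layer * 131L + k) %% 2147483647L)
      u$layer <- layer
      units[[k]] <- u
    }
    fit_vals <- vapply(units, `[[`, 0, "fitness")
    ii <- vapply(units, `[[`, 0L, "i"); jj <- vapply(units, `[[`, 0L, "j")
    ord <- order(-fit_vals, ii, jj)
    n_keep <- ceiling(control$selection_pressure * length(units))
    if (n_keep < 1L) stop("selection pressure keeps zero units")
    kept <- units[ord[seq_len(n_keep)]]
    layers[[layer]] <- kept
    layer_best <- c(layer_best, kept[[1L]]$fitness)

    cur_e <- vapply(kept, unit_output, numeric(nrow(cur_e)), features = cur_e)
    cur_v <- vapply(kept, unit_output, numeric(nrow(cur_v)), features = cur_v)
    if (!is.matrix(cur_e)) cur_e <- matrix(cur_e, nrow = 1L)
    if (!is.matrix(cur_v)) cur_v <- matrix(cur_v, nrow = 1L)
  }

  structure(list(call = cl,
                 schema = train$schema,
                 map = map,
                 weights = weights,
                 selected = sel,
                 feature_names = colnames(Fe)[sel],
                 pss = pss_result,
                 layers = layers,
                 n_layers = length(layers),
                 layer_best = layer_best,
                 control = control,
                 pso = pso,
                 seed = seed,
                 train = train),
            class = "gmdh")
}

# propagate a predictor matrix through the layers; returns final-layer outputs
gmdh_propagate <- function(object, features) {
  cur <- features
  for (kept in object$layers) {
    cur <- vapply(kept, unit_output, numeric(nrow(cur)), features = cur)
    if (!is.matrix(cur)) cur <- matrix(cur, nrow = 1L)
  }
  cur
}

#' Predict method for GMDH models
#'
#' Applies the stored preprocessing states (no refitting), propagates the
#' \[0,1\] predictors through the network layers and thresholds the output
#' unit's score at the configured cutoff.
#'
#' @param object a fitted `gmdh` model.
#' @param newdata a `cohort` with the training schema.
#' @param type `"label"` (0/1, default) or `"score"` (the output unit's
#'   continuous score in \[0,1\]).
#' @param ... unused.
#' @return Integer labels or numeric scores, one per row of `newdata`.
#' @export
predict.gmdh <- function(object, newdata, type = c("label", "score"), ...) {
  type <- match.arg(type)
  F0 <- build_predictors(object$map, newdata)[, object$selected, drop = FALSE]
  score <- gmdh_propagate(object, F0)[, 1L]  # units kept in fitness order
  if (type == "score") score else as.integer(score >= object$control$cutoff)
}

#' @export
print.gmdh <- function(x, ...) {
  cat("Optimized GMDH classifier\n")
  cat("  predictors: ", length(x$selected), " selected of ",
      x$map$Ni + x$map$Nd, " (Ni=", x$map$Ni, ", Nd=", x$map$Nd, ")\n", sep = "")
  cat("  layers:", x$n_layers, " units/layer:",
      paste(lengths(x$layers), collapse = ", "), "\n")
  cat(sprintf("  validation fitness (mean Se/Sp/Pr): %.4f\n",
              x$layer_best[length(x$layer_best)]))
  invisible(x)
}

#' @export
summary.gmdh <- function(object, ...) {
  out_unit <- object$layers[[object$n_layers]][[1L]]
  s <- list(n_layers = object$n_layers,
            units_per_layer = lengths(object$layers),
            layer_best = object$layer_best,
            selected = object$feature_names,
            weights = object$weights$w[object$selected],
            pss_kept = if (!is.null(object$pss)) length(object$pss$kept) else NA,
            pss_removed = if (!is.null(object$pss)) length(object$pss$removed) else NA,
            output_fitness = out_unit$fitness,
            control = object$control)
  class(s) <- "summary.gmdh"
  s
}

#' @export
print.summary.gmdh <- function(x, ...) {
  cat("Optimized GMDH classifier\n\nSelected predictors (I-RELIEF weight):\n")
  for (k in seq_along(x$selected))
    cat(sprintf("  %-28s %.4f\n", x$selected[k], x$weights[k]))
  if (!is.na(x$pss_kept))
    cat("\nPSS: kept", x$pss_kept, "majority samples, removed", x$pss_removed, "\n")
  cat("\nLayer progression (best validation fitness):\n")
  for (l in seq_along(x$layer_best))
    cat(sprintf("  layer %d: %d unit(s), best fitness %.4f\n",
                l, x$units_per_layer[l], x$layer_best[l]))
  cat(sprintf("\nOutput unit fitness: %.4f (cutoff %.2f)\n",
              x$output_fitness, x$control$cutoff))
  invisible(x)
}

#' @export
coef.gmdh <- function(object, ...) {
  u <- object$layers[[object$n_layers]][[1L]]
  c(stats::setNames(u$a, paste0("a", 1:14)),
    stats::setNames(u$W, paste0("W", seq_along(u$W))))
}

#' @export
residuals.gmdh <- function(object, ...) {
  class_labels(object$train) - predict(object, object$train, type = "score")
}

#' @export
plot.gmdh <- function(x, ...) {
  fits <- lapply(x$layers, function(l) vapply(l, `[[`, 0, "fitness"))
  plot(NA, xlim = c(0.5, length(fits) + 0.5), ylim = c(0, 1),
       xlab = "layer", ylab = "validation fitness (mean Se/Sp/Pr)",
       main = "GMDH layer progression", xaxt = "n", ...)
  graphics::axis(1, at = seq_along(fits))
  for (l in seq_along(fits))
    graphics::points(rep(l, length(fits[[l]])), fits[[l]], pch = 1, col = "grey50")
  graphics::lines(seq_along(fits), x$layer_best, type = "b", pch = 19)
  invisible(x)
}
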