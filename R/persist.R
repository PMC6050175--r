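# JSON persistence of fitted GMDH models

#' Persist a fitted GMDH model as JSON
#'
#' Writes everything needed for prediction — schema, preprocessing states,
#' selected predictors, layers with basis coefficients and ridge weights —
#' to a plain-text JSON file. `read_gmdh()` reconstructs a model whose
#' `predict()` agrees with the in-memory fit (numbers survive the round trip
#' at full double precision). The training table is not persisted, so
#' `residuals()` is only available on the in-memory fit.
#'
#' @param object a fitted `gmdh` model.
#' @param path output file path.
#' @return `write_gmdh()` returns `path` invisibly; `read_gmdh()` a `gmdh`
#'   model.
#' @export
write_gmdh <- function(object, path) {
  stopifnot(inherits(object, "gmdh"))
  ser_unit <- function(u) list(i = u$i, j = u$j, a = u$a, W = u$W,
                               fitness = u$fitness, layer = u$layer)
  payload <- list(
    package = "gmdhx",
    schema = lapply(unclass(object$schema), function(f)
      list(name = f$name, kind = f$kind,
           categories = as.character(f$categories), role = f$role)),
    map = list(
      interval = lapply(object$map$interval, unclass),
      indicator_cols = object$map$indicator_cols,
      indicator_map = object$map$indicator_map,
      logit = lapply(object$map$logit, unclass),
      impute = object$map$impute,
      Ni = object$map$Ni, Nd = object$map$Nd),
    weights = object$weights$w,
    selected = object$selected,
    feature_names = object$feature_names,
    layers = lapply(object$layers, function(l) lapply(l, ser_unit)),
    layer_best = object$layer_best,
    control = unclass(object$control),
    pso = unclass(object$pso),
    seed = object$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gmdh
#' @export
read_gmdh <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  schema <- cohort_schema(p$schema)
  map <- structure(list(
    schema = schema,
    interval = lapply(p$map$interval, function(s)
      structure(s, class = "interval_map")),
    indicator_map = p$map$indicator_map,
    indicator_cols = unlist(p$map$indicator_cols),
    logit = lapply(p$map$logit, function(s)
      structure(s, class = "indicator_map")),
    impute = p$map$impute,
    Ni = p$map$Ni, Nd = p$map$Nd), class = "predictor_map")
  layers <- lapply(p$layers, function(l) lapply(l, function(u)
    structure(list(i = as.integer(u$i), j = as.integer(u$j),
                   a = as.numeric(u$a), W = as.numeric(u$W),
                   fitness = u$fitness, layer = as.integer(u$layer)),
              class = "pair_unit")))
  structure(list(call = quote(read_gmdh()),
                 schema = schema,
                 map = map,
                 weights = structure(list(w = as.numeric(p$weights),
                                          iterations = NA, converged = NA),
                                     class = "feature_weights"),
                 selected = as.integer(p$selected),
                 feature_names = unlist(p$feature_names),
                 pss = NULL,
                 layers = layers,
                 n_layers = length(layers),
                 layer_best = as.numeric(p$layer_best),
                 control = do.call(gmdh_control, p$control[
                   c("lambda", "selection_pressure", "cutoff", "n_layers",
                     "max_pairs_per_layer", "val_fraction")]),
                 pso = do.call(pso_control, p$pso[
                   c("swarm_size", "max_iter", "inertia", "c1", "c2")]),
                 seed = p$seed,
                 train = NULL),
            class = "gmdh")
}
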