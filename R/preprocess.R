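#' Robust Z-score map for interval features
#'
#' Fits the location/scale state of the robust Z transform on training values:
#' the feature median and MAD (raw median absolute deviation, no consistency
#' factor — the subsequent min-max rescale makes any constant scale factor
#' immaterial), plus the post-Z minimum and maximum used to rescale onto
#' \[0,1\].
#'
#' @param x numeric training values (>= 2 distinct values).
#' @return An `interval_map` state: `median`, `mad`, `zmin`, `zmax`.
#' @export
fit_robust_z <- function(x) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 2L) stop("constant interval feature: MAD is zero")
  med <- stats::median(x)
  mad_ <- stats::median(abs(x - med))
  if (mad_ == 0) stop("constant interval feature: MAD is zero")
  z <- (x - med) / mad_
  structure(list(median = med, mad = mad_, zmin = min(z), zmax = max(z)),
            class = "interval_map")
}

#' @rdname fit_robust_z
#' @param state a fitted `interval_map`.
#' @details `apply_robust_z()` maps new values through the stored transform
#'   and clips to \[0,1\]; training values attain both endpoints, values
#'   outside the training range are clipped.
#' @export
apply_robust_z <- function(x, state) {
  stopifnot(inherits(state, "interval_map"))
  z <- (x - state$median) / state$mad
  clip01((z - state$zmin) / (state$zmax - state$zmin))
}

#' One-hot indicator expansion of categorical features
#'
#' Every category of every nominal/ordinal feature becomes a 0/1 indicator
#' column; within a feature the indicators of one row sum to 1 (complete
#' one-hot; ordinal features are expanded the same way as nominal ones).
#'
#' @param x a `cohort`, or a data frame with a `schema` attribute supplied via
#'   the `schema` argument.
#' @param schema optional `cohort_schema` when `x` is a plain data frame.
#' @param features which categorical features to expand (default: all
#'   predictor-role categorical features).
#' @return Numeric 0/1 matrix with columns named `feature=category` and a
#'   `"map"` attribute listing (feature, category) per column. Missing cells
#'   give NA across the feature's indicators.
#' @export
expand_indicators <- function(x, schema = NULL, features = NULL) {
  if (inherits(x, "cohort")) { schema <- x$schema; df <- x$data }
  else { stopifnot(inherits(schema, "cohort_schema")); df <- x }
  cats <- Filter(function(f) f$kind != "interval" && f$role == "predictor", schema)
  if (!is.null(features)) cats <- cats[names(cats) %in% features]
  cols <- list(); map <- list()
  for (f in cats) {
    v <- df[[f$name]]
    for (cg in f$categories) {
      cols[[paste0(f$name, "=", cg)]] <- ifelse(is.na(v), NA_real_, as.numeric(v == cg))
      map[[length(map) + 1L]] <- c(feature = f$name, category = cg)
    }
  }
  out <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(), nrow = nrow(df), ncol = 0L)
  attr(out, "map") <- map
  out
}

#' Univariate logit map for a binary indicator
#'
#' Maximum-likelihood logistic regression of the class on a single 0/1
#' indicator. The MLE has the closed two-cell form: `plogis(b0)` is the
#' observed positive rate at indicator 0 and `plogis(b0 + b1)` the rate at
#' indicator 1. Under complete separation (or an empty cell) Jeffreys-style
#' 0.5 pseudo-counts are added to the 2x2 cells so the coefficients stay
#' finite and deterministic.
#'
#' @param indicator 0/1 indicator values (training rows).
#' @param y 0/1 class labels, same length.
#' @return An `indicator_map` state: `b0` (intercept, log-odds), `b1` (slope),
#'   `penalized` flag.
#' @export
fit_logit_map <- function(indicator, y) {
  stopifnot(length(indicator) == length(y))
  keep <- !is.na(indicator) & !is.na(y)
  indicator <- indicator[keep]; y <- y[keep]
  stopifnot(is_binary01(indicator), is_binary01(y))
  n0 <- sum(indicator == 0); n1 <- sum(indicator == 1)
  k0 <- sum(y[indicator == 0]); k1 <- sum(y[indicator == 1])
  penalized <- n0 == 0 || n1 == 0 || k0 == 0 || k0 == n0 || k1 == 0 || k1 == n1
  if (penalized) {
    p0 <- (k0 + 0.5) / (n0 + 1); p1 <- (k1 + 0.5) / (n1 + 1)
  } else {
    p0 <- k0 / n0; p1 <- k1 / n1
  }
  b0 <- stats::qlogis(p0)
  structure(list(b0 = b0, b1 = stats::qlogis(p1) - b0, penalized = penalized),
            class = "indicator_map")
}

#' @rdname fit_logit_map
#' @param state a fitted `indicator_map`.
#' @details `apply_logit_map()` returns `plogis(b0 + b1 * x)`, a value in
#'   (0,1).
#' @export
apply_logit_map <- function(indicator, state) {
  stopifnot(inherits(state, "indicator_map"))
  stats::plogis(state$b0 + state$b1 * indicator)
}

#' Fit the full mixed-type predictor mapping
#'
#' Learns, on the training partition only, everything needed to turn a
#' mixed-type cohort into an all-continuous predictor matrix with entries in
#' \[0,1\]: robust Z-score states for the `Ni` interval features, one-hot
#' indicator expansion plus per-indicator logit maps for the `Nd` indicator
#' columns of the categorical features, and imputation values (training median
#' for interval, training mode for categorical). Constant interval features
#' (zero MAD) are dropped with a warning.
#'
#' @param train a `cohort`: the training partition (estimation + validation).
#' @return A `predictor_map` with components `interval` (named
#'   `interval_map`s), `indicators` (column map), `logit` (named
#'   `indicator_map`s), `impute`, `Ni`, `Nd`.
#' @seealso [build_predictors()]
#' @export
predictor_map <- function(train) {
  stopifnot(inherits(train, "cohort"))
  y <- class_labels(train)
  schema <- train$schema
  ints <- Filter(function(f) f$kind == "interval" && f$role == "predictor", schema)

  interval_states <- list(); impute <- list()
  for (f in ints) {
    v <- train$data[[f$name]]
    st <- tryCatch(fit_robust_z(v), error = function(e) NULL)
    if (is.null(st)) {
      warning("dropping constant interval feature '", f$name, "'")
      next
    }
    interval_states[[f$name]] <- st
    impute[[f$name]] <- stats::median(v, na.rm = TRUE)
  }

  cats <- Filter(function(f) f$kind != "interval" && f$role == "predictor", schema)
  for (f in cats) {
    v <- train$data[[f$name]]
    tab <- table(v[!is.na(v)])
    impute[[f$name]] <- if (length(tab)) names(tab)[which.max(tab)] else f$categories[1L]
  }

  ind <- expand_indicators(train)
  logit_states <- list()
  for (j in seq_len(ncol(ind))) {
    logit_states[[colnames(ind)[j]]] <- fit_logit_map(ind[, j], y)
  }

  structure(list(schema = schema,
                 interval = interval_states,
                 indicator_map = attr(ind, "map"),
                 indicator_cols = colnames(ind),
                 logit = logit_states,
                 impute = impute,
                 Ni = length(interval_states),
                 Nd = ncol(ind)),
            class = "predictor_map")
}

#' Build the predictor matrix of a cohort under a fitted mapping
#'
#' Applies stored states only — no statistic of `newdata` is re-estimated, so
#' test rows cannot leak into the mapping. Missing cells are imputed with the
#' stored training median/mode before transformation.
#'
#' @param map a [predictor_map()].
#' @param newdata a `cohort` with the same schema.
#' @return Numeric n x Np matrix, all entries in \[0,1\]; interval columns
#'   first, then logit-mapped indicator columns. Attributes `Ni` and `Nd`
#'   carry the interval/indicator column counts.
#' @export
build_predictors <- function(map, newdata) {
  stopifnot(inherits(map, "predictor_map"), inherits(newdata, "cohort"))
  df <- newdata$data
  n <- nrow(df)
  blocks <- list()

  for (nm in names(map$interval)) {
    v <- df[[nm]]
    if (is.null(v)) stop("schema mismatch: missing interval feature '", nm, "'")
    v[is.na(v)] <- map$impute[[nm]]
    blocks[[nm]] <- apply_robust_z(v, map$interval[[nm]])
  }

  if (map$Nd > 0L) {
    dfi <- df
    for (f in Filter(function(f) f$kind != "interval" && f$role == "predictor",
                     map$schema)) {
      v <- dfi[[f$name]]
      v[is.na(v)] <- map$impute[[f$name]]
      dfi[[f$name]] <- v
    }
    ind <- expand_indicators(dfi, schema = map$schema)
    if (!identical(colnames(ind), map$indicator_cols))
      stop("schema mismatch: indicator columns differ from the fitted mapping")
    for (j in seq_along(map$indicator_cols)) {
      nm <- map$indicator_cols[j]
      blocks[[nm]] <- apply_logit_map(ind[, j], map$logit[[nm]])
    }
  }

  out <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(), nrow = n, ncol = 0L)
  attr(out, "Ni") <- map$Ni
  attr(out, "Nd") <- map$Nd
  out
}
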