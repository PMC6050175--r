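# shared fixture builders (everything is generated in code; no data files)

toy_schema <- function() {
  cohort_schema(
    feature_schema("sex", "nominal", c("male", "female")),
    feature_schema("rs320", "nominal", c("TT", "GT", "GG")),
    feature_schema("age", "interval"),
    feature_schema("class", "nominal", c("no", "yes"), role = "class"))
}

toy_cohort <- function(n = 40, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    sex = sample(c("male", "female"), n, TRUE),
    rs320 = sample(c("TT", "GT", "GG"), n, TRUE),
    age = round(stats::rnorm(n, 14, 2), 2),
    class = rep(c("no", "yes"), length.out = n))
  cohort(df, toy_schema())
}

# balanced two-class cohort with one informative interval pair
small_separable <- function(n = 100, seed = 1) {
  generate_separable(n = n, imbalance_ratio = 1, n_informative = 2,
                     n_noise = 1, seed = seed)
}

# a [0,1] predictor matrix + labels without any cohort plumbing
toy_predictors <- function(n = 60, p = 3, seed = 1, signal = TRUE) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(runif(n * p), n, p)
  if (signal) X[, 1] <- clip01(0.8 * y + 0.1 + rnorm(n, 0, 0.05))
  list(X = X, y = y)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo); expect_lte(x, hi)
}
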