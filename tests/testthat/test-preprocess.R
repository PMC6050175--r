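test_that("robust Z map fits median/MAD and rescales training data onto [0,1]", {
  st <- fit_robust_z(c(1, 2, 3, 4, 5))
  expect_equal(st$median, 3)
  expect_equal(st$mad, 1)
  expect_error(fit_robust_z(c(1, 1, 1)), "MAD is zero")

  # affine case: [0,5,10] maps to [0,.5,1]
  st2 <- fit_robust_z(c(0, 5, 10))
  expect_equal(apply_robust_z(c(0, 5, 10), st2), c(0, 0.5, 1))
  # clipping below/above the training range
  expect_equal(apply_robust_z(c(-100, 100), st2), c(0, 1))
})

test_that("robust Z recovers location/scale of a normal sample", {
  set.seed(7)
  x <- rnorm(200, mean = 10, sd = 4)
  # brute-force oracle: definitions computed directly
  med_o <- sort(x)[100:101]; med_o <- mean(med_o)
  mad_o <- stats::median(abs(x - med_o))
  st <- fit_robust_z(x)
  expect_equal(st$median, med_o)
  expect_equal(st$mad, mad_o)
  expect_lt(abs(st$median - 10), 1.2)
  expect_lt(abs(st$mad - 4 * 0.6745), 0.8)  # raw MAD of N(10,4)
})

test_that("robust Z is invertible on interior points", {
  set.seed(8)
  x <- runif(50, -3, 3)
  st <- fit_robust_z(x)
  y <- apply_robust_z(x, st)
  # algebraic inverse for non-clipped values
  inv <- (y * (st$zmax - st$zmin) + st$zmin) * st$mad + st$median
  expect_equal(inv, x, tolerance = 1e-12)
})

test_that("indicator expansion is a complete one-hot per feature", {
  coh <- toy_cohort(10)
  ind <- expand_indicators(coh)
  expect_equal(ncol(ind), 2L + 3L)  # sex (2) + rs320 (3)
  sex_cols <- grep("^sex=", colnames(ind))
  rs_cols <- grep("^rs320=", colnames(ind))
  expect_true(all(rowSums(ind[, sex_cols]) == 1))
  expect_true(all(rowSums(ind[, rs_cols]) == 1))
  expect_true(all(ind %in% c(0, 1)))
})

test_that("logit map equals the analytic two-cell MLE and an independent fit", {
  # exact counts: P(y=1|0) = 0.25 on 20 rows, P(y=1|1) = 0.75 on 20 rows
  ind <- rep(c(0, 1), each = 20)
  y <- c(rep(c(1, 0), c(5, 15)), rep(c(1, 0), c(15, 5)))
  st <- fit_logit_map(ind, y)
  expect_false(st$penalized)
  expect_equal(plogis(st$b0), 0.25, tolerance = 1e-6)
  expect_equal(plogis(st$b0 + st$b1), 0.75, tolerance = 1e-6)

  # independent oracle: full logistic MLE via glm on a non-degenerate sample
  set.seed(5)
  ind2 <- rbinom(80, 1, 0.5)
  y2 <- rbinom(80, 1, 0.3 + 0.4 * ind2)
  st2 <- fit_logit_map(ind2, y2)
  g <- glm(y2 ~ ind2, family = binomial())
  expect_equal(unname(st2$b0), unname(coef(g)[1]), tolerance = 1e-6)
  expect_equal(unname(st2$b1), unname(coef(g)[2]), tolerance = 1e-6)
})

test_that("class-independent indicator gives zero slope", {
  ind <- rep(c(0, 1), each = 20)
  y <- rep(c(1, 0, 1, 0), each = 10)  # rate 0.5 at both levels
  st <- fit_logit_map(ind, y)
  expect_equal(st$b1, 0, tolerance = 1e-6)
})

test_that("complete separation yields finite penalized coefficients", {
  ind <- rep(c(0, 1), each = 10)
  y <- ind  # indicator predicts class perfectly
  st <- fit_logit_map(ind, y)
  expect_true(st$penalized)
  expect_true(all(is.finite(c(st$b0, st$b1))))
  out <- apply_logit_map(c(0, 1), st)
  expect_true(all(out > 0 & out < 1))
})

test_that("apply_logit_map follows the sigmoid definition and monotonicity", {
  st0 <- structure(list(b0 = 0, b1 = 0), class = "indicator_map")
  expect_equal(apply_logit_map(c(0, 1, 1), st0), rep(0.5, 3))
  st <- structure(list(b0 = -0.4, b1 = 1.3), class = "indicator_map")
  expect_equal(apply_logit_map(0, st), plogis(-0.4))
  expect_equal(apply_logit_map(1, st), plogis(0.9))
  expect_gt(apply_logit_map(1, st), apply_logit_map(0, st))  # b1 > 0
})

test_that("predictor matrix composes interval and indicator blocks in [0,1]", {
  set.seed(9)
  n <- 30
  df <- data.frame(
    a = rnorm(n), b = rnorm(n), c = rnorm(n),                     # Ni = 3
    f1 = sample(letters[1:4], n, TRUE), f2 = sample(letters[1:4], n, TRUE),
    f3 = sample(letters[1:3], n, TRUE), f4 = sample(letters[1:2], n, TRUE),
    class = rep(c("no", "yes"), n / 2))
  sch <- cohort_schema(
    feature_schema("a", "interval"), feature_schema("b", "interval"),
    feature_schema("c", "interval"),
    feature_schema("f1", "nominal", letters[1:4]),
    feature_schema("f2", "ordinal", letters[1:4]),
    feature_schema("f3", "nominal", letters[1:3]),
    feature_schema("f4", "nominal", letters[1:2]),
    feature_schema("class", "nominal", c("no", "yes"), role = "class"))
  coh <- cohort(df, sch)
  map <- predictor_map(coh)
  F <- build_predictors(map, coh)
  expect_equal(attr(F, "Ni"), 3L)
  expect_equal(attr(F, "Nd"), 13L)  # 4+4+3+2 indicators
  expect_equal(ncol(F), 16L)        # Np = Ni + Nd
  expect_true(all(F >= 0 & F <= 1))
})

test_that("no statistic of held-out data influences the fitted mapping", {
  coh <- toy_cohort(40)
  train <- coh[1:30]
  map1 <- predictor_map(train)
  # perturbing rows outside the training partition cannot change the states
  coh$data$age[31:40] <- coh$data$age[31:40] + 1000
  map2 <- predictor_map(coh[1:30])
  expect_identical(map1[c("interval", "logit", "impute")],
                   map2[c("interval", "logit", "impute")])
  # and transforming the training data itself uses stored states only
  expect_identical(build_predictors(map1, train), build_predictors(map2, train))
})

test_that("missing predictor cells are imputed from training statistics", {
  coh <- toy_cohort(40)
  map <- predictor_map(coh)
  holed <- coh[1:5]
  holed$data$age[2] <- NA
  holed$data$sex[3] <- NA
  F <- build_predictors(map, holed)
  expect_true(all(is.finite(F)))
})
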