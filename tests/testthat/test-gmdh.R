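test_that("the automatic layer rule follows 1 + round(log2(Np))", {
  expect_equal(n_layers_auto(3, 13), 5L)   # 16 inputs
  expect_equal(n_layers_auto(1, 0), 1L)
  expect_equal(n_layers_auto(0, 3), 3L)    # 1 + round(1.585)
  expect_equal(n_layers_auto(2, 2), 3L)
  expect_error(n_layers_auto(0, 0), "at least 1")
})

test_that("unit fitness is the mean of Se, Sp and Pr", {
  expect_equal(fitness_mean_se_sp_pr(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # TP=93 FN=7 TN=95 FP=5
  pred <- c(rep(1, 93), rep(0, 7), rep(0, 95), rep(1, 5))
  truth <- c(rep(1, 100), rep(0, 100))
  expect_equal(fitness_mean_se_sp_pr(pred, truth),
               mean(c(0.93, 0.95, 93 / 98)))
  # all-positive prediction on prevalence-0.4 data
  truth2 <- rep(c(1, 0, 0, 0, 1), 20)
  expect_equal(fitness_mean_se_sp_pr(rep(1, 100), truth2),
               mean(c(1, 0, 0.4)))
  # nothing predicted positive: precision defined as 0
  expect_equal(fitness_mean_se_sp_pr(rep(0, 100), truth2),
               mean(c(0, 1, 0)))
  expect_error(fitness_mean_se_sp_pr(rep(1, 4), rep(1, 4)), "both classes")
})

test_that("a pair carrying the class label exactly is fit to fitness 1", {
  set.seed(41)
  n <- 80
  y <- rep(0:1, n / 2)
  X <- cbind(y, runif(n))
  u <- train_pair(1, 2, X[1:60, ], y[1:60], X[61:n, ], y[61:n], seed = 41)
  expect_equal(u$fitness, 1)
  expect_equal(as.integer(unit_output(u, X) >= 0.5), y)
})

test_that("pure-noise pairs stay near chance fitness", {
  fits <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    n <- 200
    y <- rep(0:1, n / 2)
    X <- matrix(runif(n * 2), n, 2)
    train_pair(1, 2, X[1:120, ], y[1:120], X[121:n, ], y[121:n],
               seed = s)$fitness
  }, numeric(1))
  expect_lt(median(fits), 0.65)
})

test_that("pair training is deterministic under a fixed seed", {
  set.seed(42)
  n <- 60
  y <- rep(0:1, n / 2)
  X <- matrix(runif(n * 2), n, 2)
  u1 <- train_pair(1, 2, X[1:40, ], y[1:40], X[41:n, ], y[41:n], seed = 5)
  u2 <- train_pair(1, 2, X[1:40, ], y[1:40], X[41:n, ], y[41:n], seed = 5)
  expect_identical(u1, u2)
})

test_that("unit scores are local to the unit's pair and clip to [0,1]", {
  set.seed(43)
  X <- matrix(runif(60), 20, 3)
  u <- train_pair(1, 2, X[1:10, ], rep(0:1, 5), X[11:20, ], rep(0:1, 5),
                  seed = 1)
  s1 <- unit_output(u, X)
  X2 <- X; X2[, 3] <- runif(20)      # untouched third column is irrelevant
  expect_identical(unit_output(u, X2), s1)
  expect_true(all(s1 >= 0 & s1 <= 1))

  u0 <- u; u0$W <- rep(0, 7)
  expect_equal(unit_output(u0, X), rep(0, 20))  # all-zero weights clip to 0
  expect_error(unit_output(u, X[, 1, drop = FALSE]), "out of range")
})

test_that("layer growth follows the pair count and selection-pressure rule", {
  set.seed(44)
  n <- 60
  df <- data.frame(a = rnorm(n) + rep(0:1, n / 2), b = rnorm(n), c = rnorm(n),
                   d = rnorm(n),
                   class = rep(c("no", "yes"), n / 2))
  sch <- cohort_schema(
    feature_schema("a", "interval"), feature_schema("b", "interval"),
    feature_schema("c", "interval"), feature_schema("d", "interval"),
    feature_schema("class", "nominal", c("no", "yes"), role = "class"))
  coh <- cohort(df, sch)
  pso_small <- pso_control(swarm_size = 5, max_iter = 2)

  # force all 4 predictors through selection: threshold 0 keeps everything
  fit <- gmdh_fit(coh, control = gmdh_control(n_layers = 1), pso = pso_small,
                  kernel_width = 1e6, use_pss = FALSE, seed = 44)
  if (length(fit$selected) == 4L) {
    expect_length(fit$layers[[1]], ceiling(0.7 * choose(4, 2)))  # 5 of 6
  }

  fit_all <- gmdh_fit(coh, control = gmdh_control(n_layers = 1,
                                                  selection_pressure = 1),
                      pso = pso_small, use_pss = FALSE, seed = 44)
  P <- length(fit_all$selected)
  expect_length(fit_all$layers[[1]], choose(P, 2))  # no pruning
})

test_that("XOR interactions are captured end to end", {
  fits <- vapply(c(101, 202, 303), function(s) {
    coh <- generate_separable(n = 400, imbalance_ratio = 1, n_informative = 0,
                              n_noise = 2, interaction = TRUE, seed = s)
    fit <- gmdh_fit(coh, seed = s)
    fit$layer_best[length(fit$layer_best)]
  }, numeric(1))
  expect_true(all(fits >= 0.9))
})

test_that("prediction is consistent, permutation-equivariant and persistent", {
  coh <- small_separable(n = 120, seed = 45)
  fit <- gmdh_fit(coh, control = gmdh_control(n_layers = 2),
                  pso = pso_control(swarm_size = 8, max_iter = 4), seed = 45)

  # row permutation permutes outputs identically
  sc <- predict(fit, coh, type = "score")
  perm <- sample(seq_len(nrow(coh$data)))
  expect_equal(predict(fit, coh[perm], type = "score"), sc[perm])

  # fixed seed reproduces the fit exactly
  fit2 <- gmdh_fit(coh, control = gmdh_control(n_layers = 2),
                   pso = pso_control(swarm_size = 8, max_iter = 4), seed = 45)
  expect_equal(fit2$layers, fit$layers)

  # JSON round trip predicts identically (to numerical echo of the writer)
  path <- withr::local_tempfile(fileext = ".json")
  write_gmdh(fit, path)
  fit3 <- read_gmdh(path)
  expect_equal(predict(fit3, coh, type = "score"), sc, tolerance = 1e-12)

  # residuals are y - score on the training table
  expect_equal(residuals(fit),
               class_labels(fit$train) - predict(fit, fit$train, type = "score"))

  # coef exposes the output unit's basis coefficients and ridge weights
  cf <- coef(fit)
  expect_length(cf, 21L)
  expect_named(cf, c(paste0("a", 1:14), paste0("W", 1:7)))
})

test_that("validation fitness tends not to degrade across layers", {
  ok <- vapply(1:5, function(s) {
    coh <- generate_separable(n = 150, imbalance_ratio = 1.5,
                              n_informative = 2, n_noise = 2, seed = 700 + s)
    fit <- gmdh_fit(coh, control = gmdh_control(n_layers = 2),
                    pso = pso_control(swarm_size = 8, max_iter = 4),
                    seed = 700 + s)
    length(fit$layer_best) < 2 || diff(fit$layer_best) >= -1e-9
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("recovering data generated by a single basis unit", {
  set.seed(46)
  n <- 300
  X <- matrix(runif(n * 2), n, 2)
  bb <- basis_bounds()
  a_true <- runif(14, bb$lower, bb$upper)
  W_true <- rnorm(7, 0, 0.5)
  score <- drop(crossprod(basis_matrix(X[, 1], X[, 2], a_true), W_true))
  y <- as.integer(score >= median(score))  # balanced labels from the unit
  gen_fit <- fitness_mean_se_sp_pr(y, y)   # = 1 by construction

  df <- data.frame(x1 = X[, 1], x2 = X[, 2],
                   class = ifelse(y == 1, "yes", "no"))
  sch <- cohort_schema(
    feature_schema("x1", "interval"), feature_schema("x2", "interval"),
    feature_schema("class", "nominal", c("no", "yes"), role = "class"))
  fit <- gmdh_fit(cohort(df, sch), use_pss = FALSE, seed = 46)
  expect_gte(fit$layer_best[length(fit$layer_best)], gen_fit - 0.05)
})
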