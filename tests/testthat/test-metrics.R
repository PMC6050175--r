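test_that("the metrics battery reproduces the worked Se/Sp example", {
  m <- compute_metrics(confusion_counts(tp = 93, fp = 5, tn = 95, fn = 7))
  expect_equal(m$Se, 0.93)
  expect_equal(m$Sp, 0.95)
  expect_equal(m$LR_plus, 18.6)
  expect_equal(m$LR_minus, 0.07 / 0.95, tolerance = 1e-12)
  expect_equal(m$DOR, 252.43, tolerance = 1e-3)
  expect_equal(m$AUC, 0.94)
  expect_equal(m$DP, 1.3, tolerance = 0.03)  # (sqrt(3)/pi) log10(252.43)
})

test_that("a perfect classifier saturates every index", {
  m <- compute_metrics(confusion_counts(tp = 40, fp = 0, tn = 60, fn = 0))
  for (k in c("Se", "Sp", "Acc", "Pr", "F1S", "AUC", "MCC", "Kappa"))
    expect_equal(m[[k]], 1)
  expect_identical(m$DOR, Inf)
})

test_that("MCC equals the phi coefficient of the reconstituted labels", {
  set.seed(51)
  for (rep in 1:10) {
    cts <- rmultinom(1, 200, runif(4, 0.05, 1))
    tp <- cts[1]; fp <- cts[2]; tn <- cts[3]; fn <- cts[4]
    pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
    truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
    m <- compute_metrics(confusion_counts(tp, fp, tn, fn))
    phi <- suppressWarnings(cor(pred, truth))
    if (is.na(phi)) expect_true(is.nan(m$MCC))
    else expect_equal(m$MCC, phi, tolerance = 1e-12)
  }
})

test_that("metric identities hold for arbitrary counts", {
  set.seed(52)
  for (rep in 1:20) {
    cts <- as.list(rmultinom(1, 150, runif(4, 0.02, 1))[, 1] + 1)
    names(cts) <- c("tp", "fp", "tn", "fn")
    m <- do.call(compute_metrics, cts)
    expect_equal(m$FA + m$Sp, 1)
    expect_equal(m$Power, m$Se)
    expect_equal(m$AUC, (m$Se + m$Sp) / 2)
    expect_equal(m$DOR, m$LR_plus / m$LR_minus)
    expect_equal(m$FDR, 1 - m$Pr)
    expect_equal(m$DP, (sqrt(3) / pi) * log10(m$DOR))
  }
})

test_that("rate-derived confusion tables evaluate the identities exactly", {
  cc <- confusion_from_rates(se = 0.93, sp = 0.95, pr = 0.93)
  m <- compute_metrics(cc)
  expect_equal(m$Se, 0.93, tolerance = 1e-12)
  expect_equal(m$Sp, 0.95, tolerance = 1e-12)
  expect_equal(m$Pr, 0.93, tolerance = 1e-12)
  expect_equal(m$FDR, 0.07, tolerance = 1e-12)
  expect_equal(m$DOR, (0.93 * 0.95) / (0.07 * 0.05), tolerance = 1e-12)
})

test_that("the reliability gate applies its four inclusive thresholds", {
  near <- compute_metrics(confusion_from_rates(se = 0.93, sp = 0.95, pr = 0.93))
  g <- reliability_gate(near)
  expect_false(g$pass)
  expect_equal(names(which(!g$criteria)), "Pr")  # only precision fails

  zero <- compute_metrics(confusion_counts(tp = 0, fp = 0, tn = 0, fn = 10))
  expect_false(any(reliability_gate(zero)$criteria))
})

test_that("boundary reliability values pass inclusively", {
  # Se=.80, Sp=.95, Pr=.95, DOR=.8*.95/(.2*.05)=76 -> DOR fails alone;
  # construct DOR=100 via rates Se=.80 Sp=.9615..: use counts directly
  m <- structure(list(Se = 0.80, Sp = 0.95, Pr = 0.95, DOR = 100),
                 class = "metrics_report")
  g <- reliability_gate(m)
  expect_true(g$pass)
})

test_that("McNemar handles worked discordant configurations", {
  # b = c = 5: corrected statistic (|0|-1)^2/10, p from the exact route
  truth <- rep(0, 20)
  a <- c(rep(0, 10), rep(1, 5), rep(0, 5))
  b <- c(rep(0, 10), rep(0, 5), rep(1, 5))
  r <- mcnemar_test(a, b, truth)
  expect_equal(r$statistic, 0.1)
  expect_gt(r$p_value, 0.5)
  expect_equal(r$method, "exact binomial")

  # b = 10, c = 0: chi-square tail of 8.1
  a2 <- rep(0, 30)
  b2 <- c(rep(1, 10), rep(0, 20))
  r2 <- mcnemar_test(a2, b2, rep(0, 30), exact = "never")
  expect_equal(r2$statistic, 8.1)
  expect_equal(r2$p_value, pchisq(8.1, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(round(r2$p_value, 4), 0.0044)

  # identical classifiers
  expect_equal(mcnemar_test(a2, a2, rep(0, 30))$p_value, 1)
})

test_that("McNemar is symmetric and agrees with the library oracle", {
  set.seed(53)
  truth <- rbinom(100, 1, 0.5)
  a <- ifelse(runif(100) < 0.8, truth, 1 - truth)
  b <- ifelse(runif(100) < 0.6, truth, 1 - truth)
  r_ab <- mcnemar_test(a, b, truth, exact = "never")
  r_ba <- mcnemar_test(b, a, truth, exact = "never")
  expect_equal(r_ab$p_value, r_ba$p_value)
  expect_equal(r_ab$statistic, r_ba$statistic)

  oracle <- stats::mcnemar.test(table(factor(a == truth, c(FALSE, TRUE)),
                                      factor(b == truth, c(FALSE, TRUE))),
                                correct = TRUE)
  expect_equal(r_ab$statistic, unname(oracle$statistic))
  expect_equal(r_ab$p_value, oracle$p.value)
})

test_that("rank AUC behaves on separable and random scores", {
  truth <- rep(0:1, each = 50)
  expect_equal(roc_auc(c(runif(50, 0, 0.4), runif(50, 0.6, 1)), truth), 1)
  set.seed(54)
  expect_lt(abs(roc_auc(runif(100), truth) - 0.5), 0.2)
})

test_that("metrics tables carry the standard column set", {
  m <- compute_metrics(confusion_counts(tp = 93, fp = 5, tn = 95, fn = 7))
  tab <- metrics_table(list(proposed = m, other = m))
  expect_equal(colnames(tab),
               c("Se", "Sp", "Acc", "F1S", "Pr", "FA", "AUC", "MCC",
                 "DOR", "DP", "Kappa"))
  expect_equal(tab["proposed", "Se"], 93)

  pj <- withr::local_tempfile(fileext = ".json")
  pm <- withr::local_tempfile(fileext = ".md")
  write_metrics(list(proposed = m), pj)
  write_metrics(list(proposed = m), pm)
  expect_true(file.exists(pj) && file.exists(pm))
  expect_match(readLines(pm)[1], "\\| classifier \\| Se \\|")
})
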