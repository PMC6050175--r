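test_that("schema construction enforces the class and category contracts", {
  expect_error(feature_schema("x", "nominal", "one"), ">= 2 categories")
  expect_error(feature_schema("y", "nominal", c("a", "b", "c"), role = "class"),
               "exactly 2 categories")
  expect_error(cohort_schema(feature_schema("a", "interval"),
                             feature_schema("b", "interval")),
               "exactly one class column")
})

test_that("cohort CSV round trip is the identity and violations are located", {
  coh <- toy_cohort(n = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path, toy_schema())
  expect_equal(back$data, coh$data)
  expect_equal(dim(back), c(4L, 4L))

  # unknown genotype is rejected with row and column named
  bad <- coh$data; bad$rs320[3] <- "XY"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(bad, path2, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(path2, toy_schema()), "XY.*rs320.*3")

  # non-numeric interval cell
  bad2 <- coh$data; bad2$age <- as.character(bad2$age); bad2$age[2] <- "old"
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(bad2, path3, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(path3, toy_schema()), "age.*2")

  # missing class column
  expect_error(cohort(coh$data[, 1:3], toy_schema()), "class")
})

test_that("schema files round trip through YAML and JSON", {
  sch <- toy_schema()
  for (ext in c(".yaml", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_schema(sch, p)
    expect_equal(read_schema(p), sch)
  }
})

test_that("rows with missing class are dropped; missing tokens parse", {
  df <- toy_cohort(6)$data
  df$class[2] <- "NA"
  df$age[3] <- "."
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_warning(coh <- read_cohort(path, toy_schema()), "missing class")
  expect_equal(nrow(coh$data), 5L)
  expect_true(is.na(coh$data$age[2]))  # row 3 shifted up by the drop
})

test_that("genotype encodings merge heterozygotes and flag carriers", {
  sch <- cohort_schema(
    feature_schema("rs320", "nominal", c("TT", "TG", "GT", "GG")),
    feature_schema("class", "nominal", c("no", "yes"), role = "class"))
  coh <- cohort(data.frame(rs320 = c("TT", "TG", "GT", "GG"),
                           class = c("no", "yes", "no", "yes")), sch)

  pairs <- encode_genotypes(coh, "rs320", "pairs")
  expect_equal(pairs$data$rs320, c("TT", "GT", "GT", "GG"))  # sorted canonical
  expect_equal(pairs$schema$rs320$categories, c("TT", "GT", "GG"))

  carrier <- encode_genotypes(coh, "rs320", "carrier", minority_allele = "G")
  expect_equal(carrier$data$rs320, c("0", "1", "1", "1"))
  expect_equal(carrier$schema$rs320$categories, c("0", "1"))

  expect_error(encode_genotypes(coh, "rs320", "carrier", minority_allele = "A"),
               "absent")
})

test_that("hold-out split is stratified, exhaustive and seed-reproducible", {
  spec <- suppressMessages(dyslipidemia_spec())
  coh <- suppressMessages(generate_cohort(spec, n = 725, seed = 4))
  p <- split_holdout(coh, fractions = c(0.40, 0.10, 0.50), seed = 9)
  sizes <- vapply(p, function(s) nrow(s$data), 0L)
  expect_equal(sum(sizes), 725L)
  expect_true(all(abs(sizes - c(290, 72.5, 362.5)) <= 1))

  # stratification: partition prevalence within 1/|partition| of the whole
  prev <- mean(class_labels(coh))
  for (s in p)
    expect_lte(abs(mean(class_labels(s)) - prev), 1 / nrow(s$data))

  p2 <- split_holdout(coh, fractions = c(0.40, 0.10, 0.50), seed = 9)
  expect_identical(lapply(p2, `[[`, "data"), lapply(p, `[[`, "data"))
  p3 <- split_holdout(coh, fractions = c(0.40, 0.10, 0.50), seed = 10)
  expect_false(identical(p3$test$data, p$test$data))
})

test_that("balanced 60/15/25 split gives exact per-stratum counts", {
  coh <- small_separable(n = 100, seed = 2)  # 50/50 classes
  p <- split_holdout(coh, fractions = c(0.60, 0.15, 0.25), seed = 1)
  expect_equal(vapply(p, function(s) nrow(s$data), 0L),
               c(estimation = 60L, validation = 15L, test = 25L))
  # per class: enumerated stratified allocation of 50 into (30, 7.5, 12.5)
  ycounts <- vapply(p, function(s) sum(class_labels(s) == 1), 0L)
  expect_equal(ycounts[["estimation"]], 30L)
  expect_true(all(abs(ycounts - c(30, 7.5, 12.5)) <= 0.5))
})

test_that("cv folds tile the table exactly once with near-equal test sizes", {
  coh <- small_separable(n = 100, seed = 3)
  folds <- make_cv_folds(coh, k = 4, seed = 11)
  expect_length(folds, 4L)
  tests <- lapply(folds, function(f) f$test$data)
  expect_equal(vapply(tests, nrow, 0L), rep(25L, 4L))
  all_rows <- do.call(rbind, tests)
  expect_equal(nrow(unique(all_rows)), 100L)  # disjoint + exhaustive

  # n = 725: near-equal integer partition of the test partitions
  spec <- suppressMessages(dyslipidemia_spec())
  big <- suppressMessages(generate_cohort(spec, n = 725, seed = 4))
  sizes <- sort(vapply(make_cv_folds(big, k = 4, seed = 1),
                       function(f) nrow(f$test$data), 0L), decreasing = TRUE)
  expect_equal(sizes, c(182L, 181L, 181L, 181L))

  f1 <- make_cv_folds(coh, k = 4, seed = 11)
  expect_identical(lapply(f1, function(f) f$test$data),
                   lapply(folds, function(f) f$test$data))
  expect_error(make_cv_folds(coh, k = 60), "minority")
})
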