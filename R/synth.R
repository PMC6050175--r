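#' Specification of a synthetic case-control cohort
#'
#' Bundles everything [generate_cohort()] needs: the class prevalence and,
#' per feature, the class-conditional category probabilities (categorical
#' features, including SNP genotypes) or class-conditional mean and SD
#' (interval features). Probability vectors that do not sum to 1 (printed
#' percentages carry rounding error) are renormalized with a message.
#'
#' @param n default cohort size.
#' @param prevalence class-1 (disease) prevalence in (0,1).
#' @param cat_freqs named list; each element is a list with `categories`
#'   (character) and `control` / `case` probability vectors.
#' @param interval_params named list; each element has `control` and `case`
#'   as `c(mean, sd)`.
#' @param class_feature name of the class column (categories
#'   `c("no", "yes")`).
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n, prevalence, cat_freqs = list(),
                        interval_params = list(), class_feature = "dyslipidemia") {
  stopifnot(prevalence > 0, prevalence < 1, n >= 2)
  norm <- function(p, what) {
    stopifnot(all(p >= 0))
    s <- sum(p)
    if (abs(s - 1) > 1e-9) {
      message("renormalizing probabilities of ", what,
              sprintf(" (sum %.4f)", s))
      p <- p / s
    }
    p
  }
  for (nm in names(cat_freqs)) {
    f <- cat_freqs[[nm]]
    stopifnot(length(f$categories) == length(f$control),
              length(f$categories) == length(f$case))
    cat_freqs[[nm]]$control <- norm(f$control, paste0(nm, " (control)"))
    cat_freqs[[nm]]$case <- norm(f$case, paste0(nm, " (case)"))
  }
  for (nm in names(interval_params)) {
    f <- interval_params[[nm]]
    stopifnot(f$control[2L] > 0, f$case[2L] > 0)
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 cat_freqs = cat_freqs, interval_params = interval_params,
                 class_feature = class_feature),
            class = "cohort_spec")
}

#' Default cohort specification emulating the pediatric dyslipidemia study
#'
#' Class-conditional genotype frequencies for the eleven lipid-pathway
#' polymorphisms, categorical exposure frequencies (family histories,
#' anthropometric categories, lifestyle) and interval means +/- SD, at the
#' study prevalence of 0.4234, all transcribed from the published
#' case-control frequency tables. Percentages are given per group
#' (control = no dyslipidemia, case = dyslipidemia) and renormalized when
#' printed rounding keeps them from summing to 100.
#'
#' @return A `cohort_spec` with `n = 725`.
#' @export
dyslipidemia_spec <- function() {
  pc <- function(...) c(...) / 100
  snp <- function(categories, control, case)
    list(categories = categories, control = pc(control), case = pc(case))

  cat_freqs <- list(
    sex = snp(c("male", "female"), c(49.28, 50.72), c(46.61, 53.39)),
    region = snp(c("urban", "rural"), c(64.80, 35.20), c(71.71, 28.29)),
    fh_diabetes = snp(c("no", "yes"), c(70.54, 29.46), c(66.14, 33.86)),
    fh_obesity = snp(c("no", "yes"), c(68.32, 31.68), c(70.12, 29.88)),
    fh_cancer = snp(c("no", "yes"), c(83.23, 16.77), c(78.88, 21.12)),
    fh_cvd = snp(c("no", "yes"), c(87.16, 12.84), c(92.43, 7.57)),
    abdominal_obesity = snp(c("no", "yes"), c(88.41, 11.59), c(61.59, 38.41)),
    bmi_category = snp(c("underweight", "normal", "overweight", "obese"),
                       c(25.85, 58.22, 8.36, 7.57), c(19.52, 58.17, 10.76, 11.55)),
    physical_activity = snp(c("mild", "moderate", "high"),
                            c(25.47, 40.37, 34.16), c(45.82, 35.86, 18.32)),
    birth_weight = snp(c("low", "normal", "high"),
                       c(11.67, 79.58, 8.75), c(16.73, 74.10, 9.17)),
    rs1801177 = snp(c("AA", "AG"), c(96.4, 3.6), c(91.2, 8.8)),
    rs2066718 = snp(c("GG", "GA"), c(94.0, 6.0), c(98.7, 1.3)),
    rs320 = snp(c("GG", "GT", "TT"), c(24.4, 48.6, 27.0), c(50.8, 42.0, 7.2)),
    rs328 = snp(c("CC", "CG", "GG"), c(72.7, 24.6, 2.6), c(88.6, 10.4, 1.0)),
    rs2230808 = snp(c("AA", "AG", "GG"), c(66.7, 29.9, 3.3), c(47.6, 39.4, 13.0)),
    rs708272 = snp(c("CC", "CT", "TT"), c(19.1, 61.7, 19.1), c(60.6, 35.5, 3.9)),
    rs5128 = snp(c("CC", "CG", "GG"), c(83.0, 16.7, 0.2), c(83.7, 15.3, 1.0)),
    rs5880 = snp(c("CC", "CG", "GG"), c(93.5, 6.5, 0.0), c(77.9, 20.8, 1.3)),
    rs2893157 = snp(c("GG", "GA", "AA"), c(69.4, 27.8, 2.9), c(74.3, 24.8, 1.0)),
    rs662799 = snp(c("CC", "CT", "TT"), c(98.8, 0.5, 0.7), c(97.7, 1.0, 1.3)),
    apoe = snp(c("e2", "e3", "e4"), c(6.9, 91.4, 1.7), c(0.7, 86.0, 13.4)))

  iv <- function(cm, cs, dm, ds) list(control = c(cm, cs), case = c(dm, ds))
  interval_params <- list(
    age = iv(14.28, 2.26, 14.64, 2.39),
    sbp = iv(101.87, 13.16, 104.16, 13.09),
    dbp = iv(65.89, 10.74, 66.69, 10.61),
    fbs = iv(87.6, 11.85, 84.32, 11.85))

  cohort_spec(n = 725L, prevalence = 0.4234, cat_freqs = cat_freqs,
              interval_params = interval_params)
}

spec_schema <- function(spec) {
  feats <- list()
  for (nm in names(spec$interval_params))
    feats[[nm]] <- feature_schema(nm, "interval")
  for (nm in names(spec$cat_freqs))
    feats[[nm]] <- feature_schema(nm, "nominal",
                                  categories = spec$cat_freqs[[nm]]$categories)
  feats[[spec$class_feature]] <-
    feature_schema(spec$class_feature, "nominal", categories = c("no", "yes"),
                   role = "class")
  cohort_schema(feats)
}

#' Generate a synthetic cohort from a specification
#'
#' Class labels are Bernoulli(prevalence); every feature is then drawn
#' independently from its class-conditional distribution (categorical:
#' multinomial over the spec probabilities; interval: normal with the spec
#' mean and SD). Only the published per-feature marginals are emulated —
#' features are conditionally independent given the class.
#'
#' @param spec a `cohort_spec`, e.g. [dyslipidemia_spec()].
#' @param n number of subjects (default `spec$n`).
#' @param seed integer seed; the same seed yields an identical table.
#' @return A validated `cohort`.
#' @export
generate_cohort <- function(spec, n = spec$n, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  schema <- spec_schema(spec)
  with_seed(seed, {
    y <- stats::rbinom(n, 1L, spec$prevalence)
    df <- data.frame(row.names = seq_len(n))
    for (nm in names(spec$interval_params)) {
      pp <- spec$interval_params[[nm]]
      m <- ifelse(y == 1, pp$case[1L], pp$control[1L])
      s <- ifelse(y == 1, pp$case[2L], pp$control[2L])
      df[[nm]] <- round(stats::rnorm(n, m, s), 2L)
    }
    for (nm in names(spec$cat_freqs)) {
      f <- spec$cat_freqs[[nm]]
      v <- character(n)
      v[y == 0] <- sample(f$categories, sum(y == 0), TRUE, prob = f$control)
      v[y == 1] <- sample(f$categories, sum(y == 1), TRUE, prob = f$case)
      df[[nm]] <- v
    }
    df[[spec$class_feature]] <- ifelse(y == 1, "yes", "no")
    cohort(df, schema)
  })
}

#' Generate a separable / imbalanced benchmark cohort
#'
#' Interval-feature benchmark data for exercising the classifier:
#' `n_informative` features whose class means differ by two standard
#' deviations, optionally an XOR interaction pair (each member marginally
#' uninformative, the pair jointly decisive), and `n_noise` class-independent
#' features. Class counts are exact: `round(n / (1 + imbalance_ratio))`
#' minority (class 1) and the rest majority.
#'
#' @param n total subjects.
#' @param imbalance_ratio majority:minority ratio (>= 1).
#' @param n_informative shifted features.
#' @param n_noise pure-noise features.
#' @param interaction add the XOR pair (`xor1`, `xor2`).
#' @param seed integer seed.
#' @return A `cohort` with class feature `"class"` (categories
#'   `c("neg", "pos")`; minority = positive).
#' @export
generate_separable <- function(n, imbalance_ratio = 1, n_informative = 2,
                               n_noise = 2, interaction = FALSE, seed = 1L) {
  stopifnot(imbalance_ratio >= 1)
  n_min <- round(n / (1 + imbalance_ratio))
  if (n_min < 2L) stop("minority class would have fewer than 2 subjects")
  y <- c(rep(1L, n_min), rep(0L, n - n_min))

  with_seed(seed, {
    y <- sample(y)
    df <- data.frame(row.names = seq_len(n))
    feats <- list()
    for (k in seq_len(n_informative)) {
      nm <- paste0("inf", k)
      df[[nm]] <- stats::rnorm(n, mean = 2 * y, sd = 1)  # 2-SD class shift
      feats[[nm]] <- feature_schema(nm, "interval")
    }
    if (interaction) {
      u <- stats::rbinom(n, 1L, 0.5)
      v <- ifelse(y == 1L, 1L - u, u)  # u XOR v == class
      df$xor1 <- u + stats::rnorm(n, 0, 0.1)
      df$xor2 <- v + stats::rnorm(n, 0, 0.1)
      feats$xor1 <- feature_schema("xor1", "interval")
      feats$xor2 <- feature_schema("xor2", "interval")
    }
    for (k in seq_len(n_noise)) {
      nm <- paste0("noise", k)
      df[[nm]] <- stats::rnorm(n)
      feats[[nm]] <- feature_schema(nm, "interval")
    }
    df$class <- ifelse(y == 1L, "pos", "neg")
    feats$class <- feature_schema("class", "nominal",
                                  categories = c("neg", "pos"), role = "class")
    cohort(df, cohort_schema(feats))
  })
}
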