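#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative cell values. Non-integer values are
#'   allowed so that confusion tables derived analytically from rates (see
#'   [confusion_from_rates()]) evaluate the ratio-based indices exactly.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(v >= 0), sum(v) > 0)
  structure(as.list(v), class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param predicted,truth 0/1 label vectors.
#' @export
confusion <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  confusion_counts(tp = sum(predicted == 1 & truth == 1),
                   fp = sum(predicted == 1 & truth == 0),
                   tn = sum(predicted == 0 & truth == 0),
                   fn = sum(predicted == 0 & truth == 1))
}

#' Confusion table implied by sensitivity, specificity and prevalence
#'
#' Inverts the rate definitions: given Se, Sp and either the prevalence or
#' the precision, returns the (generally non-integer) confusion cells of a
#' population of size `n` with exactly those rates. When `pr` is given the
#' implied prevalence is `pr(1-sp) / (se(1-pr) + pr(1-sp))`.
#'
#' @param se,sp sensitivity and specificity in (0,1).
#' @param pr precision (positive predictive value); supply this or
#'   `prevalence`.
#' @param prevalence class-1 prevalence in (0,1).
#' @param n population size (scales all cells; ratios are unaffected).
#' @return A `confusion_counts` object.
#' @export
confusion_from_rates <- function(se, sp, pr = NULL, prevalence = NULL, n = 1000) {
  stopifnot(se > 0, se < 1, sp > 0, sp < 1)
  if (is.null(prevalence)) {
    if (is.null(pr)) stop("supply `pr` or `prevalence`")
    prevalence <- pr * (1 - sp) / (se * (1 - pr) + pr * (1 - sp))
  }
  pos <- n * prevalence; neg <- n - pos
  confusion_counts(tp = se * pos, fn = (1 - se) * pos,
                   tn = sp * neg, fp = (1 - sp) * neg)
}

#' Full diagnostic metrics report
#'
#' Computes the complete battery of two-class diagnostic indices from a
#' confusion table: sensitivity (Se, = statistical power), specificity (Sp),
#' accuracy, precision (Pr; FDR = 1 - Pr), false alarm (FA = 1 - Sp = Type I
#' error), F1 score, balanced AUC defined as `(Se + Sp) / 2`, likelihood
#' ratios `LR+ = Se / (1 - Sp)` and `LR- = (1 - Se) / Sp`, diagnostic odds
#' ratio `DOR = LR+ / LR-`, discriminant power
#' `DP = (sqrt(3) / pi) * log10(DOR)`, the Matthews correlation coefficient
#' (the phi coefficient of the 2x2 predicted-vs-observed table) and Cohen's
#' kappa (chance-corrected agreement on the same table).
#'
#' Division-by-zero conventions: a perfect specificity gives `LR+ = Inf` and
#' `DOR = Inf`; a degenerate margin gives `MCC = NaN` (flagged undefined).
#'
#' @param x a `confusion_counts` (or anything [confusion_counts()] accepts
#'   via `tp`, `fp`, `tn`, `fn` arguments).
#' @param ... passed to `confusion_counts()` when `x` is missing.
#' @return A `metrics_report` list with components `Se`, `Sp`, `Acc`, `Pr`,
#'   `FA`, `Power`, `FDR`, `F1S`, `AUC`, `LR_plus`, `LR_minus`, `DOR`, `DP`,
#'   `MCC`, `Kappa` and the input `counts`.
#' @examples
#' compute_metrics(confusion_counts(tp = 93, fp = 5, tn = 95, fn = 7))
#' @export
compute_metrics <- function(x, ...) {
  if (missing(x)) x <- confusion_counts(...)
  if (!inherits(x, "confusion_counts")) stop("x must be confusion_counts")
  tp <- x$tp; fp <- x$fp; tn <- x$tn; fn <- x$fn
  n <- tp + fp + tn + fn

  se <- if (tp + fn == 0) NaN else tp / (tp + fn)
  sp <- if (tn + fp == 0) NaN else tn / (tn + fp)
  acc <- (tp + tn) / n
  pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
  fa <- 1 - sp
  f1 <- if (isTRUE(pr + se == 0)) 0 else 2 * pr * se / (pr + se)
  auc <- (se + sp) / 2
  lr_plus <- if (isTRUE(sp == 1)) Inf else se / (1 - sp)
  lr_minus <- (1 - se) / sp
  dor <- if (isTRUE(lr_minus == 0)) Inf else lr_plus / lr_minus
  dp <- (sqrt(3) / pi) * log10(dor)

  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NaN else (tp * tn - fp * fn) / mcc_den

  po <- acc
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) NaN else (po - pe) / (1 - pe)

  structure(list(Se = se, Sp = sp, Acc = acc, Pr = pr, FA = fa, Power = se,
                 FDR = 1 - pr, F1S = f1, AUC = auc, LR_plus = lr_plus,
                 LR_minus = lr_minus, DOR = dor, DP = dp, MCC = mcc,
                 Kappa = kappa, counts = x),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Diagnostic metrics report\n")
  keys <- c("Se", "Sp", "Acc", "F1S", "Pr", "FA", "AUC", "MCC", "DOR", "DP", "Kappa")
  for (k in keys) cat(sprintf("  %-6s %s\n", k, format(round(x[[k]], digits))))
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' The trapezoidal (Mann-Whitney) area under the ROC curve from continuous
#' scores. Provided under its own name because the metrics battery's `AUC`
#' is the balanced-accuracy form `(Se + Sp) / 2` at the fixed cutoff.
#'
#' @param scores numeric scores; @param truth 0/1 labels.
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) stop("truth must contain both classes")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Clinical reliability gate
#'
#' A diagnosis system is considered clinically reliable iff all four hold:
#' sensitivity >= 0.80, specificity >= 0.95, precision >= 0.95 and
#' diagnostic odds ratio >= 100 (boundaries inclusive).
#'
#' @param m a `metrics_report`.
#' @return List: `pass` (logical) and `criteria`, the per-criterion verdicts.
#' @export
reliability_gate <- function(m) {
  stopifnot(inherits(m, "metrics_report"))
  crit <- c(Se = isTRUE(m$Se >= 0.80), Sp = isTRUE(m$Sp >= 0.95),
            Pr = isTRUE(m$Pr >= 0.95), DOR = isTRUE(m$DOR >= 100))
  list(pass = all(crit), criteria = crit)
}

#' McNemar comparison of two classifiers
#'
#' Compares paired classifier decisions against a common gold standard
#' through the discordant counts `b` (A correct, B wrong) and `c` (A wrong,
#' B correct). The continuity-corrected chi-square statistic
#' `(|b - c| - 1)^2 / (b + c)` (1 df) is always reported; the p-value uses
#' the chi-square tail when `b + c >= 25` and the exact two-sided binomial
#' test otherwise (`exact = "auto"`), or can be forced either way.
#'
#' @param labels_a,labels_b 0/1 predictions of the two classifiers.
#' @param truth 0/1 gold-standard labels.
#' @param exact `"auto"` (default), `"never"` (always chi-square tail) or
#'   `"always"` (always exact binomial).
#' @return List: `statistic` (corrected chi-square), `p_value`, `b`, `c`,
#'   `method`.
#' @export
mcnemar_test <- function(labels_a, labels_b, truth,
                         exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  stopifnot(length(labels_a) == length(truth), length(labels_b) == length(truth))
  right_a <- labels_a == truth; right_b <- labels_b == truth
  b <- sum(right_a & !right_b)
  c_ <- sum(!right_a & right_b)
  if (b + c_ == 0)
    return(list(statistic = 0, p_value = 1, b = b, c = c_, method = "degenerate"))
  stat <- (abs(b - c_) - 1)^2 / (b + c_)
  use_exact <- switch(exact, auto = (b + c_) < 25, never = FALSE, always = TRUE)
  if (use_exact) {
    p <- min(1, 2 * stats::pbinom(min(b, c_), b + c_, 0.5))
    method <- "exact binomial"
  } else {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "continuity-corrected chi-square"
  }
  list(statistic = stat, p_value = p, b = b, c = c_, method = method)
}

#' Tabulate metrics reports
#'
#' Formats one or more reports as a data frame (and optionally Markdown) with
#' the standard column set: Se, Sp, Acc, F1S, Pr, FA, AUC, MCC, DOR, DP,
#' Kappa.
#'
#' @param reports a named list of `metrics_report`s (or a single report).
#' @param percent express Se/Sp/Acc/F1S/Pr as percentages (default TRUE).
#' @return A data frame, one row per report.
#' @export
metrics_table <- function(reports, percent = TRUE) {
  if (inherits(reports, "metrics_report")) reports <- list(model = reports)
  rows <- lapply(reports, function(m) {
    pct <- function(v) if (percent) 100 * v else v
    data.frame(Se = pct(m$Se), Sp = pct(m$Sp), Acc = pct(m$Acc),
               F1S = pct(m$F1S), Pr = pct(m$Pr), FA = m$FA, AUC = m$AUC,
               MCC = m$MCC, DOR = m$DOR, DP = m$DP, Kappa = m$Kappa)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(reports)
  out
}

#' @rdname metrics_table
#' @param path optional output path; `.json` writes JSON, anything else a
#'   Markdown table.
#' @export
write_metrics <- function(reports, path, percent = TRUE) {
  tab <- metrics_table(reports, percent = percent)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cbind(classifier = rownames(tab), tab), path,
                         dataframe = "rows", digits = NA)
  } else {
    hdr <- c("classifier", colnames(tab))
    lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
               vapply(seq_len(nrow(tab)), function(r)
                 paste0("| ", rownames(tab)[r], " | ",
                        paste(signif(unlist(tab[r, ]), 4), collapse = " | "), " |"),
                 character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
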