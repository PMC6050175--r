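#' Iterative RELIEF (I-RELIEF) feature weighting
#'
#' Weights each predictor by its ability to separate neighbouring patterns of
#' opposite classes, iterated in an expectation-maximization style. In the
#' E-step every sample receives probabilistic nearest-hit and nearest-miss
#' distributions over all same-class / other-class samples, with probabilities
#' proportional to `exp(-d / kernel_width)` under the current weighted
#' Manhattan (L1) distance. The M-step averages the per-feature margin
#' (expected miss distance minus expected hit distance) over samples, keeps
#' its positive part, and renormalizes to unit Euclidean norm. Iteration stops
#' when the weight vector moves less than `tol`.
#'
#' @param X numeric n x p predictor matrix (entries in \[0,1\]).
#' @param y 0/1 class labels; both classes must be present, n >= 4.
#' @param kernel_width positive kernel width of the neighbourhood smoother.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the L2 change of the weights.
#' @return A `feature_weights` object: `w` (non-negative, unit L2 norm),
#'   `iterations`, `converged`.
#' @export
irelief <- function(X, y, kernel_width = 2, max_iter = 50L, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 4L, p >= 1L, length(y) == n)
  if (kernel_width <= 0) stop("kernel_width must be positive")
  if (length(unique(y)) < 2L) stop("both classes must be present")

  # per-feature absolute difference matrices, n x n each
  D <- lapply(seq_len(p), function(f) abs(outer(X[, f], X[, f], "-")))
  same <- outer(y, y, "==")
  diag(same) <- NA  # a sample is neither its own hit nor miss

  w <- rep(1 / sqrt(p), p)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    dist <- matrix(0, n, n)
    for (f in seq_len(p)) dist <- dist + w[f] * D[[f]]
    K <- exp(-dist / kernel_width)

    hitK <- K; hitK[!same | is.na(same)] <- 0
    missK <- K; missK[same | is.na(same)] <- 0
    hs <- rowSums(hitK); ms <- rowSums(missK)
    hs[hs == 0] <- 1; ms[ms == 0] <- 1  # isolated samples contribute nothing

    margin <- numeric(p)
    for (f in seq_len(p)) {
      margin[f] <- mean(rowSums(missK * D[[f]]) / ms - rowSums(hitK * D[[f]]) / hs)
    }
    v <- pmax(margin, 0)
    w_new <- if (sum(v) == 0) rep(1 / sqrt(p), p) else v / sqrt(sum(v^2))
    delta <- sqrt(sum((w_new - w)^2))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(w = w, iterations = it, converged = converged),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat("I-RELIEF feature weights (", length(x$w), " features, ",
      x$iterations, " iterations, ",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  print(round(x$w, 4))
  invisible(x)
}

#' Select predictors from RELIEF weights
#'
#' @param w a `feature_weights` object (or bare numeric weight vector).
#' @param rule `"threshold"` keeps features with weight >= `tau` (default:
#'   the mean weight); `"top_k"` keeps the `k` heaviest.
#' @param k,tau rule parameters.
#' @return Integer indices sorted by descending weight; ties broken by lower
#'   column index.
#' @export
select_by_weight <- function(w, rule = c("threshold", "top_k"), k = NULL, tau = NULL) {
  rule <- match.arg(rule)
  wv <- if (inherits(w, "feature_weights")) w$w else as.numeric(w)
  p <- length(wv)
  ord <- order(-wv, seq_len(p))  # descending weight, lower index wins ties
  if (rule == "top_k") {
    if (is.null(k)) stop("top_k rule needs `k`")
    if (k > p) stop("k exceeds the number of features")
    return(ord[seq_len(k)])
  }
  tau <- tau %||% mean(wv)
  keep <- ord[wv[ord] >= tau]
  keep
}

#' Sequential forward selection
#'
#' Greedy bottom-up wrapper: starting from the empty set, repeatedly adds the
#' feature whose inclusion maximizes the fitness, and stops as soon as no
#' addition improves it (or `max_features` is reached).
#'
#' @param X predictor matrix; @param y class labels.
#' @param fitness `function(Xsub, y) -> numeric` scoring a candidate column
#'   subset (typically: fit on training rows, score on validation rows).
#' @param max_features cap on the selected-set size.
#' @return Integer vector of selected column indices, in selection order.
#' @export
sfs <- function(X, y, fitness, max_features = ncol(X)) {
  X <- as.matrix(X)
  p <- ncol(X)
  selected <- integer()
  best <- -Inf
  while (length(selected) < min(max_features, p)) {
    cand <- setdiff(seq_len(p), selected)
    scores <- vapply(cand, function(j)
      fitness(X[, c(selected, j), drop = FALSE], y), numeric(1))
    j_best <- cand[which.max(scores)]
    if (max(scores) <= best) break
    best <- max(scores)
    selected <- c(selected, j_best)
  }
  selected
}
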