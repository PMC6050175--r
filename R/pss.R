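#' Parallel selective sampling (PSS) of the majority class
#'
#' Reduces class imbalance by keeping only the majority-class samples that lie
#' close to the minority class — the region where the decision boundary must
#' be resolved — and discarding majority samples deep inside their own class.
#' The minority class is never touched.
#'
#' Every majority sample's Euclidean distance to its nearest minority sample
#' is computed; a sample is kept iff that distance does not exceed the global
#' `distance_quantile` of these distances. Majority samples are processed in
#' seed-shuffled chunks (chunking exists purely to bound per-worker memory and
#' allow parallel processing; the keep rule uses the global quantile, so the
#' result does not depend on chunk boundaries). If the quantile rule would
#' push the majority below the minority count, the closest excluded samples
#' are added back in distance order until the classes are balanced — the class
#' ratio moves toward 1:1 and never past it.
#'
#' @param X numeric predictor matrix (rows = samples, entries in \[0,1\]).
#' @param y 0/1 class labels.
#' @param chunk_size majority samples per chunk (>= 2).
#' @param distance_quantile keep quantile in (0,1); smaller keeps fewer,
#'   boundary-closer samples.
#' @param seed integer seed for the chunk shuffle.
#' @return A `pss_sample`: `kept` and `removed` (majority row indices into
#'   `X`), `majority_class`, `chunks` (per-chunk id and kept count), and
#'   `index` — all retained rows (minority plus kept majority), sorted.
#' @export
pss <- function(X, y, chunk_size = 500L, distance_quantile = 0.75, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), chunk_size >= 2L,
            distance_quantile > 0, distance_quantile < 1)
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) stop("both classes must be present")
  maj <- if (counts["1"] > counts["0"]) 1 else 0
  maj_idx <- which(y == maj)
  min_idx <- which(y != maj)

  if (length(maj_idx) == length(min_idx)) {
    return(structure(list(kept = maj_idx, removed = integer(),
                          majority_class = maj, chunks = NULL,
                          index = sort(seq_along(y))),
                     class = "pss_sample"))
  }

  # distance of each majority row to its nearest minority row
  nearest <- function(A, B) {
    # rows of A vs rows of B, squared Euclidean via the Gram expansion
    a2 <- rowSums(A^2); b2 <- rowSums(B^2)
    d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
    sqrt(pmax(apply(d2, 1L, min), 0))
  }

  chunks <- with_seed(seed, {
    perm <- sample(maj_idx)
    split(perm, ceiling(seq_along(perm) / chunk_size))
  })
  d <- numeric(length(y))
  for (ch in chunks) d[ch] <- nearest(X[ch, , drop = FALSE], X[min_idx, , drop = FALSE])
  dmaj <- d[maj_idx]

  thr <- stats::quantile(dmaj, distance_quantile, names = FALSE)
  keep <- dmaj <= thr
  n_min <- length(min_idx)
  if (sum(keep) < n_min) {
    # under-shoot: re-balance to 1:1 by adding back the boundary-closest rows
    keep <- rank(dmaj, ties.method = "first") <= min(n_min, length(maj_idx))
  }

  kept <- maj_idx[keep]
  diag <- data.frame(
    chunk = seq_along(chunks),
    size = lengths(chunks),
    kept = vapply(chunks, function(ch) sum(ch %in% kept), integer(1)))
  structure(list(kept = sort(kept), removed = sort(maj_idx[!keep]),
                 majority_class = maj, chunks = diag,
                 index = sort(c(min_idx, kept))),
            class = "pss_sample")
}

#' @export
print.pss_sample <- function(x, ...) {
  cat("PSS majority-class sampling: kept ", length(x$kept), ", removed ",
      length(x$removed), " of the majority class (", x$majority_class, ")\n",
      sep = "")
  invisible(x)
}
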