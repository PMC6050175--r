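#' Feature schema for mixed-type cohort tables
#'
#' A schema describes every column of a cohort table: its measurement scale
#' (`interval`, `nominal` or `ordinal`), its admissible categories (for
#' categorical features) and its role in the analysis. Exactly one column must
#' carry `role = "class"` and list exactly two categories, in the order
#' (negative, positive).
#'
#' @param name column name.
#' @param kind one of `"interval"`, `"nominal"`, `"ordinal"`.
#' @param categories character vector of admissible category labels; must be
#'   empty for interval features and have length >= 2 otherwise.
#' @param role one of `"predictor"`, `"class"`, `"id"`, `"excluded"`.
#' @return A `feature_schema` list with the four fields above.
#' @seealso [cohort_schema()], [cohort()]
#' @export
feature_schema <- function(name, kind = c("interval", "nominal", "ordinal"),
                           categories = character(), role = "predictor") {
  kind <- match.arg(kind)
  role <- match.arg(role, c("predictor", "class", "id", "excluded"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  categories <- as.character(categories)
  if (kind == "interval" && length(categories) > 0L)
    stop("interval feature '", name, "' must not declare categories")
  if (kind != "interval" && length(categories) < 2L)
    stop("categorical feature '", name, "' needs >= 2 categories")
  if (role == "class" && length(categories) != 2L)
    stop("class column '", name, "' must have exactly 2 categories (negative, positive)")
  structure(list(name = name, kind = kind, categories = categories, role = role),
            class = "feature_schema")
}

#' Assemble a cohort schema from feature definitions
#'
#' @param ... `feature_schema` objects (or lists coercible to them).
#' @return A `cohort_schema`: a named list of `feature_schema` entries.
#' @export
cohort_schema <- function(...) {
  feats <- list(...)
  if (length(feats) == 1L && is.list(feats[[1]]) &&
      !inherits(feats[[1]], "feature_schema")) {
    feats <- feats[[1]]
  }
  feats <- lapply(feats, function(f) {
    if (inherits(f, "feature_schema")) f
    else feature_schema(f$name, f$kind, f$categories %||% character(), f$role %||% "predictor")
  })
  names(feats) <- vapply(feats, `[[`, "", "name")
  ncls <- sum(vapply(feats, function(f) f$role == "class", TRUE))
  if (ncls != 1L) stop("schema must contain exactly one class column, found ", ncls)
  structure(feats, class = "cohort_schema")
}

schema_class_feature <- function(schema) {
  schema[[which(vapply(schema, function(f) f$role == "class", TRUE))]]
}

#' Read or write a schema file (YAML or JSON)
#'
#' The on-disk format is a list of records with fields `name`, `kind`,
#' `categories`, `role`; the file extension selects YAML (`.yml`/`.yaml`)
#' or JSON.
#'
#' @param path file path.
#' @return `read_schema()` returns a `cohort_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  cohort_schema(raw)
}

#' @rdname read_schema
#' @param schema a `cohort_schema`.
#' @export
write_schema <- function(schema, path) {
  recs <- lapply(unclass(schema), function(f)
    list(name = f$name, kind = f$kind,
         categories = as.character(f$categories), role = f$role))
  names(recs) <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(recs, path)
  } else {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

MISSING_TOKENS <- c("NA", ".")

#' Construct a validated mixed-type cohort table
#'
#' Couples a data frame with a [cohort_schema()] and validates every cell:
#' interval cells must be numeric (or missing), categorical cells must be one
#' of the schema categories (or a missing token). Rows with a missing class
#' label are dropped with a warning. Binary class labels are exposed as
#' `class_labels(x)`: 0 for the first (negative) class category, 1 for the
#' second.
#'
#' @param data a data frame whose column names match the schema.
#' @param schema a `cohort_schema`.
#' @return A `cohort` object.
#' @export
cohort <- function(data, schema) {
  stopifnot(is.data.frame(data), inherits(schema, "cohort_schema"))
  miss <- setdiff(names(schema), names(data))
  if (length(miss)) stop("data is missing schema columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data[, names(schema), drop = FALSE], stringsAsFactors = FALSE)

  for (f in schema) {
    x <- data[[f$name]]
    if (f$kind == "interval") {
      if (is.character(x)) {
        x[x %in% MISSING_TOKENS] <- NA
        xn <- suppressWarnings(as.numeric(x))
        bad <- which(!is.na(x) & is.na(xn))
        if (length(bad))
          stop("non-numeric interval cell(s) in column '", f$name, "' at row(s) ",
               paste(utils::head(bad, 5L), collapse = ", "))
        x <- xn
      }
      if (!is.numeric(x)) stop("column '", f$name, "' must be numeric (interval)")
      data[[f$name]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      x[x %in% MISSING_TOKENS] <- NA
      bad <- which(!is.na(x) & !(x %in% f$categories))
      if (length(bad))
        stop("unknown category '", x[bad[1L]], "' in column '", f$name,
             "' at row(s) ", paste(utils::head(bad, 5L), collapse = ", "))
      data[[f$name]] <- x
    }
  }

  cls <- schema_class_feature(schema)
  drop <- is.na(data[[cls$name]])
  if (any(drop)) {
    warning(sum(drop), " row(s) with missing class label dropped")
    data <- data[!drop, , drop = FALSE]
  }
  rownames(data) <- NULL
  structure(list(data = data, schema = schema), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cls <- schema_class_feature(x$schema)
  y <- class_labels(x)
  cat("Mixed-type cohort: ", nrow(x$data), " subjects x ",
      length(x$schema), " columns\n", sep = "")
  cat("  class '", cls$name, "': ", sum(y == 0), " ", cls$categories[1L], " / ",
      sum(y == 1), " ", cls$categories[2L],
      sprintf("  (prevalence %.3f)\n", mean(y)), sep = "")
  kinds <- table(vapply(x$schema, `[[`, "", "kind"))
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Binary class labels of a cohort
#'
#' @param x a `cohort`.
#' @return Integer vector: 0 = negative (first class category), 1 = positive.
#' @export
class_labels <- function(x) {
  stopifnot(inherits(x, "cohort"))
  cls <- schema_class_feature(x$schema)
  as.integer(x$data[[cls$name]] == cls$categories[2L])
}

#' @export
dim.cohort <- function(x) dim(x$data)

#' Subset rows of a cohort
#' @param x a `cohort`; @param i row indices; @param ... ignored.
#' @export
`[.cohort` <- function(x, i, ...) {
  out <- x
  out$data <- x$data[i, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Read and write cohort tables as CSV/TSV
#'
#' `read_cohort()` loads a delimited text file and validates it against the
#' schema (every violation is reported with row and column). `write_cohort()`
#' writes the table back; `write_cohort()` then `read_cohort()` is the
#' identity on valid tables. `"NA"` and `"."` parse as missing.
#'
#' @param path file path; `.tsv` selects tab separation, otherwise comma.
#' @param schema a `cohort_schema` or path to a schema file.
#' @return `read_cohort()` returns a `cohort`.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.character(schema)) schema <- read_schema(schema)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                          check.names = FALSE, na.strings = character(),
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) stop("header is missing schema column(s): ",
                         paste(miss, collapse = ", "))
  cohort(df, schema)
}

#' @rdname read_cohort
#' @param x a `cohort`.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(x$data, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Re-encode SNP genotype columns
#'
#' Genotypes arrive as nucleotide-pair categories (e.g. `"TT"`, `"TG"`,
#' `"GG"`). `mode = "pairs"` canonicalizes heterozygote order (the two
#' nucleotides are sorted alphabetically, so `"TG"` and `"GT"` merge into one
#' category). `mode = "carrier"` collapses the genotype to a binary feature:
#' `"1"` iff the genotype contains at least one copy of the minority allele.
#'
#' @param x a `cohort`.
#' @param snp name of a nominal feature holding nucleotide pairs.
#' @param mode `"pairs"` or `"carrier"`.
#' @param minority_allele single nucleotide, required for `mode = "carrier"`.
#' @return The cohort with the column (and its schema entry) re-encoded.
#' @export
encode_genotypes <- function(x, snp, mode = c("pairs", "carrier"),
                             minority_allele = NULL) {
  stopifnot(inherits(x, "cohort"))
  mode <- match.arg(mode)
  f <- x$schema[[snp]]
  if (is.null(f)) stop("unknown feature: ", snp)
  if (f$kind == "interval") stop("'", snp, "' is not a categorical genotype feature")
  canon <- function(g) {
    ifelse(is.na(g), NA,
           vapply(g, function(p) paste(sort(strsplit(p, "")[[1L]]), collapse = ""), ""))
  }
  vals <- canon(x$data[[snp]])
  cats <- unique(canon(f$categories))
  if (mode == "pairs") {
    x$data[[snp]] <- unname(vals)
    x$schema[[snp]]$categories <- cats
    return(x)
  }
  if (is.null(minority_allele)) stop("carrier encoding needs `minority_allele`")
  if (!any(grepl(minority_allele, cats, fixed = TRUE)))
    stop("minority allele '", minority_allele, "' absent from categories of '", snp, "'")
  carrier <- ifelse(is.na(vals), NA,
                    ifelse(grepl(minority_allele, vals, fixed = TRUE), "1", "0"))
  x$data[[snp]] <- unname(carrier)
  x$schema[[snp]]$categories <- c("0", "1")
  x
}

#' Hold-out split plan
#'
#' @param fractions numeric (estimation, validation, test), each in (0,1),
#'   summing to 1.
#' @param stratified stratify by class (default TRUE).
#' @param seed integer seed; splitting is reproducible from it.
#' @return A `split_plan` list.
#' @export
split_plan <- function(fractions = c(0.40, 0.10, 0.50), stratified = TRUE, seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0), all(fractions < 1),
            abs(sum(fractions) - 1) < 1e-9)
  structure(list(fractions = as.numeric(fractions),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_plan")
}

# Stratified apportionment of row indices into parts. Within each stratum a
# largest-remainder rule assigns the leftover units; remainder ties are broken
# toward the partition with the largest global shortfall so that the overall
# sizes also track n * fracs as closely as possible.
stratified_partition <- function(y, fracs, seed, stratified = TRUE) {
  n <- length(y)
  k <- length(fracs)
  parts <- vector("list", k)
  tot <- numeric(k)
  served <- 0
  with_seed(seed, {
    groups <- if (stratified) split(seq_len(n), y) else list(seq_len(n))
    for (g in groups) {
      g <- sample(g)
      m <- length(g)
      raw <- m * fracs
      sizes <- floor(raw)
      rem <- m - sum(sizes)
      if (rem > 0) {
        deficit <- fracs * (served + m) - (tot + sizes)
        pick <- order(-(raw - sizes), -deficit, seq_len(k))[seq_len(rem)]
        sizes[pick] <- sizes[pick] + 1L
      }
      at <- 0L
      for (p in seq_len(k)) {
        parts[[p]] <- c(parts[[p]], g[at + seq_len(sizes[p])])
        at <- at + sizes[p]
      }
      tot <- tot + sizes
      served <- served + m
    }
  })
  lapply(parts, sort)
}

#' Split a cohort into estimation, validation and test partitions
#'
#' Partitions are disjoint, exhaustive, class-stratified to within one subject
#' per class, and reproducible from the plan seed. The canonical plan of the
#' diagnosis pipeline is 40% estimation / 10% validation / 50% test
#' (estimation + validation together forming the training set).
#'
#' @param x a `cohort` with both classes present.
#' @param plan a [split_plan()]; alternatively pass `fractions` and `seed`.
#' @param fractions,seed shortcut used when `plan` is missing.
#' @return Named list of cohorts: `estimation`, `validation`, `test`.
#' @export
split_holdout <- function(x, plan = NULL, fractions = c(0.40, 0.10, 0.50), seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(plan)) plan <- split_plan(fractions, seed = seed)
  y <- class_labels(x)
  if (length(unique(y)) < 2L) stop("both classes must be present before splitting")
  idx <- stratified_partition(y, plan$fractions, plan$seed, plan$stratified)
  out <- lapply(idx, function(i) x[i])
  names(out) <- c("estimation", "validation", "test")
  for (nm in names(out)) {
    yy <- class_labels(out[[nm]])
    if (length(yy) == 0L) stop("partition '", nm, "' is empty")
    if (length(unique(yy)) < 2L) stop("partition '", nm, "' is single-class")
  }
  out
}

#' k-fold cross-validation folds with internal estimation/validation split
#'
#' The k test partitions are class-stratified, pairwise disjoint, and tile the
#' cohort exactly once. Within each fold the non-test remainder is split into
#' estimation and validation so that the full-fold proportions equal
#' `fractions` (default 60% estimation / 15% validation / 25% test).
#'
#' @param x a `cohort`.
#' @param k number of folds (>= 2).
#' @param fractions full-table (estimation, validation, test) proportions.
#' @param seed integer seed.
#' @return List of k fold lists, each with `estimation`, `validation`, `test`.
#' @export
make_cv_folds <- function(x, k = 4L, fractions = c(0.60, 0.15, 0.25), seed = 1L) {
  stopifnot(inherits(x, "cohort"), k >= 2L)
  y <- class_labels(x)
  if (k > min(table(y))) stop("k exceeds the minority-class count")
  n <- length(y)

  # per-class fold sizes via floor + smallest-total-first extras, so fold
  # totals form a near-equal integer partition of n
  fold_idx <- vector("list", k)
  totals <- integer(k)
  with_seed(seed, {
    for (g in split(seq_len(n), y)) {
      g <- sample(g)
      m <- length(g)
      sizes <- rep(m %/% k, k)
      rem <- m %% k
      if (rem > 0) {
        ord <- order(totals, seq_len(k))  # top up the currently smallest folds
        sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
      }
      at <- 0L
      for (f in seq_len(k)) {
        fold_idx[[f]] <- c(fold_idx[[f]], g[at + seq_len(sizes[f])])
        at <- at + sizes[f]
      }
      totals <- totals + sizes
    }
  })

  inner <- fractions[1:2] / sum(fractions[1:2])
  lapply(seq_len(k), function(f) {
    test_i <- sort(fold_idx[[f]])
    rest <- setdiff(seq_len(n), test_i)
    ev <- stratified_partition(y[rest], inner, seed + f, TRUE)
    list(estimation = x[rest[ev[[1L]]]],
         validation = x[rest[ev[[2L]]]],
         test = x[test_i])
  })
}
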