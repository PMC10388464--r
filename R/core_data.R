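#' Labeled feature table
#'
#' The container every stage of the pipeline consumes: an `m x n` numeric
#' feature matrix `X` (rows = samples, columns = radiomic or clinical
#' features), a binary label vector `C` (1 = TMB-high, 0 = TMB-low), sample
#' identifiers, and a per-feature category tag in
#' `{tumor_voi, peritumoral_voi, clinical}`.
#'
#' @param X numeric matrix, samples in rows.
#' @param C binary label vector (0/1), length `nrow(X)`.
#' @param sample_ids character vector of sample identifiers.
#' @param feature_names character vector of unique feature names.
#' @param feature_category per-feature category tags; recycled default
#'   `"tumor_voi"`.
#' @return an object of class `nemtie_table`.
#' @export
feature_table <- function(X, C,
                          sample_ids = NULL,
                          feature_names = NULL,
                          feature_category = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  m <- nrow(X)
  n <- ncol(X)
  if (length(C) != m) stop("label vector length must equal nrow(X)", call. = FALSE)
  if (anyNA(X)) {
    bad <- which(rowSums(is.na(X)) > 0L)
    ids <- if (!is.null(sample_ids)) sample_ids[bad] else as.character(bad)
    stop(sprintf("missing feature values in sample(s): %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  C <- as.integer(C)
  if (anyNA(C) || !all(C %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 with no missing values", call. = FALSE)
  }
  if (length(unique(C)) < 2L) {
    stop("single-class label: both TMB-high and TMB-low must be present",
         call. = FALSE)
  }
  sample_ids <- as.character(sample_ids %||% paste0("S", seq_len(m)))
  feature_names <- as.character(feature_names %||%
                                  (colnames(X) %||% paste0("F", seq_len(n))))
  if (anyDuplicated(feature_names)) stop("feature names must be unique", call. = FALSE)
  if (length(feature_names) != n) stop("feature_names length must equal ncol(X)", call. = FALSE)
  feature_category <- as.character(feature_category %||% rep("tumor_voi", n))
  feature_category <- rep_len(feature_category, n)
  ok <- feature_category %in% c("tumor_voi", "peritumoral_voi", "clinical")
  if (!all(ok)) stop("feature_category must be tumor_voi, peritumoral_voi or clinical",
                     call. = FALSE)
  dimnames(X) <- list(sample_ids, feature_names)
  structure(
    list(X = X, C = C, sample_ids = sample_ids,
         feature_names = feature_names, feature_category = feature_category),
    class = "nemtie_table"
  )
}

#' @export
print.nemtie_table <- function(x, ...) {
  cat(sprintf("<nemtie_table> %d samples x %d features (%d TMB-high, %d TMB-low)\n",
              nrow(x$X), ncol(x$X), sum(x$C == 1L), sum(x$C == 0L)))
  tab <- table(x$feature_category)
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.nemtie_table <- function(x) dim(x$X)

#' Dichotomize tumor mutational burden
#'
#' Labels a sample TMB-high (1) when its mutation burden is at or above the
#' cutoff, TMB-low (0) otherwise. The clinical cutoff is 15.5 mutations per
#' megabase; values exactly at the cutoff are labeled high (documented
#' boundary convention, configurable via `cutoff`).
#'
#' @param mut_per_mb nonnegative numeric vector, mutations per megabase.
#' @param cutoff numeric cutoff, default 15.5 mut/Mb.
#' @return integer 0/1 vector.
#' @export
#' @examples
#' label_from_tmb(c(3.1, 20))
label_from_tmb <- function(mut_per_mb, cutoff = 15.5) {
  if (anyNA(mut_per_mb)) stop("missing mutation burden values", call. = FALSE)
  if (any(mut_per_mb < 0)) stop("mutation burden must be nonnegative", call. = FALSE)
  as.integer(mut_per_mb >= cutoff)
}

#' Read a labeled feature table from CSV
#'
#' Expects a comma-separated UTF-8 file: first row header, first column
#' sample id, remaining columns numeric features plus one label column. If
#' the label column takes only the values 0/1 it is used directly; otherwise
#' it is interpreted as mutations per megabase and thresholded with
#' [label_from_tmb()]. Rows containing missing feature values are rejected
#' with an error naming the offending samples; constant (zero-variance)
#' features are reported with a warning.
#'
#' @param path CSV file path.
#' @param label_column name of the label column.
#' @param category_map optional named character vector (or 2-column
#'   data.frame `feature,category`) mapping feature names to categories.
#' @param cutoff TMB cutoff used when the label column is continuous.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, label_column,
                               category_map = NULL, cutoff = 15.5) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("CSV must have sample id, >=1 feature and a label column",
                          call. = FALSE)
  sample_ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found", label_column), call. = FALSE)
  }
  lab_raw <- df[[label_column]]
  df[[label_column]] <- NULL
  X <- as.matrix(df)
  if (!is.numeric(X)) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop(sprintf("non-numeric feature column(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  lab_raw <- as.numeric(lab_raw)
  C <- if (all(lab_raw %in% c(0, 1))) as.integer(lab_raw) else label_from_tmb(lab_raw, cutoff)
  cat_vec <- NULL
  if (!is.null(category_map)) {
    if (is.data.frame(category_map)) {
      category_map <- stats::setNames(as.character(category_map[[2L]]),
                                      as.character(category_map[[1L]]))
    }
    cat_vec <- unname(category_map[colnames(X)])
    cat_vec[is.na(cat_vec)] <- "tumor_voi"
  }
  tab <- feature_table(X, C, sample_ids = sample_ids,
                       feature_names = colnames(X), feature_category = cat_vec)
  sds <- apply(tab$X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("constant (zero-variance) feature(s): %s",
                    paste(tab$feature_names[sds == 0], collapse = ", ")),
            call. = FALSE)
  }
  tab
}

#' Write a labeled feature table to CSV
#'
#' Inverse of [read_feature_table()]: first column `sample_id`, feature
#' columns at full double precision, label column `label`.
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_ids, check.names = FALSE)
  X <- table$X
  for (j in seq_len(ncol(X))) df[[table$feature_names[j]]] <- X[, j]
  df$label <- table$C
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a feature table
#'
#' @param table a [feature_table()].
#' @param samples optional sample index vector.
#' @param features optional feature index or name vector.
#' @return a new `nemtie_table` (label validity is re-checked).
#' @export
subset_table <- function(table, samples = NULL, features = NULL) {
  samples <- samples %||% seq_along(table$sample_ids)
  if (is.character(features)) features <- match(features, table$feature_names)
  features <- features %||% seq_along(table$feature_names)
  if (anyNA(features)) stop("unknown feature name", call. = FALSE)
  feature_table(table$X[samples, features, drop = FALSE],
                table$C[samples],
                sample_ids = table$sample_ids[samples],
                feature_names = table$feature_names[features],
                feature_category = table$feature_category[features])
}

#' Stratified three-way cohort split
#'
#' Randomly partitions samples into train/test/validation groups with the
#' study design's 70/20/10 ratios by default. Overall split sizes are
#' `round(m * ratio)` for test and validation with the remainder absorbed by
#' the training split; within each split, class quotas follow a
#' largest-remainder allocation so class proportions deviate from the cohort
#' proportion by at most one sample, and every split holds at least one
#' sample of each class.
#'
#' @param table a [feature_table()].
#' @param ratios positive length-3 vector `(train, test, validation)` summing
#'   to 1 (tolerance 1e-9).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param stratified logical; stratify by class (default TRUE). Unstratified
#'   splits are drawn uniformly and may fail the every-split-scoreable check.
#' @return an object of class `nemtie_split` with `train_idx`, `test_idx`,
#'   `validation_idx`, `ratios`, `seed`.
#' @export
#' @examples
#' tab <- generate_synthetic(default_scenario(seed = 1))$table
#' sp <- split_cohort(tab, seed = 7)
#' lengths(sp[c("train_idx", "test_idx", "validation_idx")])
split_cohort <- function(table, ratios = c(0.70, 0.20, 0.10), seed = 1L,
                         stratified = TRUE) {
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop("ratios must be three positive fractions", call. = FALSE)
  }
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1", call. = FALSE)
  m <- length(table$C)
  n_test <- round(m * ratios[2L])
  n_val <- round(m * ratios[3L])
  n_train <- m - n_test - n_val
  if (min(n_train, n_test, n_val) < 2L && stratified) {
    if (min(n_train, n_test, n_val) < 1L) stop("cohort too small to split", call. = FALSE)
  }
  cls <- sort(unique(table$C))
  if (stratified && any(table(table$C) < 3L)) {
    stop("too few samples in a class for a stratified three-way split", call. = FALSE)
  }
  perm_by_class <- with_seed(seed, {
    lapply(cls, function(cl) {
      idx <- which(table$C == cl)
      idx[sample.int(length(idx))]
    })
  })
  if (!stratified) {
    pool <- with_seed(seed, sample.int(m))
    test_idx <- pool[seq_len(n_test)]
    val_idx <- pool[n_test + seq_len(n_val)]
    train_idx <- pool[-seq_len(n_test + n_val)]
  } else {
    m_c <- lengths(perm_by_class)
    take <- function(quota_total, avail) {
      # largest-remainder allocation of `quota_total` across classes,
      # proportional to remaining class sizes, >=1 per class where possible
      q <- quota_total * avail / sum(avail)
      base <- floor(q)
      rem <- quota_total - sum(base)
      if (rem > 0) {
        ord <- order(q - base, avail, decreasing = TRUE)
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
      }
      # guarantee one of each class when the split can hold them
      if (quota_total >= length(avail)) {
        while (any(base == 0L & avail > 0L)) {
          give <- which(base == 0L & avail > 0L)[1L]
          steal <- which.max(base)
          base[steal] <- base[steal] - 1L
          base[give] <- base[give] + 1L
        }
      }
      pmin(base, avail)
    }
    avail <- m_c
    taken <- lapply(perm_by_class, function(x) 0L)
    alloc <- function(n_split, avail) take(n_split, avail)
    a_test <- alloc(n_test, avail)
    avail <- avail - a_test
    a_val <- alloc(n_val, avail)
    avail <- avail - a_val
    test_idx <- val_idx <- train_idx <- integer(0)
    for (i in seq_along(cls)) {
      p <- perm_by_class[[i]]
      test_idx <- c(test_idx, p[seq_len(a_test[i])])
      val_idx <- c(val_idx, p[a_test[i] + seq_len(a_val[i])])
      train_idx <- c(train_idx, p[-seq_len(a_test[i] + a_val[i])])
    }
  }
  sp <- structure(
    list(train_idx = sort(train_idx), test_idx = sort(test_idx),
         validation_idx = sort(val_idx), ratios = ratios, seed = seed),
    class = "nemtie_split"
  )
  if (stratified) {
    # a split of size 1 cannot hold both classes; larger splits must
    for (nm in c("train_idx", "test_idx", "validation_idx")) {
      idx <- sp[[nm]]
      if (length(idx) >= 2L && length(unique(table$C[idx])) < 2L) {
        stop(sprintf("split '%s' contains a single class", sub("_idx", "", nm)),
             call. = FALSE)
      }
    }
  }
  sp
}

#' @export
print.nemtie_split <- function(x, ...) {
  cat(sprintf("<nemtie_split> train=%d test=%d validation=%d (seed %d)\n",
              length(x$train_idx), length(x$test_idx),
              length(x$validation_idx), x$seed))
  invisible(x)
}

#' Write a split manifest CSV
#'
#' @param split a `nemtie_split`.
#' @param table the table the split indexes.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, table, path) {
  grp <- character(length(table$sample_ids))
  grp[split$train_idx] <- "train"
  grp[split$test_idx] <- "test"
  grp[split$validation_idx] <- "validation"
  utils::write.csv(data.frame(sample_id = table$sample_ids, split = grp),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize features on a reference index set
#'
#' Centers and scales every feature by the mean and sample (n-1) standard
#' deviation computed on `fit_idx` only, then applies that transform to all
#' rows — held-out samples are transformed with training parameters, never
#' their own (no leakage). Zero-variance features are centered and left
#' unscaled (divisor 1).
#'
#' @param table a [feature_table()].
#' @param fit_idx nonempty sample index set on which parameters are fit.
#' @return list with `table` (transformed `nemtie_table`), `center`, `scale`.
#' @export
standardize_features <- function(table, fit_idx) {
  if (length(fit_idx) == 0L) stop("fit_idx must be nonempty", call. = FALSE)
  Xf <- table$X[fit_idx, , drop = FALSE]
  ctr <- colMeans(Xf)
  scl <- apply(Xf, 2L, stats::sd)
  if (nrow(Xf) == 1L) scl[] <- 0
  scl[!is.finite(scl) | scl == 0] <- 1
  X <- sweep(sweep(table$X, 2L, ctr), 2L, scl, "/")
  out <- table
  out$X <- X
  list(table = out, center = ctr, scale = scl)
}

#' Write standardization parameters as YAML
#'
#' @param std result of [standardize_features()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_standardization <- function(std, path) {
  yaml::write_yaml(list(center = as.list(std$center), scale = as.list(std$scale)), path)
  invisible(path)
}
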