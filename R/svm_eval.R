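#' SVM evaluator configuration
#'
#' The wrapped SVM used everywhere a module or feature set is scored:
#' linear kernel, cost 1, on train-standardized inputs by default. The
#' linear kernel is deliberate: the tuning objective contains a training
#' AUC term, and with a radial kernel that term rewards every added
#' dimension (kernel interpolation), which steers forward selection into
#' noise; a linear evaluator keeps the objective tied to linear
#' separability, consistent with the LDA criteria used elsewhere in the
#' workflow. `kernel = "radial"` restores a nonlinear evaluator.
#'
#' @param kernel e1071 kernel name (`"linear"` default).
#' @param cost soft-margin cost C.
#' @param gamma kernel width for nonlinear kernels; `NULL` = `1/ncol`.
#' @return object of class `nemtie_svm_config`.
#' @export
svm_config <- function(kernel = "linear", cost = 1, gamma = NULL) {
  structure(list(kernel = kernel, cost = cost, gamma = gamma),
            class = "nemtie_svm_config")
}

#' Fit the wrapped SVM on a feature subset and score every split
#'
#' Standardizes the chosen columns on the training rows (no leakage), fits
#' an SVM on the training split, and returns real-valued decision scores for
#' all samples, oriented so larger scores favor the positive (TMB-high)
#' class. Deterministic given data (no random component in C-classification
#' decision values).
#'
#' @param table a [feature_table()].
#' @param split a `nemtie_split`.
#' @param features feature names or indices (nonempty).
#' @param config a [svm_config()].
#' @return list: `scores` (length-m numeric), `model`, `features`, plus
#'   per-split score vectors `train`, `test`, `validation`.
#' @export
fit_svm_scores <- function(table, split, features, config = svm_config()) {
  if (length(features) == 0L) stop("feature set must be nonempty", call. = FALSE)
  if (is.character(features)) features <- match(features, table$feature_names)
  if (anyNA(features)) stop("unknown feature name", call. = FALSE)
  sub <- table$X[, features, drop = FALSE]
  tr <- split$train_idx
  ctr <- colMeans(sub[tr, , drop = FALSE])
  scl <- apply(sub[tr, , drop = FALSE], 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(sub, 2L, ctr), 2L, scl, "/")
  ytr <- factor(table$C[tr], levels = c(0, 1))
  if (length(unique(table$C[tr])) < 2L) {
    stop("training split contains a single class", call. = FALSE)
  }
  gamma <- config$gamma %||% (1 / ncol(Z))
  fit <- e1071::svm(x = Z[tr, , drop = FALSE], y = ytr,
                    kernel = config$kernel, cost = config$cost, gamma = gamma,
                    scale = FALSE)
  pr <- stats::predict(fit, Z, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  scores <- as.numeric(dv[, 1L])
  # e1071 orients decision values toward the first class in the column name
  pos_first <- startsWith(colnames(dv)[1L], "1")
  if (!pos_first) scores <- -scores
  list(scores = scores, model = fit, features = table$feature_names[features],
       train = scores[split$train_idx],
       test = scores[split$test_idx],
       validation = scores[split$validation_idx])
}

# per-split AUCs of an SVM fit on `features`
.svm_split_aucs <- function(table, split, features, config = svm_config()) {
  sc <- fit_svm_scores(table, split, features, config)
  c(train = auc_score(sc$train, table$C[split$train_idx]),
    test = auc_score(sc$test, table$C[split$test_idx]),
    validation = auc_score(sc$validation, table$C[split$validation_idx]))
}
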