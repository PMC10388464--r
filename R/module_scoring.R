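#' Fisher-type LDA score of a feature module
#'
#' The module criterion `Z = ||(mu+ - mu-)(mu+ - mu-)^T|| / ||s+ + s-||`
#' where `mu+`/`mu-` are the class mean vectors of the module's submatrix
#' and `s+`/`s-` are the per-class unbiased (n-1) per-feature scatter
#' vectors. Norms are Frobenius/Euclidean, so the rank-1 numerator equals
#' the squared Euclidean mean separation and the 1-feature case reduces to
#' the classic Fisher ratio `(mu+ - mu-)^2 / (var+ + var-)`. `Z` is
#' invariant under a common positive rescaling of the module's features and
#' under feature permutation within the module.
#'
#' @param submatrix numeric matrix, samples x module features.
#' @param labels binary 0/1 vector.
#' @param floor denominator floor guarding degenerate zero-scatter modules.
#' @return nonnegative scalar `Z`.
#' @export
#' @examples
#' lda_module_score(cbind(c(2, 4, 0, 2)), c(1, 1, 0, 0))  # = 1
lda_module_score <- function(submatrix, labels, floor = 1e-12) {
  X <- as.matrix(submatrix)
  pos <- labels == 1L
  n1 <- sum(pos)
  n2 <- sum(!pos)
  if (n1 < 2L || n2 < 2L) {
    stop("each class needs >= 2 samples for the unbiased scatter", call. = FALSE)
  }
  mu1 <- colMeans(X[pos, , drop = FALSE])
  mu2 <- colMeans(X[!pos, , drop = FALSE])
  dm <- mu1 - mu2
  num <- sum(dm^2)  # Frobenius norm of the rank-1 outer product
  s1 <- colSums(sweep(X[pos, , drop = FALSE], 2L, mu1)^2) / (n1 - 1)
  s2 <- colSums(sweep(X[!pos, , drop = FALSE], 2L, mu2)^2) / (n2 - 1)
  den <- sqrt(sum((s1 + s2)^2))
  num / max(den, floor)
}

#' Score and rank a module set
#'
#' Attaches the [lda_module_score()] `Z` of each module (computed on the
#' full table, or on a row subset via `rows`) and records the rank.
#'
#' @param modules a `nemtie_modules`.
#' @param table a [feature_table()].
#' @param rows optional sample indices to score on (e.g. the training split).
#' @return data.frame `(module_id, size, features, Z, rank)` ordered by
#'   module id; ranks are by decreasing `Z`, ties broken by module id.
#' @export
score_modules <- function(modules, table, rows = NULL) {
  rows <- rows %||% seq_along(table$C)
  subs <- modules_to_submatrices(table, modules)
  z <- vapply(subs, function(S) lda_module_score(S[rows, , drop = FALSE], table$C[rows]),
              numeric(1))
  df <- data.frame(
    module_id = vapply(modules$modules, `[[`, integer(1), "module_id"),
    size = lengths(module_features(modules)),
    features = vapply(module_features(modules), paste, character(1), collapse = ";"),
    Z = z, stringsAsFactors = FALSE)
  df$rank <- order(order(-df$Z, df$module_id))
  df
}

#' Refine a module set by its LDA score
#'
#' Ranks modules by `Z` descending (ties broken by module id, a stable
#' order) and keeps the top `keep`. The default keeps everything — ranking
#' is recorded and the downstream feature selector does the pruning.
#'
#' @param modules a `nemtie_modules`.
#' @param table a [feature_table()].
#' @param keep number of modules to retain (`Inf` = all) or a fraction in
#'   (0, 1) interpreted as the top quantile.
#' @param rows optional sample indices to score on.
#' @return a `nemtie_modules` restricted to the kept modules (ids
#'   renumbered in rank order), with the score table in attribute `scores`.
#' @export
refine_modules <- function(modules, table, keep = Inf, rows = NULL) {
  if (length(modules$modules) == 0L) stop("no modules to refine", call. = FALSE)
  if (!is.numeric(keep) || keep <= 0) stop("keep must be positive", call. = FALSE)
  sc <- score_modules(modules, table, rows)
  n_keep <- if (keep < 1) max(1L, ceiling(keep * nrow(sc))) else min(keep, nrow(sc))
  sel <- sc$module_id[order(sc$rank)][seq_len(n_keep)]
  kept <- modules$modules[sel]
  out <- structure(
    list(k = modules$k,
         modules = lapply(seq_along(kept), function(i) {
           list(module_id = i, features = kept[[i]]$features)
         })),
    class = "nemtie_modules"
  )
  attr(out, "scores") <- sc
  out
}

#' Per-module SVM evaluation report
#'
#' For each module, fits the wrapped SVM on the module's features alone
#' (training split) and reports AUC on train / test / validation plus their
#' arithmetic mean; modules whose three-split mean AUC strictly exceeds 0.8
#' are flagged significant.
#'
#' @param modules a `nemtie_modules`.
#' @param table a [feature_table()].
#' @param split a `nemtie_split`.
#' @param config a [svm_config()].
#' @param flag_threshold mean-AUC flag cutoff (strict `>`), default 0.8.
#' @return data.frame `(module_id, features, Z, auc_train, auc_test,
#'   auc_validation, auc_mean, flagged)`.
#' @export
per_module_svm_evaluation <- function(modules, table, split,
                                      config = svm_config(),
                                      flag_threshold = 0.8) {
  feats <- module_features(modules)
  sc <- score_modules(modules, table, rows = split$train_idx)
  rows <- lapply(seq_along(feats), function(i) {
    a <- .svm_split_aucs(table, split, feats[[i]], config)
    data.frame(module_id = i,
               features = paste(feats[[i]], collapse = ";"),
               Z = sc$Z[i],
               auc_train = a[["train"]], auc_test = a[["test"]],
               auc_validation = a[["validation"]],
               auc_mean = mean(a), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_id = integer(0), features = character(0), Z = numeric(0),
               auc_train = numeric(0), auc_test = numeric(0),
               auc_validation = numeric(0), auc_mean = numeric(0))
  out$flagged <- out$auc_mean > flag_threshold
  out
}
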