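#' Rank-based AUC
#'
#' Area under the ROC curve computed from the rank statistic (equivalent to
#' the trapezoid rule), with tied scores receiving half credit via average
#' ranks: the probability that a random positive outranks a random
#' negative.
#'
#' @param scores numeric decision scores, larger = more positive.
#' @param labels binary 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_score(c(0.9, 0.8, 0.3), c(1, 0, 1))  # 0.5
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics with stratified bootstrap confidence intervals
#'
#' AUC (rank method), sensitivity and specificity at the default decision
#' threshold 0 (`score > 0` predicts positive; `rule = "youden"` instead
#' picks the threshold maximizing sensitivity + specificity - 1 on the same
#' data). 95% CIs by stratified bootstrap percentile: positives and
#' negatives are resampled separately so every replicate is scoreable.
#'
#' @param scores numeric decision scores.
#' @param labels binary 0/1 labels.
#' @param rule `"zero"` (threshold 0) or `"youden"`.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return one-row data.frame: `auc`, `sensitivity`, `specificity` and
#'   `*_lo`/`*_hi` CI bounds for each.
#' @export
classification_metrics <- function(scores, labels, rule = c("zero", "youden"),
                                   n_boot = 2000L, seed = 1L, conf = 0.95) {
  rule <- match.arg(rule)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required", call. = FALSE)
  thr <- if (rule == "zero") 0 else {
    cand <- sort(unique(scores))
    cuts <- c(-Inf, (cand[-1] + cand[-length(cand)]) / 2)
    j <- vapply(cuts, function(t) {
      mean(scores[labels == 1L] > t) + mean(scores[labels == 0L] <= t) - 1
    }, numeric(1))
    cuts[which.max(j)]
  }
  point <- function(s, y) {
    c(auc = auc_score(s, y),
      sensitivity = mean(s[y == 1L] > thr),
      specificity = mean(s[y == 0L] <= thr))
  }
  est <- point(scores, labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      point(scores[idx], labels[idx])
    }, numeric(3))
  })
  a <- (1 - conf) / 2
  ci <- apply(boot, 1L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(auc = est[["auc"]], auc_lo = ci[1L, 1L], auc_hi = ci[2L, 1L],
             sensitivity = est[["sensitivity"]],
             sensitivity_lo = ci[1L, 2L], sensitivity_hi = ci[2L, 2L],
             specificity = est[["specificity"]],
             specificity_lo = ci[1L, 3L], specificity_hi = ci[2L, 3L],
             n_boot = n_boot)
}

#' ROC curve coordinates
#'
#' @param scores numeric decision scores.
#' @param labels binary 0/1 labels.
#' @return data.frame `(threshold, fpr, tpr)` suitable for plotting.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(cuts, function(t) {
    data.frame(threshold = t,
               fpr = mean(scores[labels == 0L] >= t),
               tpr = mean(scores[labels == 1L] >= t))
  }))
}

# equal-frequency discretization into `bins` levels (constant features
# collapse to one level); shared by the MI estimators
.discretize_ef <- function(x, bins = 4L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(qs) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

# plug-in mutual information (nats) of two discrete vectors
.mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Classic mRMR with the mutual-information-difference (MID) criterion on
#' equal-frequency discretized features (4 bins by default): the first
#' feature maximizes relevance `I(f; C)`, each next maximizes
#' `I(f; C) - mean_{s in selected} I(f; s)`. Relevance and redundancy are
#' estimated on the training rows only. Deterministic (ties break toward
#' the lower feature index).
#'
#' @param table a [feature_table()].
#' @param split optional `nemtie_split`; when given, only training rows are
#'   used for estimation.
#' @param n_select number of features to rank (`>= 1`).
#' @param bins discretization bins.
#' @return character vector of feature names in selection order.
#' @export
mrmr_select <- function(table, split = NULL, n_select, bins = 4L) {
  if (n_select <= 0L) stop("n_select must be positive", call. = FALSE)
  n <- ncol(table$X)
  if (n_select > n) stop("n_select exceeds feature count", call. = FALSE)
  rows <- if (is.null(split)) seq_along(table$C) else split$train_idx
  y <- table$C[rows]
  disc <- lapply(seq_len(n), function(j) .discretize_ef(table$X[rows, j], bins))
  rel <- vapply(disc, .mutual_information, numeric(1), b = y)
  selected <- integer(0)
  red_sum <- numeric(n)
  for (step in seq_len(n_select)) {
    rest <- setdiff(seq_len(n), selected)
    crit <- if (length(selected) == 0L) rel[rest] else
      rel[rest] - red_sum[rest] / length(selected)
    pick <- rest[which.max(crit)]
    selected <- c(selected, pick)
    if (step < n_select) {
      rest2 <- setdiff(seq_len(n), selected)
      add <- vapply(rest2, function(j) .mutual_information(disc[[j]], disc[[pick]]),
                    numeric(1))
      red_sum[rest2] <- red_sum[rest2] + add
    }
  }
  table$feature_names[selected]
}

#' Laplacian-score feature ranking
#'
#' Unsupervised locality-preservation ranking: a k-nearest-neighbour sample
#' graph with heat-kernel weights (bandwidth = median pairwise distance),
#' score `L_r = (f' L f) / (f' D f)` on the degree-centered feature; lower
#' scores preserve local structure better and rank first. Zero-variance
#' features are floored and ranked last.
#'
#' @param table a [feature_table()].
#' @param n_select number of features to return.
#' @param knn neighbourhood size (`< m`).
#' @return character vector of feature names, best first.
#' @export
laplacian_score_select <- function(table, n_select, knn = 5L) {
  m <- nrow(table$X)
  if (knn >= m) stop("knn must be smaller than the sample count", call. = FALSE)
  if (n_select <= 0L || n_select > ncol(table$X)) {
    stop("n_select out of range", call. = FALSE)
  }
  sds <- apply(table$X, 2L, stats::sd)
  Z <- sweep(sweep(table$X, 2L, colMeans(table$X)), 2L, ifelse(sds > 0, sds, 1), "/")
  Dm <- as.matrix(stats::dist(Z))
  sigma <- stats::median(Dm[upper.tri(Dm)])
  if (!is.finite(sigma) || sigma <= 0) stop("degenerate all-identical samples", call. = FALSE)
  W <- matrix(0, m, m)
  for (i in seq_len(m)) {
    nb <- order(Dm[i, ])[2:(knn + 1L)]
    W[i, nb] <- exp(-Dm[i, nb]^2 / sigma^2)
  }
  W <- pmax(W, t(W))  # symmetrize: connected if either end is a neighbour
  d <- rowSums(W)
  score <- vapply(seq_len(ncol(table$X)), function(j) {
    f <- table$X[, j]
    ft <- f - sum(f * d) / sum(d)
    den <- sum(ft^2 * d)
    if (den < 1e-12) return(Inf)
    num <- sum(ft * (d * ft - as.vector(W %*% ft)))  # f' L f with L = D - W
    num / den
  }, numeric(1))
  table$feature_names[order(score)][seq_len(n_select)]
}

#' Storey positive-FDR q-values
#'
#' Estimates the null proportion `pi0` on a lambda grid
#' (`#\{p > lambda\} / (m (1 - lambda))`, smoothed by a cubic spline and
#' evaluated at the largest lambda), then
#' `q_i = min_{p_j >= p_i} pi0 * m * p_j / rank(p_j)` — monotone in the
#' p-value ordering by construction.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param lambda grid for the pi0 estimate.
#' @return q-values in `[0, 1]`, same order as `p`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < 10L || length(unique(p)) < 4L) {
    pi0 <- 1  # too few tests to estimate the null proportion
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- try(stats::smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
    pi0 <- if (inherits(fit, "try-error")) min(pi0_l[length(pi0_l)], 1) else
      stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-3), 1)
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- 1
  for (i in ord) {
    running <- min(running, pi0 * m * p[i] / sum(p <= p[i]))
    q[i] <- running
  }
  q
}

#' Per-feature Pearson association with the label
#'
#' Pearson correlation of each feature against the binary label (the
#' point-biserial correlation), two-sided p-value from [stats::cor.test()],
#' and Storey positive-FDR q-values across the tested family. Zero-variance
#' features are reported with `r = 0`, `p = 1` and flagged.
#'
#' @param table a [feature_table()].
#' @param features optional subset (names or indices); default all.
#' @param labels optional label override; default the table's `C`.
#' @return data.frame `(feature_name, pearson_r, p_value, q_value,
#'   degenerate)`.
#' @export
pearson_pfdr <- function(table, features = NULL, labels = NULL) {
  if (is.character(features)) features <- match(features, table$feature_names)
  features <- features %||% seq_along(table$feature_names)
  y <- as.numeric(labels %||% table$C)
  if (length(y) < 3L) stop("need at least 3 samples", call. = FALSE)
  res <- lapply(features, function(j) {
    x <- table$X[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(r = 0, p = 1, degen = 1))
    }
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    c(r = unname(ct$estimate), p = ct$p.value, degen = 0)
  })
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(feature_name = table$feature_names[features],
             pearson_r = r, p_value = p,
             q_value = storey_qvalue(p),
             degenerate = vapply(res, `[[`, numeric(1), "degen") == 1,
             stringsAsFactors = FALSE)
}

#' Baseline selector-classifier wrappers
#'
#' Method functions with the common signature `(table, split)` returning
#' the test-split AUC, for use with [compare_methods_resampled()]:
#' the network-evolution pipeline, mRMR + SVM, and Laplacian score + SVM.
#'
#' @param n_select features the baseline selectors keep.
#' @param ... forwarded to [nemtie_select()].
#' @return a function `(table, split) -> test AUC`.
#' @export
#' @rdname method_wrappers
method_nemtie <- function(...) {
  args <- list(...)
  function(table, split) {
    res <- do.call(nemtie_select, c(list(table = table, split = split,
                                         n_boot = 50L), args))
    if (is.null(res$final)) return(0.5)
    auc_score(res$final$scores$test, table$C[split$test_idx])
  }
}

#' @export
#' @rdname method_wrappers
method_mrmr_svm <- function(n_select = 10L) {
  function(table, split) {
    feats <- mrmr_select(table, split, n_select = n_select)
    a <- .svm_split_aucs(table, split, feats)
    a[["test"]]
  }
}

#' @export
#' @rdname method_wrappers
method_laplacian_svm <- function(n_select = 10L) {
  function(table, split) {
    feats <- laplacian_score_select(table, n_select = n_select)
    a <- .svm_split_aucs(table, split, feats)
    a[["test"]]
  }
}

#' Resampled paired comparison of methods
#'
#' Re-splits the cohort `n_resamples` times (70/20/10 by default), runs each
#' method on the shared splits, and compares every method pair with a
#' paired t-test on the per-resample test AUCs (paired because the splits
#' are shared). Zero-variance difference vectors are guarded with a small
#' epsilon so a constant offset still yields a finite, extreme t. A method
#' failure on a resample drops that resample pairwise and is recorded.
#'
#' @param table a [feature_table()].
#' @param methods named list of functions `(table, split) -> test AUC`.
#' @param n_resamples number of random re-splits (default 10).
#' @param ratios split ratios.
#' @param sides `"two"` or `"one"` (one-sided: first method greater).
#' @param seed integer seed; resample split seeds derive from it.
#' @return list `auc` (resample x method data.frame), `tests` (data.frame
#'   `method_a, method_b, t, p, n_used`), `failures`.
#' @export
compare_methods_resampled <- function(table, methods, n_resamples = 10L,
                                      ratios = c(0.70, 0.20, 0.10),
                                      sides = c("two", "one"), seed = 1L) {
  sides <- match.arg(sides)
  if (n_resamples < 2L) stop("need at least 2 resamples", call. = FALSE)
  stopifnot(length(names(methods)) == length(methods))
  seeds <- derive_seeds(seed, paste0("resample", seq_len(n_resamples)))
  auc <- matrix(NA_real_, n_resamples, length(methods),
                dimnames = list(NULL, names(methods)))
  failures <- character(0)
  for (r in seq_len(n_resamples)) {
    sp <- split_cohort(table, ratios, seed = seeds[r])
    for (mname in names(methods)) {
      v <- try(methods[[mname]](table, sp), silent = TRUE)
      if (inherits(v, "try-error") || !is.finite(v)) {
        failures <- c(failures, sprintf("%s@resample%d", mname, r))
      } else {
        auc[r, mname] <- v
      }
    }
  }
  pairs <- utils::combn(names(methods), 2L, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    ok <- stats::complete.cases(auc[, pr, drop = FALSE])
    d <- auc[ok, pr[1L]] - auc[ok, pr[2L]]
    n <- length(d)
    if (n < 2L) {
      return(data.frame(method_a = pr[1L], method_b = pr[2L], t = NA_real_,
                        p = NA_real_, n_used = n, stringsAsFactors = FALSE))
    }
    sd_d <- stats::sd(d)
    if (!is.finite(sd_d) || sd_d < 1e-12) sd_d <- 1e-12
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- if (sides == "two") 2 * stats::pt(-abs(t_stat), df = n - 1) else
      stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
    data.frame(method_a = pr[1L], method_b = pr[2L], t = t_stat, p = min(p, 1),
               n_used = n, stringsAsFactors = FALSE)
  }))
  list(auc = as.data.frame(auc), tests = tests, failures = failures)
}
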