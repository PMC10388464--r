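test_that("rank AUC matches exhaustive pair counting, including ties", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_equal(auc_score(1:10, rep(c(0, 1), each = 5)), 1)
  expect_equal(auc_score(10:1, rep(c(0, 1), each = 5)), 0)
  set.seed(19)
  for (rep in 1:25) {
    m <- sample(4:50, 1)
    y <- c(1, 0, rbinom(m - 2, 1, 0.4))
    s <- round(rnorm(m), sample(0:1, 1))  # rounding forces ties
    expect_equal(auc_score(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("classification metrics report operating point and bootstrap CIs", {
  y <- rep(c(0L, 1L), each = 10)
  s <- ifelse(y == 1L, 1, -1) + rnorm(20, sd = 0.01)
  m <- classification_metrics(s, y, n_boot = 200, seed = 3)
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_true(m$auc_lo <= m$auc && m$auc <= m$auc_hi)
  expect_true(m$sensitivity_lo <= m$sensitivity)
  expect_true(m$specificity_lo <= m$specificity)
  inv <- classification_metrics(-s, y, n_boot = 50, seed = 3)
  expect_equal(inv$auc, 0)
  # Youden rule recovers a shifted operating point
  m2 <- classification_metrics(s + 10, y, rule = "youden", n_boot = 50, seed = 1)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 1)
})

test_that("bootstrap CIs are stable under more replicates", {
  set.seed(8)
  y <- rbinom(80, 1, 0.4)
  y[1:2] <- c(0L, 1L)
  s <- rnorm(80, 1.2 * y)
  m1 <- classification_metrics(s, y, n_boot = 200, seed = 5)
  m2 <- classification_metrics(s, y, n_boot = 2000, seed = 5)
  expect_lt(abs(m1$auc_lo - m2$auc_lo), 0.02)
  expect_lt(abs(m1$auc_hi - m2$auc_hi), 0.02)
})

test_that("mRMR ranks relevance first and penalizes redundancy", {
  set.seed(23)
  m <- 120
  y <- rep(c(0L, 1L), each = m / 2)
  f1 <- rnorm(m, 2 * y, 0.3)
  f3 <- rnorm(m, 2 * y, 0.3)  # equally relevant, independent of f1 given y
  tab <- feature_table(cbind(f1, f1, f3, rnorm(m)), y,
                       feature_names = c("f1", "f1_dup", "f3", "noise"))
  ranked <- mrmr_select(tab, n_select = 4)
  expect_true(ranked[1] %in% c("f1", "f1_dup"))
  # the exact duplicate of the leader ranks below the equally relevant
  # independent copy, and dead last overall
  expect_gt(match("f1_dup", ranked), match("f3", ranked))
  expect_equal(ranked[4], "f1_dup")
  # a feature identical to the label ranks first
  tab2 <- feature_table(cbind(rnorm(m), as.numeric(y), rnorm(m)), y,
                        feature_names = c("a", "oracle", "b"))
  expect_equal(mrmr_select(tab2, n_select = 1), "oracle")
  # deterministic
  expect_identical(ranked, mrmr_select(tab, n_select = 4))
  expect_error(mrmr_select(tab, n_select = 0), "positive")
})

test_that("Laplacian score prefers cluster structure and buries constants", {
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    m <- 80
    cl <- rep(c(0, 1), each = m / 2)
    sep <- rnorm(m, 4 * cl, 0.5)   # separates the two tight clusters
    tab <- feature_table(cbind(sep, rnorm(m), rnorm(m), rep(1, m)),
                         c(rep(0L, m / 2), rep(1L, m / 2)),
                         feature_names = c("sep", "w1", "w2", "const"))
    ranked <- laplacian_score_select(tab, n_select = 4)
    ranked[1] == "sep" && ranked[4] == "const"
  }, logical(1))
  expect_gte(sum(wins), 8L)
  # invariant to feature order permutation
  set.seed(2)
  X <- matrix(rnorm(40 * 5), 40, 5)
  tab <- feature_table(X, rep(c(0L, 1L), 20), feature_names = paste0("f", 1:5))
  perm <- c(3, 1, 5, 2, 4)
  tabp <- feature_table(X[, perm], tab$C, feature_names = paste0("f", perm))
  expect_setequal(laplacian_score_select(tab, 5),
                  laplacian_score_select(tabp, 5))
  expect_identical(laplacian_score_select(tab, 5)[1],
                   laplacian_score_select(tabp, 5)[1])
})

test_that("Pearson association reports r, p and monotone q-values", {
  set.seed(3)
  m <- 80
  y <- rep(c(0L, 1L), each = m / 2)
  tab <- feature_table(cbind(as.numeric(y), rnorm(m), rep(2, m)), y,
                       feature_names = c("oracle", "noise", "flat"))
  rep_tab <- pearson_pfdr(tab)
  expect_equal(rep_tab$pearson_r[1], 1, tolerance = 1e-12)
  expect_lt(rep_tab$p_value[1], 1e-10)
  expect_true(rep_tab$degenerate[3])
  expect_equal(rep_tab$pearson_r[3], 0)
  expect_equal(rep_tab$p_value[3], 1)
  # q-values preserve the p-value ordering
  set.seed(4)
  X <- matrix(rnorm(60 * 40), 60, 40)
  X[, 1] <- X[, 1] + 2 * rep(c(0, 1), each = 30)
  tab2 <- feature_table(X, rep(c(0L, 1L), each = 30))
  r2 <- pearson_pfdr(tab2)
  ord <- order(r2$p_value)
  expect_true(all(diff(r2$q_value[ord]) >= -1e-12))
  expect_true(all(r2$q_value >= 0 & r2$q_value <= 1))
})

test_that("resampled method comparison computes paired t-tests with guards", {
  tab <- toy_table(m = 60, seed = 5)
  base <- function(table, split) {
    set.seed(split$seed)
    runif(1, 0.6, 0.8)
  }
  same <- list(A = base, B = base)
  outA <- compare_methods_resampled(tab, same, n_resamples = 6,
                                    ratios = c(0.6, 0.2, 0.2), seed = 2)
  expect_equal(outA$tests$t, 0)
  expect_equal(outA$tests$p, 1)
  shifted <- list(A = function(table, split) base(table, split) + 0.1, B = base)
  outB <- compare_methods_resampled(tab, shifted, n_resamples = 10,
                                    ratios = c(0.6, 0.2, 0.2), seed = 2)
  expect_lt(outB$tests$p, 0.01)
  # one-sided p is half the two-sided p when t > 0
  outC <- compare_methods_resampled(tab, shifted, n_resamples = 10,
                                    ratios = c(0.6, 0.2, 0.2), sides = "one", seed = 2)
  expect_equal(outC$tests$p, outB$tests$p / 2, tolerance = 1e-12)
  # a failing method is dropped pairwise and recorded
  flaky <- list(A = base, B = function(table, split) stop("boom"))
  outD <- compare_methods_resampled(tab, flaky, n_resamples = 4,
                                    ratios = c(0.6, 0.2, 0.2), seed = 3)
  expect_length(outD$failures, 4L)
  expect_equal(outD$tests$n_used, 0L)
})

test_that("paired comparison holds its nominal type-I error under the null", {
  set.seed(61)
  tab <- toy_table(m = 40, seed = 1)
  rejections <- vapply(1:200, function(rep) {
    null_method <- function(offset) {
      force(offset)
      function(table, split) {
        set.seed(split$seed + offset)
        runif(1, 0.4, 0.6)
      }
    }
    out <- compare_methods_resampled(tab, list(A = null_method(0), B = null_method(1000)),
                                     n_resamples = 10,
                                     ratios = c(0.6, 0.2, 0.2), seed = rep)
    out$tests$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.12)
})

test_that("baseline selector-SVM wrappers return scoreable test AUCs", {
  g <- generate_synthetic(small_scenario(seed = 4))
  sp <- split_cohort(g$table, seed = 3)
  a_m <- method_mrmr_svm(n_select = 5)(g$table, sp)
  a_l <- method_laplacian_svm(n_select = 5)(g$table, sp)
  expect_true(a_m >= 0 && a_m <= 1)
  expect_true(a_l >= 0 && a_l <= 1)
})
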