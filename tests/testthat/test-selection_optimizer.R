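test_that("composite objective is the exact convex combination", {
  expect_equal(composite_auc_loss(1.0, 0.5), 0.75)
  expect_equal(composite_auc_loss(0.9, 0.1, loss_config(1, 0)), 0.9)
  for (x in c(0, 0.3, 0.77, 1)) expect_equal(composite_auc_loss(x, x), x)
  expect_error(composite_auc_loss(1.2, 0.5), "\\[0, 1\\]")
  expect_error(loss_config(0.7, 0.7), "equal 1")
  expect_error(loss_config(-0.1, 1.1), "nonnegative")
})

test_that("PSO recovers an analytic optimum and reports a monotone trace", {
  cfg <- pso_config(n_particles = 20L, n_iterations = 100L, seed = 42)
  out <- pso_optimize(function(x) -(x - 0.3)^2, cfg)
  expect_lt(abs(out$T_star - 0.3), 1e-3)
  expect_true(all(diff(out$trace) >= 0))
  # deterministic under the seed
  out2 <- pso_optimize(function(x) -(x - 0.3)^2, cfg)
  expect_identical(out$T_star, out2$T_star)
  # constant objective: any point in bounds, flat trace
  flat <- pso_optimize(function(x) 1, cfg)
  expect_true(flat$T_star >= 0 && flat$T_star <= 1)
  expect_equal(unique(flat$trace), 1)
  expect_error(pso_optimize(function(x) NA_real_, cfg), "non-finite")
})

test_that("threshold evaluation handles empty, informative and dense regimes", {
  g <- generate_synthetic(small_scenario(seed = 5))
  sp <- split_cohort(g$table, seed = 2)
  net <- normalize_adjacency(build_entropy_network(g$table, cv_protocol(seed = 3)))
  # T = 1: empty graph scores as chance
  empty <- evaluate_threshold(1, g$table, sp, net)
  expect_equal(empty$loss, 0.5)
  expect_length(empty$features, 0L)
  # an ultra-dense candidate trips the density guard and scores as chance
  dense <- evaluate_threshold(0, g$table, sp, net, max_mean_degree = 2)
  expect_equal(dense$loss, 0.5)
  expect_true(all(vapply(seq(0.3, 0.9, by = 0.1), function(T) {
    l <- evaluate_threshold(T, g$table, sp, net)$loss
    l >= 0 && l <= 1
  }, logical(1))))
  # at the full default study conditions some threshold isolates the planted
  # structure with a high objective
  gd <- generate_synthetic(default_scenario(seed = 1))
  spd <- split_cohort(gd$table, seed = 2)
  netd <- normalize_adjacency(build_entropy_network(gd$table, cv_protocol(seed = 3)))
  losses <- vapply(seq(0.35, 0.75, by = 0.05), function(T) {
    evaluate_threshold(T, gd$table, spd, netd)$loss
  }, numeric(1))
  expect_gt(max(losses), 0.9)
})

test_that("greedy selection finds perfect features, skips duplicates, improves strictly", {
  set.seed(14)
  m <- 60
  y <- rep(c(0L, 1L), each = m / 2)
  X <- cbind(as.numeric(y), as.numeric(y), rnorm(m), rnorm(m))
  tab <- feature_table(X, y, feature_names = c("oracle", "oracle_dup", "n1", "n2"))
  sp <- split_cohort(tab, c(0.6, 0.2, 0.2), seed = 4)
  out <- greedy_feature_subset(tab$feature_names, tab, sp)
  expect_equal(out$features[1], "oracle")
  # the exact duplicate never improves the objective, so it is never added
  expect_false("oracle_dup" %in% out$features)
  expect_true(all(diff(c(0, out$trace)) > 0))
  # the perfect feature drives training misclassification to zero
  sc <- fit_svm_scores(tab, sp, out$features)
  expect_equal(sum((sc$train > 0) != (tab$C[sp$train_idx] == 1L)), 0L)
  expect_error(greedy_feature_subset(character(0), tab, sp), "nonempty")
  # exhaustive audit on a small candidate set can only match or beat greedy
  ex <- greedy_feature_subset(tab$feature_names, tab, sp, exhaustive = TRUE)
  expect_gte(ex$loss, out$loss - 1e-12)
})

test_that("final model is deterministic, separates separable data, nulls out permuted labels", {
  tab <- toy_table(m = 60, seed = 3, delta = 3)
  sp <- split_cohort(tab, c(0.6, 0.2, 0.2), seed = 6)
  f1 <- fit_final_model(tab, sp, c("sig1", "sig2"), n_boot = 100, seed = 9)
  expect_equal(f1$metrics$auc[f1$metrics$split == "train"], 1)
  f2 <- fit_final_model(tab, sp, c("sig1", "sig2"), n_boot = 100, seed = 9)
  expect_identical(f1$scores$scores, f2$scores$scores)
  expect_identical(f1$metrics, f2$metrics)
  # permuted labels: held-out AUC near chance on average
  null_aucs <- vapply(1:6, function(s) {
    set.seed(s)
    tabp <- feature_table(tab$X, sample(tab$C), feature_names = tab$feature_names)
    spp <- split_cohort(tabp, c(0.6, 0.2, 0.2), seed = s)
    fit <- fit_svm_scores(tabp, spp, c("sig1", "sig2"))
    auc_score(fit$test, tabp$C[spp$test_idx])
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.15)
})

test_that("end-to-end selection is reproducible and honors the module constraint", {
  g <- generate_synthetic(small_scenario(seed = 8))
  res <- nemtie_select(g$table, seed = 77, n_boot = 50)
  res2 <- nemtie_select(g$table, seed = 77, n_boot = 50)
  expect_identical(res$T_star, res2$T_star)
  expect_identical(res$selected_features, res2$selected_features)
  expect_identical(res$final$metrics, res2$final$metrics)
  # every selected feature traces back to a module at T*
  union_feats <- unique(unlist(module_features(res$modules_used)))
  expect_true(all(res$selected_features %in% union_feats))
  expect_true(all(diff(res$loss_trace) >= 0))
  expect_true(all(diff(c(0, res$greedy_trace)) > 0))
})

test_that("holdout tuning keeps the outer test split out of the objective", {
  g <- generate_synthetic(small_scenario(seed = 9))
  res <- nemtie_select(g$table, seed = 31, n_boot = 50, holdout_tuning = TRUE)
  expect_s3_class(res, "nemtie_selection")
  expect_true(res$holdout_tuning)
  # reported split is the outer one: 70/20/10 of 80 samples
  expect_equal(length(res$split$test_idx), 16L)
})
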