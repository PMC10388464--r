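test_that("pointwise information gain matches hand computation", {
  expect_equal(pair_information_gain(0.5, 0.5, 1.0), log(4), tolerance = 1e-12)
  expect_identical(pair_information_gain(0.6, 0.5, 0.3), 0.3 * log(1))
  expect_equal(pair_information_gain(0.6, 0.7, 0.9), 0.9 * log(0.9 / 0.42),
               tolerance = 1e-12)
  expect_error(pair_information_gain(0, 0.5, 0.5), "\\(0, 1\\]")
  expect_error(pair_information_gain(0.5, 0.5, 1.2), "\\(0, 1\\]")
})

test_that("LDA accuracy probe behaves on separable, noise and augmented inputs", {
  set.seed(4)
  m <- 100
  y <- rep(c(0L, 1L), each = m / 2)
  tab <- feature_table(cbind(as.numeric(y), rep(1, m), rnorm(m)), y,
                       feature_names = c("perfect", "const", "noise"))
  cvp <- cv_protocol(seed = 2)
  expect_equal(lda_accuracy(tab, "perfect", cvp), 1.0)
  # constant feature, balanced classes: chance within CV noise
  expect_lt(abs(lda_accuracy(tab, "const", cvp) - 0.5), 0.1)
  # a perfect feature stays perfect when a noise feature is added
  expect_equal(lda_accuracy(tab, c("perfect", "noise"), cvp), 1.0)
  expect_error(lda_accuracy(tab, "nope", cvp), "1 or 2")
})

test_that("internal pooled-covariance LDA agrees with MASS::lda on well-posed data", {
  skip_if_not_installed("MASS")
  set.seed(9)
  m <- 60
  y <- rep(c(0L, 1L), each = m / 2)
  X <- cbind(rnorm(m, 1.2 * y), rnorm(m, -0.8 * y) + 0.3 * rnorm(m))
  tr <- sort(sample(m, 40))
  te <- setdiff(seq_len(m), tr)
  ours <- nemtie:::.lda_predict(X[tr, ], y[tr], X[te, ])
  fit <- MASS::lda(X[tr, ], grouping = y[tr])
  theirs <- as.integer(as.character(predict(fit, X[te, ])$class))
  expect_equal(ours, theirs)
})

test_that("vectorized pair matrix equals the scalar accuracy probe", {
  g <- generate_synthetic(small_scenario(seed = 6))
  tab <- subset_table(g$table, features = 1:8)
  cvp <- cv_protocol(seed = 13)
  net <- build_entropy_network(tab, cvp)
  for (j in 1:7) {
    for (k in (j + 1):8) {
      p_jk <- lda_accuracy(tab, c(j, k), cvp)
      expect_equal(net$E[j, k],
                   unname(pair_information_gain(net$p_single[[j]],
                                                net$p_single[[k]], p_jk)),
                   tolerance = 1e-10)
    }
  }
  expect_equal(net$p_single[3], lda_accuracy(tab, 3, cvp), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("information-gain matrix is symmetric with zero diagonal and caches singles", {
  g <- generate_synthetic(small_scenario(seed = 2))
  tab <- subset_table(g$table, features = 1:12)
  net <- build_entropy_network(tab, cv_protocol(seed = 3))
  expect_identical(net$E, t(net$E))
  expect_equal(unname(diag(net$E)), rep(0, 12))
  expect_length(net$p_single, 12L)
  expect_true(all(net$p_single >= 1e-6 & net$p_single <= 1))
  expect_error(build_entropy_network(subset_table(tab, features = 1)), "at least 2")
})

test_that("a duplicated perfect feature contributes zero gain", {
  y <- rep(c(0L, 1L), each = 20)
  tab <- feature_table(cbind(as.numeric(y), as.numeric(y), rnorm(40)), y,
                       feature_names = c("p1", "p2", "noise"))
  net <- build_entropy_network(tab, cv_protocol(seed = 1))
  # p_x = p_y = p_xy = 1, so E = 1 * log(1) = 0
  expect_equal(net$E["p1", "p2"], 0, tolerance = 1e-12)
  # general duplicate relationship: joint accuracy equals the single accuracy
  cvp <- cv_protocol(seed = 5)
  set.seed(8)
  weak <- rnorm(40, 0.8 * y)
  tab2 <- feature_table(cbind(weak, weak, rnorm(40)), y,
                        feature_names = c("w1", "w2", "noise"))
  expect_equal(lda_accuracy(tab2, c("w1", "w2"), cvp),
               lda_accuracy(tab2, "w1", cvp), tolerance = 1e-12)
})

test_that("min-max normalization maps extremes to 0 and 1 and degenerates to zero", {
  net <- structure(list(feature_names = c("a", "b", "c"),
                        p_single = c(a = .5, b = .5, c = .5),
                        E = matrix(c(0, -1, 0, -1, 0, 3, 0, 3, 0), 3, 3,
                                   dimnames = list(c("a","b","c"), c("a","b","c"))),
                        R = NULL, protocol = cv_protocol()),
                   class = "nemtie_network")
  out <- normalize_adjacency(net)
  expect_equal(out$R["a", "b"], 0)
  expect_equal(out$R["a", "c"], 0.25)
  expect_equal(out$R["b", "c"], 1)
  expect_equal(unname(diag(out$R)), rep(0, 3))

  net$E[] <- 2
  diag(net$E) <- 0
  net$E["a", "b"] <- net$E["b", "a"] <- 2
  net$E[upper.tri(net$E)] <- 2
  net$E[lower.tri(net$E)] <- 2
  out2 <- normalize_adjacency(net)
  expect_true(all(out2$R == 0))
})

test_that("thresholding is strict, monotone and respects bounds", {
  A <- random_weighted_graph(12, 0.5, seed = 3)
  A <- A / max(A)
  net <- structure(list(R = A), class = "nemtie_network")
  g1 <- threshold_graph(net, 1)
  expect_equal(igraph::ecount(g1), 0)
  g0 <- threshold_graph(net, 0)
  expect_equal(igraph::ecount(g0), sum(A[upper.tri(A)] > 0))
  for (pair in list(c(0.2, 0.5), c(0.4, 0.9), c(0.1, 0.15))) {
    lo <- igraph::as_edgelist(threshold_graph(net, pair[1]))
    hi <- igraph::as_edgelist(threshold_graph(net, pair[2]))
    key <- function(e) paste(e[, 1], e[, 2])
    expect_true(all(key(hi) %in% key(lo)))
  }
  expect_error(threshold_graph(net, 1.2), "\\[0, 1\\]")
})

test_that("degrees report the thresholded topology", {
  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  expect_equal(unname(feature_degrees(tri)), c(2, 2, 2))
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  expect_equal(unname(feature_degrees(star)), c(3, 1, 1, 1))
  iso <- igraph::make_graph(~ a - b, b - c, c - a) + igraph::vertices("z")
  expect_equal(feature_degrees(iso)[["z"]], 0)
})

test_that("network matrices and graph export to CSV and GraphML", {
  g <- generate_synthetic(small_scenario(seed = 4))
  tab <- subset_table(g$table, features = 1:10)
  net <- normalize_adjacency(build_entropy_network(tab, cv_protocol(seed = 1)))
  dir <- withr::local_tempdir()
  paths <- write_network(net, T = 0.5, dir = dir)
  expect_true(all(file.exists(paths)))
  R_back <- as.matrix(read.csv(file.path(dir, "adjacency_R.csv"), row.names = 1))
  expect_equal(unname(R_back), unname(net$R), tolerance = 1e-6)
})
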