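# Independent oracles and shared fixtures for the suite. These deliberately
# use brute-force constructions so they share no code path with the package.

# Brute-force k-clique percolation: enumerate every k-subset, keep the fully
# connected ones, link cliques sharing exactly >= k-1 vertices, and merge
# connected components by fixed-point iteration. Returns a sorted list of
# sorted vertex-name sets.
oracle_clique_percolation <- function(graph, k) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  vn <- igraph::V(graph)$name
  if (is.null(vn)) vn <- as.character(seq_len(nrow(A)))
  n <- nrow(A)
  if (n < k) return(list())
  cl <- Filter(function(s) all(A[s, s][upper.tri(A[s, s])] == 1),
               utils::combn(n, k, simplify = FALSE))
  if (length(cl) == 0L) return(list())
  comp <- seq_along(cl)
  repeat {
    changed <- FALSE
    for (i in seq_along(cl)) {
      for (j in seq_along(cl)) {
        if (comp[i] != comp[j] &&
            length(intersect(cl[[i]], cl[[j]])) >= k - 1L) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(comp), function(cc) {
    sort(vn[sort(unique(unlist(cl[comp == cc])))])
  })
  out[order(vapply(out, paste, character(1), collapse = ","))]
}

# canonical form of a package module set for comparison with the oracle
modules_canonical <- function(mods) {
  out <- lapply(nemtie::module_features(mods), sort)
  out[order(vapply(out, paste, character(1), collapse = ","))]
}

# Exhaustive concordant-pair AUC: loop every (positive, negative) pair.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small labeled table: two informative features + noise, both classes present
toy_table <- function(m = 40, n_noise = 3, seed = 1, delta = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = m)
  X <- cbind(rnorm(m, delta * y), rnorm(m, delta * y),
             matrix(rnorm(m * n_noise), m, n_noise))
  feature_table(X, y, feature_names = c("sig1", "sig2", paste0("noise", seq_len(n_noise))))
}

# a small synthetic scenario that keeps end-to-end tests fast
small_scenario <- function(seed = 1, delta = 1.5) {
  synthetic_spec(m = 80, n_noise = 30,
                 blocks = list(c(size = 5, rho = 0.5)),
                 informative_block = c(size = 3, delta = delta, rho = 0.6),
                 clinical_pos = c(0.6, 0.2), clinical_neg = c(0.2, 0.5),
                 prevalence = 0.35, seed = seed)
}

random_weighted_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- (runif(n * (n - 1) / 2) < p) * runif(n * (n - 1) / 2)
  A <- A + t(A)
  dimnames(A) <- list(paste0("v", 1:n), paste0("v", 1:n))
  A
}
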