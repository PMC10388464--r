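#' Composite AUC loss configuration
#'
#' Weights of the tuning objective `alpha * AUC_train + beta * AUC_test`
#' (the optimizer maximizes it). Defaults `alpha = beta = 1/2`.
#'
#' @param alpha,beta nonnegative weights summing to 1.
#' @return object of class `nemtie_loss_config`.
#' @export
loss_config <- function(alpha = 0.5, beta = 0.5) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be nonnegative", call. = FALSE)
  if (abs(alpha + beta - 1) > 1e-9) stop("alpha + beta must equal 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "nemtie_loss_config")
}

#' Composite AUC tuning objective
#'
#' `alpha * auc_train + beta * auc_test`. Note the test split enters the
#' tuning objective by design of the method being implemented; see
#' [nemtie_select()]'s `holdout_tuning` for the leakage-free variant.
#'
#' @param auc_train,auc_test AUCs in `[0, 1]`.
#' @param config a [loss_config()].
#' @return numeric objective value.
#' @export
composite_auc_loss <- function(auc_train, auc_test, config = loss_config()) {
  if (any(c(auc_train, auc_test) < 0) || any(c(auc_train, auc_test) > 1)) {
    stop("AUCs must lie in [0, 1]", call. = FALSE)
  }
  config$alpha * auc_train + config$beta * auc_test
}

#' Particle swarm optimizer configuration
#'
#' Canonical global-best PSO on `[0, 1]` with inertia `a = 0.8` and
#' acceleration coefficients `c1 = c2 = 1.49445` (the study's printed
#' settings); swarm size 20 and 100 iterations by default.
#'
#' @param inertia inertia weight `a`.
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param n_particles swarm size (`>= 2`).
#' @param n_iterations iteration count.
#' @param seed integer seed; the optimizer is deterministic given it.
#' @return object of class `nemtie_pso_config`.
#' @export
pso_config <- function(inertia = 0.8, c1 = 1.49445, c2 = 1.49445,
                       n_particles = 20L, n_iterations = 100L, seed = 1L) {
  if (n_particles < 2L) stop("need at least 2 particles", call. = FALSE)
  structure(list(inertia = inertia, c1 = c1, c2 = c2,
                 n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "nemtie_pso_config")
}

#' Maximize a scalar objective on [0, 1] by particle swarm
#'
#' Velocity update `v <- a*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`;
#' positions are clamped to `[0, 1]` after each move. Returns the best-ever
#' position and the per-iteration global-best trace (non-decreasing by
#' construction).
#'
#' @param objective function of one numeric argument returning a finite
#'   scalar to maximize.
#' @param config a [pso_config()].
#' @return list `T_star`, `value`, `trace` (length `n_iterations`).
#' @export
#' @examples
#' pso_optimize(function(x) -(x - 0.3)^2, pso_config(seed = 1))$T_star
pso_optimize <- function(objective, config = pso_config()) {
  np <- config$n_particles
  with_seed(config$seed, {
    x <- stats::runif(np)
    v <- stats::runif(np, -0.1, 0.1)
    val <- vapply(x, objective, numeric(1))
    if (any(!is.finite(val))) stop("objective returned a non-finite value", call. = FALSE)
    pbest_x <- x
    pbest_v <- val
    g <- which.max(val)
    gbest_x <- x[g]
    gbest_v <- val[g]
    trace <- numeric(config$n_iterations)
    for (it in seq_len(config$n_iterations)) {
      r1 <- stats::runif(np)
      r2 <- stats::runif(np)
      v <- config$inertia * v +
        config$c1 * r1 * (pbest_x - x) +
        config$c2 * r2 * (gbest_x - x)
      x <- pmin(pmax(x + v, 0), 1)
      val <- vapply(x, objective, numeric(1))
      if (any(!is.finite(val))) stop("objective returned a non-finite value", call. = FALSE)
      imp <- val > pbest_v
      pbest_x[imp] <- x[imp]
      pbest_v[imp] <- val[imp]
      g <- which.max(pbest_v)
      if (pbest_v[g] > gbest_v) {
        gbest_v <- pbest_v[g]
        gbest_x <- pbest_x[g]
      }
      trace[it] <- gbest_v
    }
    list(T_star = gbest_x, value = gbest_v, trace = trace)
  })
}

#' Evaluate one adjacency threshold
#'
#' The inner step of the outer tuning loop: threshold the adjacency at `T`,
#' mine k-clique-percolation modules, take the union of module features,
#' fit the wrapped SVM on the training split, and return the composite AUC
#' objective. An empty module set scores as chance
#' (`0.5 * (alpha + beta)`); so does a graph denser than `max_mean_degree`,
#' where the percolation collapses to one near-global module and provides
#' no selection (see the package vignette).
#'
#' @param T threshold in `[0, 1]`.
#' @param table a [feature_table()].
#' @param split a `nemtie_split`.
#' @param network a `nemtie_network` with `R` computed.
#' @param loss a [loss_config()].
#' @param k clique size.
#' @param svm a [svm_config()].
#' @param max_mean_degree density guard; `Inf` disables it.
#' @param auc_splits which splits feed the objective: `c(train, test)` index
#'   pair, used internally by the holdout-tuning mode.
#' @return list `loss`, `modules`, `features` (union, possibly empty),
#'   `aucs`.
#' @export
evaluate_threshold <- function(T, table, split, network,
                               loss = loss_config(), k = 3L,
                               svm = svm_config(), max_mean_degree = 30) {
  chance <- 0.5 * (loss$alpha + loss$beta)
  g <- threshold_graph(network, T)
  if (igraph::ecount(g) > max_mean_degree * igraph::vcount(g) / 2) {
    return(list(loss = chance, modules = NULL, features = character(0),
                aucs = c(train = NA_real_, test = NA_real_)))
  }
  mods <- clique_percolation(g, k = k)
  feats <- sort(unique(unlist(module_features(mods))))
  if (length(feats) == 0L) {
    return(list(loss = chance, modules = mods, features = character(0),
                aucs = c(train = NA_real_, test = NA_real_)))
  }
  a <- .svm_split_aucs(table, split, feats, svm)
  list(loss = composite_auc_loss(a[["train"]], a[["test"]], loss),
       modules = mods, features = feats,
       aucs = a[c("train", "test")])
}

#' Greedy solution of the module-constrained feature-subset problem
#'
#' Forward selection over the union of module features: starting from the
#' empty set, repeatedly adds the candidate whose inclusion maximizes the
#' composite AUC of the wrapped SVM, stopping when no addition improves the
#' objective by more than `tol`. This is a feasible approximate solution of
#' the combinatorial subset problem (exhaustive search is exponential);
#' `exhaustive = TRUE` enables full enumeration for up to 15 candidates to
#' audit greedy quality. Ties break toward the lowest feature index for
#' determinism.
#'
#' @param candidates candidate feature names (nonempty), the union of the
#'   selected modules' features.
#' @param table a [feature_table()].
#' @param split a `nemtie_split`.
#' @param loss a [loss_config()].
#' @param svm a [svm_config()].
#' @param tol minimal improvement to accept a step.
#' @param max_features optional cap on the subset size.
#' @param exhaustive if TRUE and `length(candidates) <= 15`, search all
#'   nonempty subsets instead.
#' @return list `features` (selected, in acceptance order), `loss`, `trace`
#'   (objective after each accepted step, strictly increasing).
#' @export
greedy_feature_subset <- function(candidates, table, split,
                                  loss = loss_config(), svm = svm_config(),
                                  tol = 1e-4, max_features = Inf,
                                  exhaustive = FALSE) {
  if (length(candidates) == 0L) stop("candidate set must be nonempty", call. = FALSE)
  if (is.character(candidates)) {
    cand_idx <- match(candidates, table$feature_names)
    if (anyNA(cand_idx)) stop("unknown candidate feature", call. = FALSE)
  } else {
    cand_idx <- as.integer(candidates)
  }
  cand_idx <- sort(unique(cand_idx))
  obj <- function(idx) {
    a <- .svm_split_aucs(table, split, idx, svm)
    composite_auc_loss(a[["train"]], a[["test"]], loss)
  }
  if (exhaustive) {
    if (length(cand_idx) > 15L) stop("exhaustive search limited to 15 candidates",
                                     call. = FALSE)
    best <- NULL
    best_v <- -Inf
    for (sz in seq_along(cand_idx)) {
      for (comb in utils::combn(cand_idx, sz, simplify = FALSE)) {
        v <- obj(comb)
        if (v > best_v + 1e-12) {
          best_v <- v
          best <- comb
        }
      }
    }
    return(list(features = table$feature_names[best], loss = best_v, trace = best_v))
  }
  chosen <- integer(0)
  cur <- -Inf
  trace <- numeric(0)
  while (length(chosen) < max_features) {
    rest <- setdiff(cand_idx, chosen)
    if (length(rest) == 0L) break
    vals <- vapply(rest, function(j) obj(c(chosen, j)), numeric(1))
    best <- which.max(vals)  # which.max takes the first = lowest index on ties
    if (vals[best] <= cur + tol && length(chosen) > 0L) break
    if (vals[best] <= cur && length(chosen) == 0L) {
      # even a forced first step takes the best single feature
      best <- which.max(vals)
    }
    chosen <- c(chosen, rest[best])
    cur <- vals[best]
    trace <- c(trace, cur)
  }
  list(features = table$feature_names[chosen], loss = cur, trace = trace)
}

#' Fit the final classifier on the selected features
#'
#' @param table a [feature_table()].
#' @param split a `nemtie_split`.
#' @param features nonempty selected feature set.
#' @param svm a [svm_config()].
#' @param n_boot bootstrap replicates for the metric CIs.
#' @param seed seed for the bootstrap.
#' @return list `scores` (full [fit_svm_scores()] result) and `metrics`
#'   (data.frame of per-split AUC / sensitivity / specificity with CIs).
#' @export
fit_final_model <- function(table, split, features, svm = svm_config(),
                            n_boot = 2000L, seed = 1L) {
  sc <- fit_svm_scores(table, split, features, svm)
  splits <- list(train = split$train_idx, test = split$test_idx,
                 validation = split$validation_idx)
  metrics <- do.call(rbind, lapply(names(splits), function(nm) {
    idx <- splits[[nm]]
    m <- classification_metrics(sc$scores[idx], table$C[idx],
                                n_boot = n_boot, seed = seed)
    cbind(split = nm, as.data.frame(m))
  }))
  list(scores = sc, metrics = metrics)
}

#' Run the full network-evolution-model feature selection
#'
#' End-to-end driver: entropy network (once), PSO over the adjacency
#' threshold against the composite SVM-AUC objective, clique-percolation
#' modules at the optimum, greedy subset search over the module-feature
#' union, and the final SVM with per-split metrics. All stage seeds derive
#' from the single `seed`, so the whole run is reproducible from one
#' integer. Threshold evaluations are memoized on the rounded threshold.
#'
#' @param table a [feature_table()].
#' @param split optional precomputed `nemtie_split` (else drawn from
#'   `ratios` and the derived split seed).
#' @param ratios split ratios when `split` is NULL.
#' @param k clique size.
#' @param loss a [loss_config()].
#' @param pso a [pso_config()] (its `seed` is overridden by the derived
#'   seed).
#' @param svm a [svm_config()].
#' @param cv a [cv_protocol()] for the accuracy probes (its `seed` is
#'   overridden by the derived seed).
#' @param seed single top-level integer seed.
#' @param network optional precomputed normalized `nemtie_network`.
#' @param max_mean_degree density guard for [evaluate_threshold()].
#' @param holdout_tuning if TRUE, the tuning objective replaces the test
#'   AUC with an inner validation fold carved from the training split, so
#'   the test split never informs selection (a documented deviation from
#'   the method's own design).
#' @param greedy_tol,max_features forwarded to [greedy_feature_subset()].
#' @param n_boot bootstrap replicates in the final metrics.
#' @return object of class `nemtie_selection`: `T_star`,
#'   `selected_features`, `modules_used`, `module_report`, `loss_trace`,
#'   `greedy_trace`, `final` (model + metrics), `network`, `split`, `seeds`.
#' @export
nemtie_select <- function(table, split = NULL, ratios = c(0.70, 0.20, 0.10),
                          k = 3L, loss = loss_config(), pso = pso_config(),
                          svm = svm_config(), cv = cv_protocol(),
                          seed = 1L, network = NULL, max_mean_degree = 30,
                          holdout_tuning = FALSE,
                          greedy_tol = 1e-4, max_features = Inf,
                          n_boot = 2000L) {
  seeds <- derive_seeds(seed, c("split", "cv", "pso", "boot", "inner"))
  if (is.null(split)) split <- split_cohort(table, ratios, seed = seeds[["split"]])
  if (is.null(network)) {
    cv$seed <- seeds[["cv"]]
    network <- normalize_adjacency(build_entropy_network(table, cv))
  }
  tune_split <- split
  if (holdout_tuning) {
    # carve an inner validation fold out of the training rows; the outer
    # test/validation splits stay untouched for reporting
    tr <- split$train_idx
    inner <- with_seed(seeds[["inner"]], {
      idx <- unlist(lapply(base::split(tr, table$C[tr]), function(v) {
        v[sample.int(length(v), max(1L, round(0.25 * length(v))))]
      }))
      sort(idx)
    })
    tune_split <- split
    tune_split$train_idx <- setdiff(tr, inner)
    tune_split$test_idx <- inner
  }
  pso$seed <- seeds[["pso"]]
  # the objective is piecewise constant in T: the thresholded edge set (and
  # hence modules, union and loss) changes only where T crosses a distinct
  # R value, so evaluations are memoized on the surviving edge count
  roff <- network$R[upper.tri(network$R)]
  memo <- new.env(hash = TRUE)
  eval_memo <- function(T) {
    key <- as.character(sum(roff > T))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- evaluate_threshold(T, table, tune_split, network, loss, k, svm,
                              max_mean_degree)
    memo[[key]] <- res
    res
  }
  objective <- function(T) eval_memo(T)$loss
  opt <- pso_optimize(objective, pso)
  at_star <- eval_memo(opt$T_star)
  selected <- character(0)
  greedy <- NULL
  module_report <- NULL
  if (length(at_star$features) > 0L) {
    greedy <- greedy_feature_subset(at_star$features, table, tune_split, loss,
                                    svm, tol = greedy_tol,
                                    max_features = max_features)
    selected <- greedy$features
    module_report <- per_module_svm_evaluation(at_star$modules, table, split, svm)
  }
  final <- if (length(selected) > 0L) {
    fit_final_model(table, split, selected, svm, n_boot = n_boot,
                    seed = seeds[["boot"]])
  } else {
    NULL
  }
  structure(
    list(T_star = opt$T_star, tuning_value = opt$value,
         selected_features = selected,
         modules_used = at_star$modules,
         module_report = module_report,
         loss_trace = opt$trace,
         greedy_trace = greedy$trace %||% numeric(0),
         final = final, network = network, split = split,
         seeds = seeds, k = k, loss = loss, holdout_tuning = holdout_tuning),
    class = "nemtie_selection"
  )
}

#' @export
print.nemtie_selection <- function(x, ...) {
  cat(sprintf("<nemtie_selection> T* = %.4f, %d module(s), %d selected feature(s)\n",
              x$T_star,
              if (is.null(x$modules_used)) 0L else length(x$modules_used),
              length(x$selected_features)))
  if (length(x$selected_features)) {
    cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  }
  if (!is.null(x$final)) {
    m <- x$final$metrics
    cat(sprintf("  AUC train/test/validation: %.3f / %.3f / %.3f\n",
                m$auc[m$split == "train"], m$auc[m$split == "test"],
                m$auc[m$split == "validation"]))
  }
  invisible(x)
}
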