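#' Pipeline run configuration
#'
#' Validated defaults matching the study design: 70/20/10 split ratios,
#' objective weights `alpha = beta = 0.5`, PSO inertia 0.8 with
#' `c1 = c2 = 1.49445`, TMB cutoff 15.5 mut/Mb, triangle percolation
#' (`k = 3`).
#'
#' @param input path to a feature-table CSV (or NULL when `table` is passed
#'   to [run_pipeline()] directly).
#' @param label_column label column name in the CSV.
#' @param ratios split ratios.
#' @param k clique size.
#' @param alpha,beta composite-objective weights.
#' @param pso_inertia,pso_c1,pso_c2,pso_particles,pso_iterations PSO
#'   settings.
#' @param cv_method,cv_folds accuracy-probe protocol.
#' @param svm_kernel,svm_cost SVM settings.
#' @param cutoff TMB cutoff.
#' @param baselines logical; also run mRMR and Laplacian baselines.
#' @param n_boot bootstrap replicates for metric CIs.
#' @param seed top-level seed.
#' @param out_dir output directory.
#' @return object of class `nemtie_run_config`.
#' @export
run_config <- function(input = NULL, label_column = "label",
                       ratios = c(0.70, 0.20, 0.10), k = 3L,
                       alpha = 0.5, beta = 0.5,
                       pso_inertia = 0.8, pso_c1 = 1.49445, pso_c2 = 1.49445,
                       pso_particles = 20L, pso_iterations = 100L,
                       cv_method = "cv", cv_folds = 5L,
                       svm_kernel = "radial", svm_cost = 1,
                       cutoff = 15.5, baselines = FALSE, n_boot = 2000L,
                       seed = 1L, out_dir = "nemtie_run") {
  cfg <- structure(
    list(input = input, label_column = label_column, ratios = ratios,
         k = as.integer(k), alpha = alpha, beta = beta,
         pso_inertia = pso_inertia, pso_c1 = pso_c1, pso_c2 = pso_c2,
         pso_particles = as.integer(pso_particles),
         pso_iterations = as.integer(pso_iterations),
         cv_method = cv_method, cv_folds = as.integer(cv_folds),
         svm_kernel = svm_kernel, svm_cost = svm_cost, cutoff = cutoff,
         baselines = isTRUE(baselines), n_boot = as.integer(n_boot),
         seed = as.integer(seed), out_dir = out_dir),
    class = "nemtie_run_config"
  )
  # validation happens at construction so a bad config fails before compute
  loss_config(cfg$alpha, cfg$beta)
  pso_config(cfg$pso_inertia, cfg$pso_c1, cfg$pso_c2, cfg$pso_particles,
             cfg$pso_iterations)
  cv_protocol(cfg$cv_method, cfg$cv_folds)
  if (length(cfg$ratios) != 3L || abs(sum(cfg$ratios) - 1) > 1e-9) {
    stop("ratios must be three fractions summing to 1", call. = FALSE)
  }
  cfg
}

#' Load a run configuration from YAML
#'
#' Flat key-value schema mirroring [run_config()]'s arguments; unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  do.call(run_config, vals)
}

#' Execute the full workflow and persist artifacts
#'
#' Runs split, entropy network, clique percolation, module scoring,
#' PSO/greedy selection and final metrics (plus optional baselines with a
#' resampled comparison) and writes every artifact into `out_dir`:
#' the echoed config (`config.yaml`), split manifest, network matrices and
#' GraphML, module CSV, module evaluation report, selected features, loss
#' trace, per-split metrics, and a structured log recording all derived
#' seeds. Any stage failure aborts with the stage name; artifacts written
#' before the failure persist.
#'
#' @param config a [run_config()].
#' @param table optional in-memory [feature_table()] (otherwise read from
#'   `config$input`).
#' @return the `nemtie_selection` result, invisibly; side effect: files
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config, table = NULL) {
  stopifnot(inherits(config, "nemtie_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      say("stage %s: FAILED: %s", name, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    say("stage %s: done", name)
    out
  }
  if (is.null(table)) {
    table <- stage("load", read_feature_table(config$input, config$label_column,
                                              cutoff = config$cutoff))
  }
  seeds <- derive_seeds(config$seed, c("pipeline", "baseline"))
  say("seeds: top=%d pipeline=%d baseline=%d", config$seed,
      seeds[["pipeline"]], seeds[["baseline"]])
  res <- stage("select", nemtie_select(
    table,
    ratios = config$ratios, k = config$k,
    loss = loss_config(config$alpha, config$beta),
    pso = pso_config(config$pso_inertia, config$pso_c1, config$pso_c2,
                     config$pso_particles, config$pso_iterations),
    svm = svm_config(config$svm_kernel, config$svm_cost),
    cv = cv_protocol(config$cv_method, config$cv_folds),
    seed = seeds[["pipeline"]], n_boot = config$n_boot))
  stage("artifacts", {
    write_split_manifest(res$split, table, file.path(config$out_dir, "split.csv"))
    write_network(res$network, res$T_star, config$out_dir)
    if (!is.null(res$modules_used)) {
      write_modules(res$modules_used, file.path(config$out_dir, "modules.csv"))
    }
    if (!is.null(res$module_report)) {
      utils::write.csv(res$module_report,
                       file.path(config$out_dir, "module_report.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(data.frame(feature = res$selected_features),
                     file.path(config$out_dir, "selected_features.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(iteration = seq_along(res$loss_trace),
                                best_loss = res$loss_trace),
                     file.path(config$out_dir, "loss_trace.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(res$final)) {
      utils::write.csv(res$final$metrics, file.path(config$out_dir, "metrics.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  })
  if (config$baselines) {
    cmp <- stage("baselines", {
      methods <- list(
        nemtie = function(tb, sp) {
          if (length(res$selected_features) == 0L) return(0.5)
          a <- .svm_split_aucs(tb, sp, res$selected_features,
                               svm_config(config$svm_kernel, config$svm_cost))
          a[["test"]]
        },
        mrmr_svm = method_mrmr_svm(),
        laplacian_svm = method_laplacian_svm())
      compare_methods_resampled(table, methods, n_resamples = 10L,
                                ratios = config$ratios,
                                seed = seeds[["baseline"]])
    })
    utils::write.csv(cmp$auc, file.path(config$out_dir, "comparison_auc.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(cmp$tests, file.path(config$out_dir, "comparison_tests.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  say("run complete: %d selected feature(s), T* = %.4f",
      length(res$selected_features), res$T_star)
  invisible(res)
}

#' Render human-readable reports from a completed run
#'
#' Reads the artifacts in a run directory and writes plot-ready companions:
#' per-split ROC coordinates, a per-feature degree/association table for
#' the selected features, and a plain-text summary.
#'
#' @param res the `nemtie_selection` returned by [run_pipeline()].
#' @param table the [feature_table()] of the run.
#' @param out_dir the run directory.
#' @return invisible character vector of written paths.
#' @export
render_reports <- function(res, table, out_dir) {
  if (is.null(res$final)) stop("run selected no features; nothing to report", call. = FALSE)
  paths <- character(0)
  sc <- res$final$scores
  splits <- list(train = res$split$train_idx, test = res$split$test_idx,
                 validation = res$split$validation_idx)
  roc <- do.call(rbind, lapply(names(splits), function(nm) {
    idx <- splits[[nm]]
    cbind(split = nm, roc_points(sc$scores[idx], table$C[idx]))
  }))
  p <- file.path(out_dir, "roc_points.csv")
  utils::write.csv(roc, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  g <- threshold_graph(res$network, res$T_star)
  deg <- feature_degrees(g)
  assoc <- pearson_pfdr(table, features = res$selected_features)
  assoc$degree <- deg[assoc$feature_name]
  p <- file.path(out_dir, "selected_feature_table.csv")
  utils::write.csv(assoc, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  m <- res$final$metrics
  lines <- c(
    sprintf("Adjacency threshold T* = %.4f (k = %d)", res$T_star, res$k),
    sprintf("Modules at T*: %d", if (is.null(res$modules_used)) 0L else length(res$modules_used)),
    sprintf("Selected features (%d): %s", length(res$selected_features),
            paste(res$selected_features, collapse = ", ")),
    sprintf("%-12s AUC %.4f (%.4f-%.4f)  Sens %.4f  Spec %.4f",
            m$split, m$auc, m$auc_lo, m$auc_hi, m$sensitivity, m$specificity))
  p <- file.path(out_dir, "summary.txt")
  writeLines(lines, p)
  paths <- c(paths, p)
  invisible(paths)
}
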