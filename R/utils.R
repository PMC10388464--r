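#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library internals never perturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive named child seeds from one top-level seed
#'
#' Hierarchical seeding: every stochastic stage of a run consumes its own
#' seed derived deterministically from a single integer, so a whole pipeline
#' is reproducible from one number.
#'
#' @param seed integer top-level seed.
#' @param names character vector of stage names.
#' @return named integer vector of seeds (all < 2^31).
#' @export
#' @examples
#' derive_seeds(1, c("split", "pso"))
derive_seeds <- function(seed, names) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(names)))
  stats::setNames(s, names)
}

# Stratified fold assignment: length-m integer vector in 1..folds with each
# class spread as evenly as possible across folds. Errors if a class has
# fewer members than `folds` would need to keep every training fold two-class.
stratified_folds <- function(labels, folds, seed) {
  m <- length(labels)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  assign <- integer(m)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

`%||%` <- function(a, b) if (is.null(a)) b else a
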