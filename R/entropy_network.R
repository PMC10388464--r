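#' Accuracy-probe protocol for the feature network
#'
#' The network edge weights are built from LDA classification accuracies of
#' single features and feature pairs. The probe protocol is either
#' stratified k-fold cross-validation (default, 5 folds, fixed seed) or
#' resubstitution (fit and score on all samples).
#'
#' @param method `"cv"` or `"resubstitution"`.
#' @param folds number of CV folds (ignored for resubstitution).
#' @param seed integer seed controlling the fold assignment.
#' @return object of class `nemtie_cv`.
#' @export
cv_protocol <- function(method = c("cv", "resubstitution"), folds = 5L, seed = 1L) {
  method <- match.arg(method)
  if (method == "cv" && folds < 2L) stop("folds must be >= 2", call. = FALSE)
  structure(list(method = method, folds = as.integer(folds), seed = as.integer(seed)),
            class = "nemtie_cv")
}

# Pooled-covariance LDA with a small ridge on the covariance so collinear or
# within-class-constant columns cannot make the solve singular. Returns 0/1
# predictions for Xte. Priors are the training class proportions.
.lda_predict <- function(Xtr, ytr, Xte, ridge = 1e-6) {
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  n1 <- sum(ytr == 1L); n0 <- sum(ytr == 0L)
  if (n1 == 0L || n0 == 0L) stop("training fold contains a single class", call. = FALSE)
  mu1 <- colMeans(Xtr[ytr == 1L, , drop = FALSE])
  mu0 <- colMeans(Xtr[ytr == 0L, , drop = FALSE])
  Xc <- Xtr
  Xc[ytr == 1L, ] <- sweep(Xtr[ytr == 1L, , drop = FALSE], 2L, mu1)
  Xc[ytr == 0L, ] <- sweep(Xtr[ytr == 0L, , drop = FALSE], 2L, mu0)
  S <- crossprod(Xc) / max(nrow(Xtr) - 2L, 1L)
  w <- solve(S + diag(ridge, ncol(Xtr)), mu1 - mu0)
  score <- as.vector(Xte %*% w) - sum(w * (mu1 + mu0) / 2) + log(n1 / n0)
  as.integer(score > 0)
}

# fold iterator shared by lda_accuracy and the vectorized matrix builder,
# so scalar and vectorized paths see identical folds
.cv_folds <- function(labels, cv) {
  if (cv$method == "resubstitution") {
    return(list(list(tr = seq_along(labels), te = seq_along(labels))))
  }
  if (any(table(labels) < cv$folds)) {
    stop("a class has fewer samples than CV folds; accuracy protocol failure",
         call. = FALSE)
  }
  fid <- stratified_folds(labels, cv$folds, cv$seed)
  lapply(seq_len(cv$folds), function(f) {
    list(tr = which(fid != f), te = which(fid == f))
  })
}

#' LDA classification accuracy of a small feature subset
#'
#' The probability attached to each network node or node pair: the accuracy
#' of a pooled-covariance LDA classifier fit on exactly the given feature
#' columns, estimated under the chosen protocol (cross-validated accuracy
#' pools the held-out predictions over all samples). Clipped to
#' `[1e-6, 1]` so downstream logarithms stay finite.
#'
#' @param table a [feature_table()].
#' @param features one or two feature indices (or names).
#' @param cv a [cv_protocol()].
#' @param ridge ridge added to the pooled covariance.
#' @return accuracy in `[1e-6, 1]`.
#' @export
lda_accuracy <- function(table, features, cv = cv_protocol(), ridge = 1e-6) {
  if (is.character(features)) features <- match(features, table$feature_names)
  if (length(features) < 1L || anyNA(features)) {
    stop("features must name 1 or 2 columns of the table", call. = FALSE)
  }
  X <- table$X[, features, drop = FALSE]
  y <- table$C
  correct <- 0L
  total <- 0L
  for (f in .cv_folds(y, cv)) {
    pred <- .lda_predict(X[f$tr, , drop = FALSE], y[f$tr], X[f$te, , drop = FALSE],
                         ridge = ridge)
    correct <- correct + sum(pred == y[f$te])
    total <- total + length(f$te)
  }
  min(max(correct / total, 1e-6), 1)
}

#' Pointwise information gain between two feature nodes
#'
#' The edge-weight primitive of the network evolution model: given the LDA
#' accuracies of two features alone (`p_x`, `p_y`) and jointly (`p_xy`),
#' returns `p_xy * log(p_xy / (p_x * p_y))` with the natural logarithm. The
#' value is a pointwise-mutual-information-style gain on accuracies — high
#' when the pair classifies better than its parts multiply predict — and may
#' be negative; the log base only rescales the matrix and is absorbed by the
#' min-max normalization of [normalize_adjacency()].
#'
#' @param p_x,p_y,p_xy accuracies in (0, 1].
#' @return numeric gain.
#' @export
#' @examples
#' pair_information_gain(0.5, 0.5, 1)   # log(4)
pair_information_gain <- function(p_x, p_y, p_xy) {
  p <- c(p_x, p_y, p_xy)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("accuracies must lie in (0, 1]", call. = FALSE)
  }
  p_xy * log(p_xy / (p_x * p_y))
}

#' Build the information-gain matrix of the network evolution model
#'
#' Computes the single-feature accuracy vector `p` and, for every feature
#' pair, the joint accuracy and the pointwise information gain
#' `E[j,k] = p_jk * log(p_jk / (p_j p_k))`. Single-feature accuracies are
#' computed once and cached in the returned object; all `n(n-1)/2` pair fits
#' are evaluated with a closed-form 2x2 pooled-covariance LDA vectorized
#' over the full pair grid per CV fold, which keeps 200-feature tables in
#' the seconds range.
#'
#' @param table a [feature_table()] with at least 2 features.
#' @param cv a [cv_protocol()].
#' @param ridge ridge added to pooled variances.
#' @return object of class `nemtie_network` with fields `feature_names`,
#'   `p_single`, `E` (symmetric, zero diagonal), `R` (empty until
#'   [normalize_adjacency()]), `protocol`.
#' @export
build_entropy_network <- function(table, cv = cv_protocol(), ridge = 1e-6) {
  X <- table$X
  y <- table$C
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 features to build a network", call. = FALSE)
  folds <- .cv_folds(y, cv)
  corr1 <- numeric(n)
  corr2 <- matrix(0, n, n)
  total <- 0L
  for (f in folds) {
    Xtr <- X[f$tr, , drop = FALSE]
    ytr <- y[f$tr]
    Xte <- X[f$te, , drop = FALSE]
    yte <- y[f$te]
    n1 <- sum(ytr == 1L); n0 <- sum(ytr == 0L)
    mu1 <- colMeans(Xtr[ytr == 1L, , drop = FALSE])
    mu0 <- colMeans(Xtr[ytr == 0L, , drop = FALSE])
    Xc <- Xtr
    Xc[ytr == 1L, ] <- sweep(Xtr[ytr == 1L, , drop = FALSE], 2L, mu1)
    Xc[ytr == 0L, ] <- sweep(Xtr[ytr == 0L, , drop = FALSE], 2L, mu0)
    S <- crossprod(Xc) / max(nrow(Xtr) - 2L, 1L)
    dm <- mu1 - mu0
    mb <- (mu1 + mu0) / 2
    lp <- log(n1 / n0)
    v <- diag(S) + ridge
    # single features: score = dm/v * (x - mb) + lp
    sc1 <- sweep(sweep(Xte, 2L, mb), 2L, dm / v, "*") + lp
    corr1 <- corr1 + colSums((sc1 > 0) == (yte == 1L))
    # pairs: w = [vj vk - S^2]^-1 closed form, vectorized over the pair grid
    Vj <- matrix(v, n, n)
    Vk <- t(Vj)
    det <- Vj * Vk - S * S
    dmj <- matrix(dm, n, n)
    dmk <- t(dmj)
    W1 <- (Vk * dmj - S * dmk) / det
    W2 <- (Vj * dmk - S * dmj) / det
    c0 <- W1 * matrix(mb, n, n) + W2 * matrix(mb, n, n, byrow = TRUE) - lp
    for (i in seq_along(yte)) {
      xi <- Xte[i, ]
      sc <- W1 * xi + W2 * matrix(xi, n, n, byrow = TRUE) - c0
      corr2 <- corr2 + ((sc > 0) == (yte[i] == 1L))
    }
    total <- total + length(yte)
  }
  p1 <- pmin(pmax(corr1 / total, 1e-6), 1)
  Pxy <- pmin(pmax(corr2 / total, 1e-6), 1)
  E <- Pxy * log(Pxy / outer(p1, p1))
  E <- (E + t(E)) / 2   # symmetric up to fp noise; enforce exactly
  diag(E) <- 0
  dimnames(E) <- list(table$feature_names, table$feature_names)
  structure(
    list(feature_names = table$feature_names,
         p_single = stats::setNames(p1, table$feature_names),
         E = E, R = NULL, protocol = cv),
    class = "nemtie_network"
  )
}

#' @export
print.nemtie_network <- function(x, ...) {
  cat(sprintf("<nemtie_network> %d features; E %s; R %s (%s accuracy probe)\n",
              length(x$feature_names),
              "computed", if (is.null(x$R)) "pending" else "computed",
              x$protocol$method))
  invisible(x)
}

#' Min-max normalize the information-gain matrix into an adjacency
#'
#' Maps the off-diagonal entries of `E` onto `[0, 1]` by
#' `R = (E - min) / (max - min)`; the minimum entry maps to exactly 0 and
#' the maximum to exactly 1. If all off-diagonal gains are equal the network
#' is degenerate and `R` is all zero (edgeless at every threshold). The
#' diagonal is forced to 0.
#'
#' @param network a `nemtie_network` with `E` computed.
#' @return the network with `R` filled.
#' @export
normalize_adjacency <- function(network) {
  E <- network$E
  if (is.null(E)) stop("E must be computed first", call. = FALSE)
  off <- E[upper.tri(E)]
  lo <- min(off)
  hi <- max(off)
  R <- if (hi > lo) (E - lo) / (hi - lo) else matrix(0, nrow(E), ncol(E))
  diag(R) <- 0
  dimnames(R) <- dimnames(E)
  network$R <- R
  network
}

#' Threshold the adjacency into an unweighted feature graph
#'
#' An edge joins features `j` and `k` iff `R[j,k] > T` (strict), so `T = 1`
#' gives the empty graph and raising `T` never adds edges.
#'
#' @param network a `nemtie_network` with `R` computed (or a symmetric
#'   numeric matrix in `[0,1]`).
#' @param T threshold in `[0, 1]`.
#' @return an undirected [igraph::graph] whose vertices are the features;
#'   edges carry the adjacency weight as attribute `weight`.
#' @export
threshold_graph <- function(network, T) {
  R <- if (inherits(network, "nemtie_network")) network$R else as.matrix(network)
  if (is.null(R)) stop("adjacency R not computed; call normalize_adjacency()", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || T < 0 || T > 1) {
    stop("threshold T must lie in [0, 1]", call. = FALSE)
  }
  A <- R * (R > T)
  diag(A) <- 0
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Vertex degrees of the thresholded feature graph
#'
#' @param graph an [igraph::graph] from [threshold_graph()].
#' @return named integer vector of degrees.
#' @export
feature_degrees <- function(graph) {
  igraph::degree(graph)
}

#' Export the network matrices and graph
#'
#' Writes `E` and `R` as square CSV matrices with feature-name headers, and
#' the thresholded graph as GraphML plus a 3-column edge list
#' (`feature_j, feature_k, weight`).
#'
#' @param network a `nemtie_network` with `R` computed.
#' @param T threshold for the exported graph.
#' @param dir output directory (created if missing).
#' @return invisible character vector of written paths.
#' @export
write_network <- function(network, T, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pe <- file.path(dir, "information_gain_E.csv")
  pr <- file.path(dir, "adjacency_R.csv")
  utils::write.csv(network$E, pe, quote = FALSE)
  utils::write.csv(network$R, pr, quote = FALSE)
  g <- threshold_graph(network, T)
  pg <- file.path(dir, "network.graphml")
  igraph::write_graph(g, pg, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  names(el) <- c("feature_j", "feature_k", "weight")
  pl <- file.path(dir, "edges.csv")
  utils::write.csv(el, pl, row.names = FALSE, quote = FALSE)
  invisible(c(pe, pr, pg, pl))
}
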