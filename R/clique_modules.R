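#' Enumerate all k-cliques of a graph
#'
#' @param graph an undirected [igraph::graph].
#' @param k clique size, `k >= 2`.
#' @return list of integer vertex-id vectors, each a fully connected set of
#'   size `k`.
#' @export
enumerate_k_cliques <- function(graph, k) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  lapply(igraph::cliques(graph, min = k, max = k), as.integer)
}

#' k-clique percolation communities
#'
#' Standard clique-percolation (CPM) communities: two k-cliques are adjacent
#' when they share `k - 1` vertices; a community is the vertex union of a
#' connected component of this clique-adjacency relation. A vertex may
#' belong to several modules (overlap is preserved), and isolated edges or
#' vertices never form a module. Implemented by percolating maximal cliques
#' of size `>= k` (adjacent when sharing `>= k - 1` vertices), which is
#' equivalent to percolating the k-cliques themselves but avoids
#' enumerating every k-subset of large cliques.
#'
#' @param graph an undirected [igraph::graph] with named vertices.
#' @param k clique size, default 3 (triangle percolation).
#' @return object of class `nemtie_modules`: a list with `k` and `modules`,
#'   each module a list `(module_id, features)`; modules are ordered by
#'   decreasing size, ties broken by the lexicographically smallest feature
#'   name, so ids are stable across runs.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - a, c - d, d - e, e - c)
#' clique_percolation(g, k = 3)
clique_percolation <- function(graph, k = 3L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(graph)))
  mc <- igraph::max_cliques(graph, min = k)
  comms <- list()
  if (length(mc) > 0L) {
    mc <- lapply(mc, function(x) sort(as.integer(x)))
    nmc <- length(mc)
    # union-find over maximal cliques; two cliques are adjacent iff they
    # share >= k-1 vertices, i.e. iff they share some (k-1)-subset. Bucket
    # cliques by every (k-1)-subset they contain: all members of a bucket
    # are mutually adjacent, so it suffices to union each bucket to its
    # first member — no pairwise intersection tests.
    parent <- seq_len(nmc)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    if (nmc > 1L) {
      buckets <- new.env(hash = TRUE)
      for (i in seq_len(nmc)) {
        subs <- if (length(mc[[i]]) == k - 1L) list(mc[[i]]) else
          utils::combn(mc[[i]], k - 1L, simplify = FALSE)
        for (s in subs) {
          key <- paste(s, collapse = "_")
          first <- buckets[[key]]
          if (is.null(first)) {
            buckets[[key]] <- i
          } else {
            ri <- find(first)
            rj <- find(i)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
    }
    roots <- vapply(seq_len(nmc), find, integer(1))
    comms <- lapply(split(seq_len(nmc), roots), function(idx) {
      sort(unique(unlist(mc[idx])))
    })
  }
  feats <- lapply(comms, function(v) sort(vnames[v]))
  if (length(feats) > 0L) {
    ord <- order(-lengths(feats),
                 vapply(feats, function(f) f[1L], character(1)))
    feats <- feats[ord]
  }
  structure(
    list(k = as.integer(k),
         modules = lapply(seq_along(feats), function(i) {
           list(module_id = i, features = feats[[i]])
         })),
    class = "nemtie_modules"
  )
}

#' @export
print.nemtie_modules <- function(x, ...) {
  cat(sprintf("<nemtie_modules> %d module(s), k = %d\n", length(x$modules), x$k))
  for (mo in x$modules) {
    cat(sprintf("  [%d] (%d) %s\n", mo$module_id, length(mo$features),
                paste(mo$features, collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.nemtie_modules <- function(x) length(x$modules)

#' Feature vertex sets of a module set
#' @param modules a `nemtie_modules`.
#' @return list of character vectors.
#' @export
module_features <- function(modules) {
  lapply(modules$modules, `[[`, "features")
}

#' Column-slice a table into per-module submatrices
#'
#' For modules `s = 1, ..., D` returns the corresponding feature submatrices
#' `X[, features_s]`; overlapping modules repeat shared columns in each
#' submatrix.
#'
#' @param table a [feature_table()].
#' @param modules a `nemtie_modules`.
#' @return list of numeric matrices, one per module, in module order.
#' @export
modules_to_submatrices <- function(table, modules) {
  lapply(module_features(modules), function(f) {
    j <- match(f, table$feature_names)
    if (anyNA(j)) stop("module feature missing from table", call. = FALSE)
    table$X[, j, drop = FALSE]
  })
}

#' Write a module set as CSV
#'
#' Long format: one row per (module, feature) pair.
#'
#' @param modules a `nemtie_modules`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  rows <- do.call(rbind, lapply(modules$modules, function(mo) {
    data.frame(module_id = mo$module_id, feature_name = mo$features,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(module_id = integer(0), feature_name = character(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
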