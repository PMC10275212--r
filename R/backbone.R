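#' Minimum spanning tree backbone of a weighted layer
#'
#' Extracts the binary backbone of a weighted connectivity matrix as the
#' minimum spanning tree of the graph with edge cost `1/w` (Kruskal's
#' algorithm), i.e. the maximum-total-weight spanning tree of the original
#' weights: the tree retains the network's strongest connections. Zero-weight
#' pairs are non-edges (they never enter the candidate set as infinite-cost
#' edges). Ties in cost are broken deterministically by `(cost, i, j)`.
#'
#' @param matrix A [connectivity_matrix] or a symmetric nonnegative square
#'   matrix with zero diagonal.
#' @return An object of class `backbone_graph` with fields `adjacency`
#'   (binary `N x N`), `edge_list` (two-column matrix of 1-based endpoints,
#'   `i < j`), `edge_weights` (original weights of the retained edges) and
#'   `source_modality`.
#' @export
mst_backbone <- function(matrix) {
  modality <- NA_character_
  if (inherits(matrix, "connectivity_matrix")) {
    modality <- matrix$modality
    w <- matrix$weights
  } else {
    w <- as.matrix(matrix)
  }
  N <- nrow(w)
  if (N != ncol(w)) stop("weight matrix must be square")
  ut <- upper.tri(w)
  keep <- ut & w > 0
  ei <- row(w)[keep]
  ej <- col(w)[keep]
  ew <- w[keep]
  ord <- order(1 / ew, ei, ej)
  ei <- ei[ord]; ej <- ej[ord]; ew <- ew[ord]

  parent <- seq_len(N)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {
      nxt <- parent[x]
      parent[x] <<- root
      x <- nxt
    }
    root
  }
  sel <- logical(length(ew))
  n_sel <- 0L
  for (k in seq_along(ew)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) {
      parent[ri] <- rj
      sel[k] <- TRUE
      n_sel <- n_sel + 1L
      if (n_sel == N - 1L) break
    }
  }
  if (n_sel < N - 1L) {
    n_comp <- length(unique(vapply(seq_len(N), find, integer(1))))
    stop("positive-weight graph is disconnected (", n_comp,
         " components); cannot build a spanning tree backbone")
  }
  adj <- matrix(0, N, N, dimnames = dimnames(w))
  adj[cbind(ei[sel], ej[sel])] <- 1
  adj <- adj + t(adj)
  structure(
    list(adjacency = adj,
         edge_list = cbind(i = ei[sel], j = ej[sel]),
         edge_weights = ew[sel],
         source_modality = modality),
    class = "backbone_graph"
  )
}

#' @export
as.matrix.backbone_graph <- function(x, ...) x$adjacency

#' @export
print.backbone_graph <- function(x, ...) {
  cat("<backbone_graph> ", nrow(x$adjacency), " nodes, ",
      nrow(x$edge_list), " edges", sep = "")
  if (!is.na(x$source_modality)) {
    cat(" (from '", x$source_modality, "')", sep = "")
  }
  cat("\n")
  invisible(x)
}
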