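#' Atlas mapping of regions to canonical subnetworks
#'
#' Builds a mapping of atlas regions to the seven canonical cortical
#' subnetworks (VN, SMN, DAN, VAN, LMN, FPN, DMN). Region indices are
#' 0-based, matching the on-disk atlas file convention.
#'
#' @param n_regions Number of regions.
#' @param subnetwork_sizes Named integer vector over the seven subnetworks
#'   summing to `n_regions`. Defaults to a near-even split (presets exist for
#'   60 and 197 regions).
#' @return A data frame of class `atlas_mapping` with columns
#'   `region_index`, `region_name`, `subnetwork`.
#' @export
make_atlas <- function(n_regions, subnetwork_sizes = NULL) {
  nets <- c("VN", "SMN", "DAN", "VAN", "LMN", "FPN", "DMN")
  if (is.null(subnetwork_sizes)) {
    subnetwork_sizes <- default_partition(n_regions)
  }
  if (is.null(names(subnetwork_sizes)) ||
      !setequal(names(subnetwork_sizes), nets)) {
    stop("'subnetwork_sizes' must be named with exactly the seven canonical ",
         "subnetworks: ", paste(nets, collapse = ", "))
  }
  subnetwork_sizes <- subnetwork_sizes[nets]
  if (any(subnetwork_sizes < 1L)) stop("every subnetwork must be nonempty")
  if (sum(subnetwork_sizes) != n_regions) {
    stop("subnetwork sizes sum to ", sum(subnetwork_sizes),
         ", not n_regions = ", n_regions)
  }
  subnet <- rep(nets, times = subnetwork_sizes)
  name <- paste0(subnet, "_", unlist(lapply(subnetwork_sizes, seq_len)))
  out <- data.frame(
    region_index = seq_len(n_regions) - 1L,
    region_name = name,
    subnetwork = subnet,
    stringsAsFactors = FALSE
  )
  class(out) <- c("atlas_mapping", "data.frame")
  out
}

default_partition <- function(n_regions) {
  nets <- c("VN", "SMN", "DAN", "VAN", "LMN", "FPN", "DMN")
  if (n_regions == 60L) {
    sizes <- c(9L, 9L, 8L, 8L, 8L, 9L, 9L)
  } else if (n_regions == 197L) {
    # mirrors the post-exclusion region count of the 210-parcel atlas
    sizes <- c(30L, 30L, 28L, 26L, 25L, 28L, 30L)
  } else {
    if (n_regions < 10L) {
      stop("n_regions = ", n_regions,
           " is too small for a 7-subnetwork partition (need >= 10)")
    }
    base <- n_regions %/% 7L
    sizes <- rep(base, 7L)
    extra <- n_regions - 7L * base
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  stats::setNames(sizes, nets)
}

#' Logical mask of regions belonging to a subnetwork
#'
#' @param mapping An `atlas_mapping`.
#' @param label Subnetwork label, e.g. `"FPN"`.
#' @return Logical vector of length N.
#' @export
subnetwork_mask <- function(mapping, label) {
  if (!label %in% mapping$subnetwork) {
    stop("subnetwork '", label, "' not present in the atlas mapping")
  }
  mapping$subnetwork == label
}

#' Build the supra-adjacency matrix of a multiplex network
#'
#' Assembles the `(L*N) x (L*N)` supra-adjacency matrix of a binary
#' multiplex: diagonal blocks hold the intralayer adjacencies (one backbone
#' per layer, in `layer_order`), and off-diagonal blocks couple each node
#' only to its own copies in other layers with weight `omega`. With the
#' default categorical topology every pair of layers is coupled; the chain
#' topology couples consecutive layers only.
#'
#' @param layers Named list of [mst_backbone()] outputs (or binary adjacency
#'   matrices) sharing the same node set and ordering.
#' @param omega Interlayer coupling weight (default 1, as for the intralayer
#'   links of a binary multiplex).
#' @param topology `"categorical"` (all layer pairs) or `"chain"`
#'   (consecutive layers).
#' @return An object of class `supra_adjacency` with the sparse symmetric
#'   matrix in `$matrix` and bookkeeping fields `L`, `N`, `layer_order`,
#'   `omega`, `topology`.
#' @export
build_supra_adjacency <- function(layers, omega = 1,
                                  topology = c("categorical", "chain")) {
  topology <- match.arg(topology)
  if (length(layers) < 1L) stop("need at least one layer")
  adjs <- lapply(layers, function(l) {
    a <- if (inherits(l, "backbone_graph")) l$adjacency else as.matrix(l)
    if (nrow(a) != ncol(a)) stop("layer adjacency must be square")
    a
  })
  Ns <- vapply(adjs, nrow, integer(1))
  if (length(unique(Ns)) != 1L) {
    stop("layers have mismatched node counts: ",
         paste(unique(Ns), collapse = ", "))
  }
  labs <- lapply(adjs, rownames)
  has_labs <- !vapply(labs, is.null, logical(1))
  if (any(has_labs)) {
    ref <- labs[has_labs][[1L]]
    for (lb in labs[has_labs]) {
      if (!identical(lb, ref)) stop("layers have mismatched region orderings")
    }
  }
  N <- Ns[[1L]]
  L <- length(adjs)
  layer_order <- names(layers)
  if (is.null(layer_order)) layer_order <- paste0("layer", seq_len(L))

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (l in seq_len(L)) {
    a <- adjs[[l]]
    idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
    off <- (l - 1L) * N
    ii <- c(ii, idx[, 1L] + off)
    jj <- c(jj, idx[, 2L] + off)
    xx <- c(xx, a[idx])
  }
  pairs <- if (L < 2L) {
    matrix(integer(0), 2L, 0L)
  } else if (topology == "categorical") {
    utils::combn(L, 2L)
  } else {
    rbind(seq_len(L - 1L), seq(2L, length.out = L - 1L))
  }
  if (L > 1L && omega != 0) {
    for (k in seq_len(ncol(pairs))) {
      la <- pairs[1L, k]; lb <- pairs[2L, k]
      ii <- c(ii, (la - 1L) * N + seq_len(N))
      jj <- c(jj, (lb - 1L) * N + seq_len(N))
      xx <- c(xx, rep(omega, N))
    }
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(L * N, L * N),
                            symmetric = TRUE)
  structure(
    list(matrix = M, L = L, N = N, layer_order = layer_order,
         omega = omega, topology = topology,
         region_labels = if (any(has_labs)) labs[has_labs][[1L]] else NULL),
    class = "supra_adjacency"
  )
}

#' @export
print.supra_adjacency <- function(x, ...) {
  cat("<supra_adjacency> L = ", x$L, " layers x N = ", x$N,
      " nodes (", x$L * x$N, " x ", x$L * x$N, "), omega = ", x$omega,
      ", ", x$topology, " coupling\n", sep = "")
  cat("  layers: ", paste(x$layer_order, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Leading (Perron) eigenpair of a symmetric nonnegative matrix by shifted
# power iteration. The shift by the maximum row sum makes the spectrum
# nonnegative, so the Perron eigenvalue strictly dominates and the iteration
# converges from the deterministic positive uniform start whenever the graph
# is connected. Convergence is declared when the geometric-tail bound
# diff * rho / (1 - rho) on the remaining error (rho the observed
# contraction ratio of successive iterate differences) falls below `tol`.
leading_eigenpair <- function(M, tol = 1e-10, maxit = 100000L) {
  n <- nrow(M)
  shift <- max(Matrix::rowSums(abs(M))) + 1
  v <- rep(1 / sqrt(n), n)
  prev_diff <- Inf
  for (it in seq_len(maxit)) {
    w <- as.numeric(M %*% v) + shift * v
    w <- w / sqrt(sum(w^2))
    diff <- max(abs(w - v))
    v <- w
    done <- if (diff == 0) TRUE else if (is.finite(prev_diff) &&
                                         prev_diff > 0) {
      rho <- min(diff / prev_diff, 0.999999)
      diff * rho / (1 - rho) < tol
    } else FALSE
    prev_diff <- diff
    if (done || diff < tol * 1e-4) {
      lambda <- as.numeric(crossprod(v, as.numeric(M %*% v)))
      v[v < 1e-12] <- 0
      return(list(vector = v, lambda = lambda, iterations = it))
    }
  }
  stop("power iteration failed to converge within ", maxit, " iterations")
}

# connectivity check on a symmetric sparse/dense adjacency via BFS
is_connected_graph <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(FALSE)
  Mc <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  p <- Mc@p; idx <- Mc@i
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- idx[seq.int(p[v] + 1L, length.out = p[v + 1L] - p[v])] + 1L
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Single-layer eigenvector centrality
#'
#' Leading eigenvector of a (weighted or binary) nonnegative connected
#' adjacency matrix, oriented nonnegative and normalized to unit Euclidean
#' norm. Weighted matrices are used as-is (weight inversion applies only to
#' the MST cost, not to centrality).
#'
#' @param matrix A [connectivity_matrix], `backbone_graph`, or square
#'   nonnegative matrix.
#' @param tol Convergence tolerance of the eigensolver.
#' @return A `centrality_scores` object: `scores` (length N, unit norm),
#'   `lambda` (leading eigenvalue), `method`.
#' @export
single_layer_ec <- function(matrix, tol = 1e-10) {
  method <- "ec_single_weighted"
  if (inherits(matrix, "backbone_graph")) {
    w <- matrix$adjacency
    method <- "ec_single_mst"
  } else if (inherits(matrix, "connectivity_matrix")) {
    w <- matrix$weights
  } else {
    w <- as.matrix(matrix)
  }
  if (any(w < 0)) stop("adjacency must be nonnegative")
  if (!is_connected_graph(w)) {
    stop("graph is disconnected: eigenvector centrality is not well-defined")
  }
  ep <- leading_eigenpair(w, tol = tol)
  structure(
    list(scores = ep$vector, lambda = ep$lambda, method = method,
         region_labels = rownames(w)),
    class = "centrality_scores"
  )
}

#' Multilayer eigenvector centrality
#'
#' Computes the leading eigenvector of the supra-adjacency matrix (oriented
#' nonnegative, unit Euclidean norm) and aggregates the `L*N` vector to one
#' score per node by averaging the `L` entries that correspond to the same
#' node. On a connected supra-graph (guaranteed when every layer is a
#' spanning tree and `omega > 0`) the aggregated scores are strictly
#' positive.
#'
#' @param supra A [build_supra_adjacency()] result.
#' @param mapping Optional `atlas_mapping` carried through to the result.
#' @param tol Convergence tolerance of the eigensolver.
#' @return A `centrality_scores` object with `scores` (length N),
#'   `supra_vector` (length `L*N`, unit norm), `lambda`, `method`.
#' @export
multilayer_ec <- function(supra, mapping = NULL, tol = 1e-10) {
  stopifnot(inherits(supra, "supra_adjacency"))
  if (!is_connected_graph(supra$matrix)) {
    stop("supra-adjacency graph is disconnected: the leading eigenvector ",
         "is not strictly positive / not unique")
  }
  ep <- leading_eigenpair(supra$matrix, tol = tol)
  scores <- rowMeans(matrix(ep$vector, nrow = supra$N, ncol = supra$L))
  structure(
    list(scores = scores, supra_vector = ep$vector, lambda = ep$lambda,
         method = "ec_multilayer", region_labels = supra$region_labels,
         mapping = mapping),
    class = "centrality_scores"
  )
}

#' Multilayer (overlapping) degree centrality
#'
#' Per node, the sum of its intralayer degrees across all layers. Interlayer
#' links are excluded: in a multiplex they contribute the same constant
#' `2 * omega * (L - 1)` to every node and carry no between-node
#' information.
#'
#' @param supra A [build_supra_adjacency()] result.
#' @param include_interlayer If `TRUE`, add the constant interlayer
#'   contribution (documented alternative; default `FALSE`).
#' @return A `centrality_scores` object with `method = "degree_multilayer"`.
#' @export
multilayer_degree <- function(supra, include_interlayer = FALSE) {
  stopifnot(inherits(supra, "supra_adjacency"))
  N <- supra$N; L <- supra$L
  total <- numeric(N)
  for (l in seq_len(L)) {
    idx <- (l - 1L) * N + seq_len(N)
    block <- supra$matrix[idx, idx, drop = FALSE]
    total <- total + as.numeric(Matrix::rowSums(block != 0))
  }
  if (include_interlayer && L > 1L) {
    n_coupled <- if (supra$topology == "categorical") {
      rep(L - 1L, L)
    } else {
      ifelse(seq_len(L) %in% c(1L, L) & L > 1L, 1L, 2L)
    }
    total <- total + sum(n_coupled) * ifelse(supra$omega != 0, 1, 0)
  }
  structure(
    list(scores = total, lambda = NA_real_, method = "degree_multilayer",
         region_labels = supra$region_labels),
    class = "centrality_scores"
  )
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat("<centrality_scores> method '", x$method, "', ", length(x$scores),
      " nodes", sep = "")
  if (!is.na(x$lambda)) cat(", lambda = ", format(x$lambda), sep = "")
  cat("\n")
  invisible(x)
}

#' Mean centrality over a subnetwork
#'
#' Arithmetic mean of the node scores over all regions carrying the given
#' subnetwork label (e.g. the FPN), yielding one value per network per
#' subject.
#'
#' @param cv A `centrality_scores` object (or plain numeric vector).
#' @param mapping An `atlas_mapping`.
#' @param label Subnetwork label.
#' @return A single number.
#' @export
subnetwork_mean <- function(cv, mapping, label) {
  scores <- if (inherits(cv, "centrality_scores")) cv$scores else
    as.numeric(cv)
  mask <- subnetwork_mask(mapping, label)
  if (length(scores) != length(mask)) {
    stop("centrality vector length (", length(scores),
         ") does not match atlas size (", length(mask), ")")
  }
  mean(scores[mask])
}
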