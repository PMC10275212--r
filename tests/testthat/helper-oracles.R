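# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (dense eigendecompositions, exhaustive
# enumeration, closed forms) rather than calling the package's own code
# paths.

# analytic-signal phase via an independently coded Hilbert transform
oracle_phase <- function(x) {
  n <- length(x)
  X <- fft(x)
  mult <- rep(0, n)
  mult[1] <- 1
  half <- floor(n / 2)
  if (n %% 2 == 0) {
    mult[half + 1] <- 1
    if (half >= 2) mult[2:half] <- 2
  } else {
    mult[2:(half + 1)] <- 2
  }
  a <- fft(X * mult, inverse = TRUE) / n
  atan2(Im(a), Re(a))
}

# brute-force PLI: |<sign(sin(phase difference))>|
oracle_pli <- function(x, y) {
  dphi <- oracle_phase(x) - oracle_phase(y)
  abs(mean(sign(sin(dphi))))
}

# dense leading-eigenvector oracle (nonnegative orientation, unit norm)
oracle_leading_eigen <- function(m) {
  m <- as.matrix(m)
  ee <- eigen(m, symmetric = TRUE)
  v <- ee$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  list(vector = v, lambda = ee$values[1L])
}

# decode a Pruefer sequence into the edge list of a labelled tree on n nodes
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(seq)) {
    leaf <- which(degree == 1L)[1L]
    v <- seq[k]
    edges[k, ] <- c(leaf, v)
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

# exhaustive maximum-weight spanning tree total over all n^(n-2) trees
oracle_max_weight_tree <- function(w) {
  n <- nrow(w)
  if (n == 2L) return(w[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_decode(as.integer(seqs[r, ]), n)
    tw <- sum(w[ed])
    if (tw > best) best <- tw
  }
  best
}

# uniformly random labelled tree adjacency on n nodes
random_tree_adjacency <- function(n) {
  ed <- if (n == 2L) matrix(c(1L, 2L), 1L) else
    prufer_decode(sample.int(n, n - 2L, replace = TRUE), n)
  a <- matrix(0, n, n)
  a[ed] <- 1
  a + t(a)
}

# random connected weighted graph (complete, distinct positive weights)
random_weighted_graph <- function(n, distinct = TRUE) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- runif(sum(ut), 0.05, 1)
  if (distinct) vals <- rank(vals) / length(vals) + runif(sum(ut), 0, 1e-4)
  w[ut] <- vals
  w <- w + t(w)
  diag(w) <- 0
  w
}

# cohort parameters at desk-scale test sizes (regions, sampling and epoch
# counts reduced; cohort size and effect sizes at their defaults)
test_cohort_params <- function(n_subjects = 40, seed = 1L, ...) {
  cohort_params(n_subjects = n_subjects, n_regions = 35,
                sampling_rate = 128, n_epochs = 6, epoch_len = 256,
                n_volumes = 120, seed = seed, ...)
}

# minimal subject stub for standalone layer generation
test_subject <- function(n_regions = 20, g = 0, sampling_rate = 128,
                         n_epochs = 8, epoch_len = 512) {
  list(subject_id = "stub", latent_g_std = g,
       atlas = make_atlas(n_regions),
       sampling_rate = sampling_rate, n_epochs = n_epochs,
       epoch_len = epoch_len, n_volumes = 120, tr = 1.52)
}

# per-subject multilayer FPN summaries for replicate suites (lighter than
# run_pipeline: skips the stepwise stage)
pipeline_fpn_table <- function(cohort) {
  feats <- do.call(rbind, lapply(cohort$subjects, subject_features,
                                 atlas = cohort$atlas))
  cbind(cohort$covariates, feats[, -1L, drop = FALSE])
}
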