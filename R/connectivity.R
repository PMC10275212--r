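#' Canonical MEG frequency bands
#'
#' The six canonical frequency bands used throughout the package: delta
#' (0.5--4 Hz), theta (4--8 Hz), lower alpha (8--10 Hz), upper alpha
#' (10--13 Hz), beta (13--30 Hz) and gamma (30--48 Hz). Adjacent bands share
#' their boundary; the band-pass convention `[f_lo, f_hi)` keeps each Fourier
#' bin in exactly one band.
#'
#' @return A data frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "lower_alpha", "upper_alpha", "beta", "gamma"),
    f_lo = c(0.5, 4, 8, 10, 13, 30),
    f_hi = c(4, 8, 10, 13, 30, 48),
    stringsAsFactors = FALSE
  )
}

#' Look up a band specification by name
#'
#' @param name One of `"delta"`, `"theta"`, `"lower_alpha"`, `"upper_alpha"`,
#'   `"beta"`, `"gamma"`.
#' @return A list with elements `name`, `f_lo`, `f_hi`.
#' @export
band_spec <- function(name) {
  tab <- canonical_bands()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown frequency band '", name, "'; must be one of ",
         paste(tab$name, collapse = ", "))
  }
  list(name = tab$name[i], f_lo = tab$f_lo[i], f_hi = tab$f_hi[i])
}

#' Epoched regional time series
#'
#' Container for epoched multichannel time series (one channel per atlas
#' region), as produced by source-reconstructed MEG or by averaging BOLD
#' signal within atlas regions.
#'
#' @param values A numeric array of dimension `epochs x samples x regions`,
#'   or a `samples x regions` matrix (treated as a single epoch).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param region_labels Optional character vector of region names.
#' @return An object of class `epoched_series`.
#' @export
epoched_series <- function(values, sampling_rate, region_labels = NULL) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(1L, nrow(values), ncol(values)))
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be an epochs x samples x regions array")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("'sampling_rate' must be a single positive number")
  }
  n_reg <- dim(values)[3L]
  if (is.null(region_labels)) {
    region_labels <- paste0("R", sprintf("%03d", seq_len(n_reg)))
  }
  if (length(region_labels) != n_reg) {
    stop("length of 'region_labels' (", length(region_labels),
         ") does not match region count (", n_reg, ")")
  }
  structure(
    list(values = values, sampling_rate = sampling_rate,
         region_labels = as.character(region_labels)),
    class = "epoched_series"
  )
}

#' @export
print.epoched_series <- function(x, ...) {
  d <- dim(x$values)
  cat("<epoched_series> ", d[1L], " epochs x ", d[2L], " samples x ",
      d[3L], " regions @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

n_epochs <- function(series) dim(series$values)[1L]
n_samples <- function(series) dim(series$values)[2L]
n_regions_of <- function(series) dim(series$values)[3L]

#' Weighted connectivity matrix for one subject and layer
#'
#' @param weights Symmetric nonnegative `N x N` numeric matrix with zero
#'   diagonal.
#' @param modality Layer tag (e.g. a band name, `"rsfmri"`, `"dmri"`).
#' @param subject_id Optional subject identifier.
#' @param region_labels Optional region names (stored as dimnames).
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, modality, subject_id = NA_character_,
                                region_labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("'weights' must be square")
  if (!is.null(region_labels)) {
    dimnames(weights) <- list(region_labels, region_labels)
  }
  structure(
    list(weights = weights, modality = as.character(modality),
         subject_id = subject_id),
    class = "connectivity_matrix"
  )
}

#' @export
as.matrix.connectivity_matrix <- function(x, ...) x$weights

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x$weights), " regions, modality '",
      x$modality, "'", sep = "")
  if (!is.na(x$subject_id)) cat(", subject '", x$subject_id, "'", sep = "")
  cat("\n")
  invisible(x)
}

# frequency of each DFT bin folded to [0, fs/2]
folded_freqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

#' Band-pass filter epoched time series by Fourier masking
#'
#' Applies, per epoch and region, a brickwall frequency-domain filter:
#' Fourier coefficients whose absolute frequency lies outside
#' `[f_lo, f_hi)` are zeroed and the series is inverse-transformed. The
#' half-open convention makes adjacent canonical bands partition the
#' spectrum without double-counting shared boundaries.
#'
#' @param series An [epoched_series].
#' @param band A band specification from [band_spec()] (or any list with
#'   `name`, `f_lo`, `f_hi`).
#' @return A filtered [epoched_series] of identical shape.
#' @export
bandpass <- function(series, band) {
  stopifnot(inherits(series, "epoched_series"))
  fs <- series$sampling_rate
  S <- n_samples(series)
  if (S < 2L) stop("epochs must contain at least 2 samples")
  if (band$f_hi >= fs / 2) {
    stop("band '", band$name, "' has f_hi = ", band$f_hi,
         " Hz at or above the Nyquist frequency (", fs / 2, " Hz)")
  }
  f <- folded_freqs(S, fs)
  keep <- f >= band$f_lo & f < band$f_hi
  out <- series$values
  for (e in seq_len(n_epochs(series))) {
    X <- mvfft(matrix(series$values[e, , ], nrow = S))
    X[!keep, ] <- 0+0i
    out[e, , ] <- Re(mvfft(X, inverse = TRUE)) / S
  }
  epoched_series(out, fs, series$region_labels)
}

#' Analytic signal via the Hilbert transform
#'
#' @param x A real numeric vector (length >= 2).
#' @return A complex vector whose argument is the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Phase lag index between two signals
#'
#' The phase lag index (PLI) is the absolute mean sign of the instantaneous
#' phase difference between the analytic signals of `x` and `y`:
#' `PLI = |mean(sign(sin(phi_x - phi_y)))|`. Samples where the phase
#' difference is exactly 0 or pi contribute 0. PLI is 0 for consistently
#' zero-lag (or no) coupling and 1 for a perfectly consistent nonzero lag,
#' and is invariant to channel amplitude rescaling.
#'
#' @param x,y Real numeric vectors of equal length (>= 16), non-constant.
#' @return A number in `[0, 1]`.
#' @export
pli_pair <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 16L) stop("need at least 16 samples")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant input signal: instantaneous phase is undefined")
  }
  ax <- analytic_signal(x)
  ay <- analytic_signal(y)
  # Im(ax * Conj(ay)) = |ax||ay| sin(phi_x - phi_y): its sign is the sign of
  # the wrapped phase difference, with exact 0 / pi ties contributing 0
  abs(mean(sign(Im(ax * Conj(ay)))))
}

#' PLI connectivity matrix for one frequency band
#'
#' Band-pass filters the series (see [bandpass()]), extracts instantaneous
#' phases via the analytic signal, and computes the phase lag index for every
#' pair of regions. With `epoch_average = TRUE` (default) the PLI is computed
#' per epoch and averaged across epochs; otherwise epochs are concatenated
#' and a single PLI is computed.
#'
#' @param series An [epoched_series].
#' @param band A band specification from [band_spec()].
#' @param epoch_average Average per-epoch PLI matrices (default) or
#'   concatenate epochs first.
#' @param subject_id Optional subject identifier for the result.
#' @return A [connectivity_matrix] with entries in `[0, 1]`, zero diagonal.
#' @export
pli_matrix <- function(series, band, epoch_average = TRUE,
                       subject_id = NA_character_) {
  stopifnot(inherits(series, "epoched_series"))
  fs <- series$sampling_rate
  S <- n_samples(series)
  N <- n_regions_of(series)
  E <- n_epochs(series)
  if (E < 1L) stop("need at least one epoch")
  if (band$f_hi >= fs / 2) {
    stop("band '", band$name, "' has f_hi = ", band$f_hi,
         " Hz at or above the Nyquist frequency (", fs / 2, " Hz)")
  }
  f <- folded_freqs(S, fs)
  pos <- c(FALSE, rep(TRUE, ceiling(S / 2) - 1L),
           rep(FALSE, S - ceiling(S / 2)))
  h <- ifelse(f >= band$f_lo & f < band$f_hi & pos, 2, 0)
  analytic_of_epoch <- function(mat) {
    Z <- mvfft(mat) * h
    mvfft(Z, inverse = TRUE) / S
  }
  if (epoch_average) {
    acc <- matrix(0, N, N)
    for (e in seq_len(E)) {
      A <- analytic_of_epoch(matrix(series$values[e, , ], nrow = S))
      acc <- acc + pli_epoch_cpp(Re(A), Im(A))
    }
    W <- acc / E
  } else {
    mat <- matrix(aperm(series$values, c(2L, 1L, 3L)), nrow = S * E)
    # concatenated series: filter per epoch, then a single PLI pass
    A <- matrix(0+0i, S * E, N)
    for (e in seq_len(E)) {
      idx <- (e - 1L) * S + seq_len(S)
      A[idx, ] <- analytic_of_epoch(matrix(series$values[e, , ], nrow = S))
    }
    W <- pli_epoch_cpp(Re(A), Im(A))
  }
  diag(W) <- 0
  connectivity_matrix(W, modality = band$name, subject_id = subject_id,
                      region_labels = series$region_labels)
}

#' Absolutized Pearson correlation connectivity matrix
#'
#' Pearson correlation between all pairs of regional time series, with
#' coefficients absolutized (negative correlations may carry relevant
#' coupling information, and most network metrics require nonnegative
#' weights). Intended for the BOLD-like layer, computed on the full
#' (non-epoched) acquisition.
#'
#' @param x A `samples x regions` numeric matrix, or a single-epoch
#'   [epoched_series] (multi-epoch input is concatenated).
#' @param subject_id Optional subject identifier.
#' @param region_labels Optional region names.
#' @return A [connectivity_matrix] with entries in `[0, 1]`, zero diagonal.
#' @export
correlation_matrix <- function(x, subject_id = NA_character_,
                               region_labels = NULL) {
  if (inherits(x, "epoched_series")) {
    if (is.null(region_labels)) region_labels <- x$region_labels
    x <- matrix(aperm(x$values, c(2L, 1L, 3L)),
                nrow = dim(x$values)[1L] * dim(x$values)[2L])
  }
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 samples")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    lab <- if (!is.null(region_labels)) region_labels[bad] else bad
    stop("constant time series for region(s): ",
         paste(lab, collapse = ", "))
  }
  W <- abs(cor(x))
  diag(W) <- 0
  connectivity_matrix(W, modality = "rsfmri", subject_id = subject_id,
                      region_labels = region_labels)
}

#' Validate an ingested structural connectivity matrix
#'
#' Checks that a raw streamline-count matrix is square, symmetric (to
#' tolerance), nonnegative, and has a (near-)zero diagonal, which is zeroed
#' if within tolerance.
#'
#' @param m A square numeric matrix.
#' @param subject_id Optional subject identifier.
#' @param region_labels Optional region names.
#' @param tol Absolute tolerance for symmetry and diagonal checks.
#' @return A [connectivity_matrix] tagged with modality `"dmri"`.
#' @export
validate_structural <- function(m, subject_id = NA_character_,
                                region_labels = NULL, tol = 1e-9) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("structural matrix must be square")
  if (!is.numeric(m)) stop("structural matrix must be numeric")
  if (max(abs(m - t(m))) > tol) {
    stop("structural matrix is asymmetric beyond tolerance ", tol)
  }
  if (any(m < 0)) stop("structural matrix has negative entries")
  if (any(abs(diag(m)) > tol)) {
    stop("structural matrix has nonzero diagonal entries beyond tolerance ",
         tol)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (is.null(region_labels) && !is.null(rownames(m))) {
    region_labels <- rownames(m)
  }
  connectivity_matrix(m, modality = "dmri", subject_id = subject_id,
                      region_labels = region_labels)
}

drop_regions_matrix <- function(w, bad) {
  w[-bad, -bad, drop = FALSE]
}

#' Exclude atlas regions from all layers
#'
#' Removes the given regions (e.g., regions with rsfMRI signal loss) from
#' every connectivity matrix of every subject and from the atlas mapping, so
#' that all layers keep an identical region ordering. Exclusion is global:
#' the same index list is applied to every subject and layer.
#'
#' @param x A [connectivity_matrix], a plain square matrix, a list of either
#'   (possibly nested, e.g. subjects of layers), or an `atlas_mapping`.
#' @param bad_regions Integer vector of 1-based region indices to remove.
#' @return Object of the same shape with the regions removed everywhere.
#' @export
exclude_regions <- function(x, bad_regions) {
  if (length(bad_regions) == 0L) return(x)
  bad_regions <- as.integer(bad_regions)
  if (anyDuplicated(bad_regions)) stop("duplicated region indices")
  exclude_one <- function(obj) {
    if (inherits(obj, "connectivity_matrix")) {
      check_idx(bad_regions, nrow(obj$weights))
      obj$weights <- drop_regions_matrix(obj$weights, bad_regions)
      obj
    } else if (inherits(obj, "atlas_mapping")) {
      check_idx(bad_regions, nrow(obj))
      out <- obj[-bad_regions, , drop = FALSE]
      out$region_index <- seq_len(nrow(out)) - 1L
      rownames(out) <- NULL
      out
    } else if (is.matrix(obj)) {
      check_idx(bad_regions, nrow(obj))
      drop_regions_matrix(obj, bad_regions)
    } else if (is.list(obj)) {
      lapply(obj, exclude_one)
    } else {
      stop("cannot exclude regions from object of class ",
           paste(class(obj), collapse = "/"))
    }
  }
  exclude_one(x)
}

check_idx <- function(idx, n) {
  if (any(idx < 1L) || any(idx > n)) {
    stop("region indices out of range 1..", n)
  }
  invisible(TRUE)
}
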