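#' Read a connectivity matrix from delimited text
#'
#' Reads a square numeric matrix stored as tab-delimited text with a header
#' row of region labels. If an atlas mapping is supplied and the header
#' labels are a permutation of the atlas's region names, rows and columns
#' are reordered to atlas order (with a message).
#'
#' @param path File path.
#' @param modality Layer tag to attach.
#' @param subject_id Optional subject identifier.
#' @param atlas Optional `atlas_mapping` fixing the region order.
#' @return A [connectivity_matrix].
#' @export
read_matrix <- function(path, modality = "unknown",
                        subject_id = NA_character_, atlas = NULL) {
  df <- tryCatch(
    read.delim(path, header = TRUE, check.names = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e))
  )
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    stop("non-numeric cells in '", path, "' (column ",
         paste(names(df)[bad], collapse = ", "), ")")
  }
  if (nrow(m) != ncol(m)) {
    stop("matrix in '", path, "' is not square: ", nrow(m), " x ", ncol(m))
  }
  labels <- colnames(m)
  rownames(m) <- labels
  if (!is.null(atlas)) {
    ref <- atlas$region_name
    if (!setequal(labels, ref) || length(labels) != length(ref)) {
      stop("region labels in '", path, "' do not match the atlas mapping")
    }
    if (!identical(labels, ref)) {
      perm <- match(ref, labels)
      m <- m[perm, perm, drop = FALSE]
      message("reordered '", basename(path), "' to atlas region order")
    }
  }
  connectivity_matrix(m, modality = modality, subject_id = subject_id)
}

#' Write a connectivity matrix as delimited text
#'
#' @param x A [connectivity_matrix] or square matrix.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(x, path) {
  m <- if (inherits(x, "connectivity_matrix")) x$weights else as.matrix(x)
  if (is.null(colnames(m))) {
    colnames(m) <- paste0("R", sprintf("%03d", seq_len(ncol(m))))
  }
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read / write an atlas mapping file
#'
#' CSV with columns `region_index` (0-based), `region_name`, `subnetwork`.
#'
#' @param path File path.
#' @return For `read_atlas`, an `atlas_mapping`; `write_atlas` returns the
#'   path invisibly.
#' @export
read_atlas <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_index", "region_name", "subnetwork")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("atlas file lacks column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[order(df$region_index), need]
  rownames(df) <- NULL
  class(df) <- c("atlas_mapping", "data.frame")
  df
}

#' @rdname read_atlas
#' @param atlas An `atlas_mapping`.
#' @export
write_atlas <- function(atlas, path) {
  write.csv(as.data.frame(atlas), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# epoched series <-> delimited text: first column the epoch index, then one
# column per region, one row per sample
write_series <- function(series, path) {
  E <- dim(series$values)[1L]; S <- dim(series$values)[2L]
  N <- dim(series$values)[3L]
  flat <- matrix(aperm(series$values, c(2L, 1L, 3L)), nrow = E * S)
  out <- data.frame(epoch = rep(seq_len(E), each = S), flat)
  names(out) <- c("epoch", series$region_labels)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_series <- function(path, sampling_rate) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  ep <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  E <- length(unique(ep))
  S <- nrow(mat) / E
  if (S != floor(S)) stop("ragged epochs in '", path, "'")
  vals <- array(0, dim = c(E, S, ncol(mat)))
  for (e in seq_len(E)) {
    vals[e, , ] <- mat[ep == unique(ep)[e], , drop = FALSE]
  }
  epoched_series(vals, sampling_rate, colnames(mat))
}

#' Write a synthetic cohort to a directory tree
#'
#' One sub-directory per subject holding `<layer>.tsv` files (matrices for
#' matrix layers, epoch-indexed series for time-series layers), plus a
#' cohort covariate table `covariates.csv` and the atlas mapping
#' `atlas.csv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE, quote = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.csv"))
  for (subj in cohort$subjects) {
    sdir <- file.path(dir, subj$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (nm in names(subj$layers)) {
      layer <- subj$layers[[nm]]
      path <- file.path(sdir, paste0(nm, ".tsv"))
      if (inherits(layer, "epoched_series")) {
        write_series(layer, path)
      } else {
        write_matrix(layer, path)
      }
    }
  }
  invisible(dir)
}

#' Read a cohort directory tree written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param sampling_rate,tr Sampling rates (Hz / seconds) of the band layers
#'   and BOLD-like layer, used to re-attach timing to the series files.
#' @return A list with `subjects`, `covariates`, `atlas` (layer objects as
#'   in a generated cohort; generator-only fields are absent).
#' @export
read_cohort <- function(dir, sampling_rate = 1250, tr = 1.52) {
  covariates <- read.csv(file.path(dir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  atlas <- read_atlas(file.path(dir, "atlas.csv"))
  subjects <- lapply(covariates$subject_id, function(sid) {
    sdir <- file.path(dir, sid)
    layers <- stats::setNames(vector("list", 8L), layer_names())
    for (nm in layer_names()) {
      path <- file.path(sdir, paste0(nm, ".tsv"))
      if (!file.exists(path)) {
        stop("subject '", sid, "' is missing layer '", nm, "'")
      }
      layers[[nm]] <- if (nm == "dmri") {
        read_matrix(path, modality = "dmri", subject_id = sid, atlas = atlas)
      } else if (nm == "rsfmri") {
        read_series(path, 1 / tr)
      } else {
        read_series(path, sampling_rate)
      }
    }
    row <- covariates[covariates$subject_id == sid, , drop = FALSE]
    list(subject_id = sid, age = row$age,
         cognition = list(EF = row$EF), layers = layers, atlas = atlas)
  })
  list(subjects = subjects, covariates = covariates, atlas = atlas)
}
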