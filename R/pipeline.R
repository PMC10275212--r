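#' Pipeline configuration
#'
#' Settings for the end-to-end analysis: which single-layer summaries use
#' the MST backbone versus the full weighted matrix, the interlayer
#' coupling, the stepwise-regression settings, and the subnetwork of
#' interest.
#'
#' @param subnetwork Subnetwork whose mean centrality is analysed.
#' @param omega Interlayer coupling weight of the multiplex.
#' @param topology Interlayer coupling topology, `"categorical"` or
#'   `"chain"`.
#' @param meg_single_layer,other_single_layer Whether single-layer
#'   eigenvector centrality of the MEG bands / of the BOLD-like and
#'   structural layers is computed on the `"mst"` backbone or the full
#'   `"weighted"` matrix (defaults: MST for MEG, weighted otherwise).
#' @param epoch_average Average PLI across epochs (default) or concatenate.
#' @param direction,p_remove,p_enter,block2_entry Stepwise-regression
#'   settings, see [stepwise_blockwise()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(subnetwork = "FPN", omega = 1,
                            topology = c("categorical", "chain"),
                            meg_single_layer = c("mst", "weighted"),
                            other_single_layer = c("weighted", "mst"),
                            epoch_average = TRUE,
                            direction = c("backward", "forward"),
                            p_remove = 0.10, p_enter = 0.05,
                            block2_entry = c("before", "after")) {
  structure(
    list(subnetwork = subnetwork, omega = omega,
         topology = match.arg(topology),
         meg_single_layer = match.arg(meg_single_layer),
         other_single_layer = match.arg(other_single_layer),
         epoch_average = epoch_average,
         direction = match.arg(direction),
         p_remove = p_remove, p_enter = p_enter,
         block2_entry = match.arg(block2_entry)),
    class = "pipeline_config"
  )
}

#' Connectivity matrices for one subject's eight layers
#'
#' Turns a subject's raw layers into weighted connectivity matrices: PLI for
#' the six band-specific series, absolutized correlation for the BOLD-like
#' series, and the validated structural matrix.
#'
#' @param subject A subject list (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @return Named list of eight [connectivity_matrix] objects.
#' @export
subject_connectivity <- function(subject, config = pipeline_config()) {
  bands <- canonical_bands()$name
  mats <- stats::setNames(vector("list", 8L), layer_names())
  for (b in bands) {
    mats[[b]] <- pli_matrix(subject$layers[[b]], band_spec(b),
                            epoch_average = config$epoch_average,
                            subject_id = subject$subject_id)
  }
  mats[["rsfmri"]] <- correlation_matrix(subject$layers[["rsfmri"]],
                                         subject_id = subject$subject_id)
  dm <- subject$layers[["dmri"]]
  mats[["dmri"]] <- validate_structural(
    if (inherits(dm, "connectivity_matrix")) dm$weights else dm,
    subject_id = subject$subject_id)
  mats
}

#' Network features for one subject
#'
#' Chains one subject through the pipeline stages: eight connectivity
#' matrices, eight MST backbones, the supra-adjacency multiplex, multilayer
#' eigenvector and degree centrality, and the eight single-layer
#' centralities, each averaged over the configured subnetwork.
#'
#' @param subject A subject list.
#' @param atlas An `atlas_mapping`.
#' @param config A [pipeline_config()].
#' @return A one-row data frame of subnetwork-mean centralities.
#' @export
subject_features <- function(subject, atlas, config = pipeline_config()) {
  mats <- subject_connectivity(subject, config)
  backbones <- lapply(mats, mst_backbone)
  supra <- build_supra_adjacency(backbones, omega = config$omega,
                                 topology = config$topology)
  mec <- multilayer_ec(supra, mapping = atlas)
  mdeg <- multilayer_degree(supra)
  sub <- config$subnetwork
  single <- vapply(layer_names(), function(nm) {
    use_mst <- if (nm %in% c("rsfmri", "dmri")) {
      config$other_single_layer == "mst"
    } else {
      config$meg_single_layer == "mst"
    }
    ec <- if (use_mst) single_layer_ec(backbones[[nm]]) else
      single_layer_ec(mats[[nm]])
    subnetwork_mean(ec, atlas, sub)
  }, numeric(1))
  out <- data.frame(
    subject_id = subject$subject_id,
    fpn_ec_multilayer = subnetwork_mean(mec, atlas, sub),
    fpn_degree_multilayer = subnetwork_mean(mdeg, atlas, sub),
    stringsAsFactors = FALSE
  )
  for (nm in layer_names()) out[[paste0("fpn_ec_", nm)]] <- single[[nm]]
  out
}

#' Run the full multilayer analysis pipeline on a cohort
#'
#' Per subject: eight connectivity matrices, eight MST backbones, the
#' binary multiplex supra-adjacency, multilayer eigenvector and degree
#' centrality and single-layer centralities, each summarized over the
#' subnetwork of interest; then the statistical stage: blockwise stepwise
#' regression of the cognition score on the eight single-layer subnetwork
#' centralities (block 1) with the multilayer centrality forced in block 2,
#' and the hierarchical quadratic age model for the multilayer centrality.
#'
#' @param cohort A [generate_cohort()] (or [read_cohort()]) result.
#' @param config A [pipeline_config()].
#' @param cognition Name of the cognition variable in the covariate table.
#' @return A list of class `pipeline_result`: `features` (per-subject
#'   table joined with covariates), `regression` (the [stepwise_blockwise()]
#'   fit), `age_model` (the [hierarchical_quadratic()] fit), `loocv_r2`
#'   (cross-validated R-squared of the final regression model), `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         cognition = "EF") {
  atlas <- cohort$atlas
  feats <- lapply(cohort$subjects, function(subj) {
    for (nm in layer_names()) {
      if (is.null(subj$layers[[nm]])) {
        stop("pipeline aborted at stage 'connectivity': subject '",
             subj$subject_id, "' is missing layer '", nm, "'")
      }
    }
    tryCatch(
      subject_features(subj, atlas, config),
      error = function(e) {
        stop("pipeline aborted for subject '", subj$subject_id, "': ",
             conditionMessage(e))
      }
    )
  })
  features <- do.call(rbind, feats)
  features <- merge(cohort$covariates, features, by = "subject_id",
                    sort = TRUE)
  single_cols <- paste0("fpn_ec_", layer_names())
  regression <- stepwise_blockwise(
    features, response = cognition,
    block1 = single_cols, block2 = "fpn_ec_multilayer",
    direction = config$direction, p_remove = config$p_remove,
    p_enter = config$p_enter, block2_entry = config$block2_entry)
  age_model <- hierarchical_quadratic(features$age,
                                      features$fpn_ec_multilayer)
  final_preds <- regression$models[[length(regression$models)]]$predictors
  cv <- if (length(final_preds)) {
    loocv_r2(features[, final_preds, drop = FALSE], features[[cognition]])
  } else NA_real_
  structure(
    list(features = features, regression = regression,
         age_model = age_model, loocv_r2 = cv, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$features), " subjects\n", sep = "")
  print(x$regression)
  cat(sprintf("  age model: delta R2 (age^2) = %.3f, F(%g, %g) = %.3f, p = %.4f\n",
              x$age_model$delta_r2, x$age_model$df_change[1L],
              x$age_model$df_change[2L], x$age_model$f_change,
              x$age_model$p_change))
  if (!is.na(x$loocv_r2)) {
    cat(sprintf("  LOOCV R2 of final model: %.2f\n", x$loocv_r2))
  }
  invisible(x)
}
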