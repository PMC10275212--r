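#' Phase-coupling parameters of the oscillatory generator
#'
#' Controls how strongly regional phase oscillators are coupled within
#' subnetwork modules, how often modules phase-lock to a global integration
#' rhythm, and how the fronto-parietal lock probability scales with the
#' subject's latent integration factor. Because two drifting oscillators
#' only show a consistent phase lag while both track the same reference,
#' locking is modelled as an epoch-level regime: in each epoch a module
#' either follows its own rhythm or the global one, and the epoch-averaged
#' phase lag index between two modules grows with the probability that both
#' are locked simultaneously.
#'
#' @param within Weight of the shared reference phase in each region's phase
#'   mixture (0 = independent regions; must stay > 0.5 for within-module
#'   locking).
#' @param between Per-epoch probability that a non-FPN module locks to the
#'   global integration rhythm.
#' @param fpn_base,fpn_gain,fpn_scale The FPN module locks with probability
#'   `fpn_base + fpn_gain * plogis(fpn_scale * g)`, a bounded monotone
#'   function of the standardized latent integration factor `g`.
#' @param phase_diffusion Variance rate of the Wiener phase noise of each
#'   oscillator, rad^2/s.
#' @param phase_jitter_sd Per-sample iid phase jitter, rad.
#' @param obs_noise_sd Additive white measurement noise on the signals.
#' @return A list of class `coupling_params`.
#' @export
coupling_params <- function(within = 0.85, between = 0.35,
                            fpn_base = 0.15, fpn_gain = 0.6,
                            fpn_scale = 1.5, phase_diffusion = 4,
                            phase_jitter_sd = 0.4, obs_noise_sd = 0.2) {
  structure(
    list(within = within, between = between, fpn_base = fpn_base,
         fpn_gain = fpn_gain, fpn_scale = fpn_scale,
         phase_diffusion = phase_diffusion,
         phase_jitter_sd = phase_jitter_sd, obs_noise_sd = obs_noise_sd),
    class = "coupling_params"
  )
}

#' Parameters of a synthetic multimodal cohort
#'
#' Defines the cohort the generator emulates: subjects aged 20--70 with a
#' latent "FPN integration" factor that follows a quadratic (inverted-U) age
#' trend, an executive-functioning (EF) z-score coupled to that factor, six
#' MEG-band layers of phase-coupled oscillators, one BOLD-like layer and one
#' heavy-tailed structural layer.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Number of atlas regions (default 60; a 197-region preset
#'   mirrors the post-exclusion parcel count of the full atlas).
#' @param subnetwork_sizes Optional named partition over the seven canonical
#'   subnetworks (see [make_atlas()]).
#' @param age_range Ages are drawn uniformly over this interval (years).
#' @param age_quad_coeffs `(a0, a1, a2)` of the latent trend
#'   `g = a0 + a1*age + a2*age^2 + N(0, noise_sd)`. The default peaks at age
#'   45 with a range of about 1 over 20--70 and `a2 < 0` (inverted U).
#' @param effect_slope Cognition slope: `EF = effect_slope * standardize(g)
#'   + N(0, noise_sd)`.
#' @param noise_sd Standard deviation of the latent and cognition noise.
#' @param sampling_rate MEG-like sampling rate, Hz.
#' @param n_epochs,epoch_len Number of epochs and samples per epoch of the
#'   band-specific series (defaults 88 x 4096, i.e. 3.28 s epochs at
#'   1250 Hz).
#' @param n_volumes Number of BOLD-like volumes (default 306 at TR 1.52 s).
#' @param tr Repetition time of the BOLD-like layer, seconds.
#' @param coupling A [coupling_params()] object.
#' @param seed Integer seed; identical parameters give bit-identical cohorts.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 40, n_regions = 60,
                          subnetwork_sizes = NULL,
                          age_range = c(20, 70),
                          age_quad_coeffs = c(-3.24, 0.144, -0.0016),
                          effect_slope = 0.8, noise_sd = 0.4,
                          sampling_rate = 1250, n_epochs = 88,
                          epoch_len = 4096, n_volumes = 306, tr = 1.52,
                          coupling = coupling_params(), seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be a positive integer")
  if (n_regions < 10L) {
    stop("n_regions = ", n_regions,
         " is too small for a 7-subnetwork partition (need >= 10)")
  }
  atlas <- make_atlas(n_regions, subnetwork_sizes)
  if (length(age_range) != 2L || age_range[1L] >= age_range[2L]) {
    stop("age_range must be (lower, upper) with lower < upper")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(age_quad_coeffs) != 3L) {
    stop("age_quad_coeffs must be (a0, a1, a2)")
  }
  if (sampling_rate <= 0 || n_epochs < 1L || epoch_len < 2L) {
    stop("invalid sampling parameters")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_regions = as.integer(n_regions), atlas = atlas,
         age_range = age_range, age_quad_coeffs = age_quad_coeffs,
         effect_slope = effect_slope, noise_sd = noise_sd,
         sampling_rate = sampling_rate, n_epochs = as.integer(n_epochs),
         epoch_len = as.integer(epoch_len),
         n_volumes = as.integer(n_volumes), tr = tr,
         coupling = coupling, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' Epoch duration implied by the sampling parameters
#'
#' @param params A [cohort_params()] object (or anything with
#'   `epoch_len` and `sampling_rate` fields).
#' @return Duration of one epoch in seconds (e.g. 4096 samples at 1250 Hz =
#'   3.2768 s, printed as 3.28 s at two decimals).
#' @export
epoch_duration <- function(params) {
  params$epoch_len / params$sampling_rate
}

layer_names <- function() {
  c("delta", "theta", "lower_alpha", "upper_alpha", "beta", "gamma",
    "rsfmri", "dmri")
}

# bounded monotone map from latent integration to the FPN lock probability
fpn_lock_prob <- function(coupling, g) {
  coupling$fpn_base + coupling$fpn_gain * stats::plogis(coupling$fpn_scale * g)
}

#' Generate one band-specific epoched oscillatory series
#'
#' Produces phase-coupled stochastic oscillators with carrier frequencies
#' inside the requested band. Each region's phase is the argument of a
#' mixture of its own noisy phase walk and a shared reference phase: within
#' each epoch a module's reference is either its own module rhythm or, with
#' the module's lock probability, a global integration rhythm shared by all
#' locked modules. The FPN lock probability scales monotonically with the
#' subject's latent integration factor, so the phase lag index between FPN
#' and other modules grows with integration. Fixed nonzero per-region phase
#' offsets keep the phase lag index of coupled pairs away from zero.
#'
#' @param subject A subject list carrying `latent_g_std` (standardized latent
#'   integration), `atlas`, `sampling_rate`, `n_epochs`, `epoch_len` (as
#'   produced by [generate_cohort()], or assembled by hand).
#' @param band Band name or [band_spec()] list.
#' @param module_coupling A [coupling_params()] object.
#' @param seed Integer seed.
#' @return An [epoched_series].
#' @export
generate_band_series <- function(subject, band,
                                 module_coupling = coupling_params(),
                                 seed = 1L) {
  if (is.character(band)) band <- band_spec(band)
  if (!band$name %in% canonical_bands()$name) {
    stop("unknown frequency band '", band$name, "'")
  }
  atlas <- subject$atlas
  fs <- subject$sampling_rate
  E <- subject$n_epochs
  S <- subject$epoch_len
  N <- nrow(atlas)
  g <- if (!is.null(subject$latent_g_std)) subject$latent_g_std else 0
  cp <- module_coupling
  set.seed(seed)

  nets <- unique(atlas$subnetwork)
  K <- length(nets)
  m_idx <- match(atlas$subnetwork, nets)
  step_sd <- sqrt(cp$phase_diffusion / fs)
  # per-module, per-band carriers from the interior of the band (plus one
  # for the global integration rhythm and one per region for its own walk)
  f_mod <- band$f_lo + (0.25 + 0.5 * runif(K + 1L)) * (band$f_hi - band$f_lo)
  f_own <- band$f_lo + (0.25 + 0.5 * runif(N)) * (band$f_hi - band$f_lo)
  lag <- runif(N, 0.1 * pi, 0.9 * pi) * sample(c(-1, 1), N, replace = TRUE)
  p_lock <- ifelse(nets == "FPN", fpn_lock_prob(cp, g), cp$between)
  w_ref <- cp$within
  w_own <- 1 - w_ref

  tt <- seq_len(S)
  vals <- array(0, dim = c(E, S, N))
  for (e in seq_len(E)) {
    walks <- matrix(rnorm(S * (K + 1L), sd = step_sd), S, K + 1L)
    psi <- 2 * pi * outer(tt / fs, f_mod) + apply(walks, 2L, cumsum)
    locked <- runif(K) < p_lock
    ref <- psi[, seq_len(K), drop = FALSE]
    if (any(locked)) ref[, locked] <- psi[, K + 1L]
    theta <- 2 * pi * outer(tt / fs, f_own) +
      apply(matrix(rnorm(S * N, sd = step_sd), S, N), 2L, cumsum)
    v <- w_own * exp(1i * theta) + w_ref * exp(1i * ref[, m_idx, drop = FALSE])
    phi <- Arg(v) + rep(lag, each = S) +
      rnorm(S * N, sd = cp$phase_jitter_sd)
    vals[e, , ] <- sin(phi) + rnorm(S * N, sd = cp$obs_noise_sd)
  }
  epoched_series(vals, fs, atlas$region_name)
}

# BOLD-like regional series: module factor model with a global integration
# factor whose FPN loading scales with the latent integration factor
generate_bold_series <- function(subject, coupling = coupling_params(),
                                 seed = 1L) {
  atlas <- subject$atlas
  N <- nrow(atlas)
  Tn <- subject$n_volumes
  g <- if (!is.null(subject$latent_g_std)) subject$latent_g_std else 0
  set.seed(seed)
  nets <- unique(atlas$subnetwork)
  Fm <- matrix(rnorm(Tn * length(nets)), Tn, length(nets))
  G <- rnorm(Tn)
  b <- 0.5
  gamma <- ifelse(atlas$subnetwork == "FPN",
                  0.2 + 0.3 * stats::plogis(coupling$fpn_scale * g), 0.2)
  eps <- matrix(rnorm(Tn * N), Tn, N)
  m_idx <- match(atlas$subnetwork, nets)
  w_res <- sqrt(pmax(1 - b^2 - gamma^2, 0.05))
  x <- sweep(eps, 2L, w_res, "*") + b * Fm[, m_idx] + outer(G, gamma)
  epoched_series(x, 1 / subject$tr, atlas$region_name)
}

#' Generate a heavy-tailed modular structural matrix
#'
#' Log-normal (right-skewed) streamline-count-like weights, heavier within
#' subnetwork modules, symmetric with zero diagonal and connected.
#'
#' @param subject A subject list carrying `atlas` (see
#'   [generate_band_series()]).
#' @param params A [cohort_params()] object (reserved for future weight
#'   scaling options; the atlas is taken from `subject`).
#' @param seed Integer seed.
#' @return A [connectivity_matrix] with modality `"dmri"`.
#' @export
generate_structural_matrix <- function(subject, params = NULL, seed = 1L) {
  atlas <- subject$atlas
  N <- nrow(atlas)
  set.seed(seed)
  same_mod <- outer(atlas$subnetwork, atlas$subnetwork, "==")
  meanlog <- ifelse(same_mod, 1.1, 0)
  w <- matrix(0, N, N)
  ut <- upper.tri(w)
  w[ut] <- rlnorm(sum(ut), meanlog = meanlog[ut], sdlog = 1)
  w <- w + t(w)
  diag(w) <- 0
  connectivity_matrix(w, modality = "dmri",
                      subject_id = subject$subject_id,
                      region_labels = atlas$region_name)
}

#' Generate a synthetic multimodal cohort
#'
#' Draws `n_subjects` subjects with uniform ages, a latent integration
#' factor `g = a0 + a1*age + a2*age^2 + noise`, an EF z-score coupled to the
#' standardized latent factor, and for each subject the eight layers of the
#' multiplex: six MEG-band epoched oscillator series (left as time series),
#' one BOLD-like series, and one structural weight matrix. Identical
#' parameters (including the seed) give bit-identical cohorts.
#'
#' @param params A [cohort_params()] object.
#' @return An object of class `synthetic_cohort`: `subjects` (list of
#'   subject lists with `subject_id`, `age`, `latent_g`, `latent_g_std`,
#'   `cognition`, `layers`), `covariates` (data frame), `atlas`, `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_subjects
  atlas <- params$atlas
  a <- params$age_quad_coeffs
  set.seed(params$seed)
  age <- runif(n, params$age_range[1L], params$age_range[2L])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  education <- sample(1:7, n, replace = TRUE, prob = c(1, 1, 2, 3, 4, 4, 3))
  latent <- a[1L] + a[2L] * age + a[3L] * age^2 + rnorm(n, sd = params$noise_sd)
  g_sd <- if (n > 1L) sd(latent) else 0
  g_std <- if (is.finite(g_sd) && g_sd > 0) {
    (latent - mean(latent)) / g_sd
  } else {
    rep(0, n)
  }
  ef <- params$effect_slope * g_std + rnorm(n, sd = params$noise_sd)
  layer_seeds <- matrix(sample.int(.Machine$integer.max %/% 2L, n * 8L),
                        nrow = n, ncol = 8L)

  bands <- canonical_bands()$name
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    subj <- list(
      subject_id = sprintf("sub%03d", s),
      age = age[s], sex = sex[s], education = education[s],
      latent_g = latent[s], latent_g_std = g_std[s],
      cognition = list(EF = ef[s]),
      atlas = atlas,
      sampling_rate = params$sampling_rate,
      n_epochs = params$n_epochs, epoch_len = params$epoch_len,
      n_volumes = params$n_volumes, tr = params$tr
    )
    layers <- vector("list", 8L)
    names(layers) <- layer_names()
    for (b in seq_along(bands)) {
      layers[[bands[b]]] <- generate_band_series(
        subj, bands[b], params$coupling, seed = layer_seeds[s, b])
    }
    layers[["rsfmri"]] <- generate_bold_series(subj, params$coupling,
                                               seed = layer_seeds[s, 7L])
    layers[["dmri"]] <- generate_structural_matrix(subj, params,
                                                   seed = layer_seeds[s, 8L])
    subj$layers <- layers
    subjects[[s]] <- subj
  }
  covariates <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    age = age, sex = sex, education = education,
    latent_g = latent, latent_g_std = g_std, EF = ef,
    stringsAsFactors = FALSE
  )
  structure(
    list(subjects = subjects, covariates = covariates, atlas = atlas,
         params = params),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$subjects), " subjects x ",
      x$params$n_regions, " regions, layers: ",
      paste(layer_names(), collapse = ", "), "\n", sep = "")
  invisible(x)
}
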