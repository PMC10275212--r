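---
title: "Multimodal multilayer brain networks: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal multilayer brain networks: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multibrain)
```

## The scientific problem

Executive functioning is thought to depend on integration across brain
subnetworks, with the fronto-parietal network (FPN) acting as a connector
module. Different imaging modalities see different facets of that network:
diffusion MRI yields structural (streamline-count) connectivity, resting-state
fMRI yields slow haemodynamic coupling, and MEG yields band-specific
electrophysiological coupling. `multibrain` implements a multiplex
("network of networks") analysis that integrates all of these into a single
multilayer network per subject and quantifies FPN integration by multilayer
eigenvector centrality, together with the statistical machinery to relate
that centrality to cognition and age, and an edge-significance procedure that
justifies the sparse backbone on which the multiplex is built.

## From signals to layers

**MEG-band layers.** Epoched regional time series are band-pass filtered by
brickwall Fourier masking into the six canonical bands (delta 0.5–4, theta
4–8, lower alpha 8–10, upper alpha 10–13, beta 13–30, gamma 30–48 Hz). The
half-open convention `[f_lo, f_hi)` makes adjacent bands partition the
spectrum. Coupling is measured by the phase lag index (PLI),
`|mean(sign(sin(phase difference)))|`, computed from analytic-signal phases;
the phase is extracted with the Hilbert transform, the standard companion of
the PLI definition. PLI is insensitive to zero-lag coupling (hence to simple
amplitude crosstalk) and to channel rescaling. PLI is computed per epoch and
averaged across epochs — standard MEG practice that limits nonstationarity
bias; a concatenated-epoch variant is available via
`pli_matrix(epoch_average = FALSE)`. Samples with a phase difference of
exactly 0 or π contribute sign 0, a literal reading of the sign function.

**BOLD-like layer.** Pearson correlations between regional time series on
the full (non-epoched) acquisition, absolutized: negative correlations may
carry real coupling information and most network metrics require nonnegative
weights.

**Structural layer.** Streamline-count matrices are consumed as input and
validated (symmetry to 1e−9, nonnegativity, zero diagonal).

Region exclusion (e.g. for signal dropout) is applied globally — the same
index list across every subject and every layer — before any network
construction, so all layers keep an identical region ordering.

## Backbones and the multiplex

Each weighted layer is reduced to its minimum spanning tree under edge cost
`1/w` (Kruskal's algorithm), i.e. the maximum-total-weight spanning tree:
the strongest-connection backbone, with exactly `N − 1` links per layer.
This removes density and mean-connectivity differences between layers and
subjects, which would otherwise bias multilayer metrics. Zero-weight pairs
are non-edges, never infinite-cost edges; a disconnected positive-weight
graph is a hard error rather than a silent spanning forest, because the
multiplex construction presumes a tree per layer. Ties in cost are broken
deterministically by `(cost, i, j)`; with continuous weights ties have
measure zero, so this only pins down reproducibility.

The eight binary backbones are stacked into an `(L·N) × (L·N)`
supra-adjacency matrix: diagonal blocks are the layers, off-diagonal blocks
couple each node only to its own copies in other layers with weight ω = 1,
identical to the intralayer weights. Two genuinely open design points are
resolved as follows:

* **Coupling topology.** Layers (modalities and frequency bands) have no
  natural ordering, so the default couples every pair of layers
  (categorical multiplex), which is also the default of the established
  multiplex tooling. An ordinal chain is available
  (`build_supra_adjacency(topology = "chain")`).
* **Degree centrality and interlayer links.** In a multiplex every node
  copy has the same interlayer degree, so interlayer links add a constant
  and carry no between-node information; `multilayer_degree()` therefore
  excludes them by default and offers them as a documented constant shift.

## Centrality

Single-layer eigenvector centrality (EC) is the leading eigenvector of the
(weighted or binary) adjacency; weighted matrices are used as-is — inversion
applies only to the MST cost. Multilayer EC is the leading eigenvector of
the supra-adjacency, normalized to unit Euclidean norm, oriented
nonnegative, and aggregated to one score per node by averaging the node's
`L` entries. Subnetwork summaries (`subnetwork_mean()`) average scores over
the seven-network parcellation labels (VN, SMN, DAN, VAN, LMN, FPN, DMN).

Numerically, the leading eigenpair is found by shifted power iteration with
a deterministic positive uniform start: shifting by the maximum row sum
makes the spectrum nonnegative, so the Perron eigenvalue strictly dominates
(tree layers are bipartite, and the unshifted supra spectrum can be nearly
symmetric). Iteration stops when a geometric-tail bound on the remaining
error — successive-difference times `ρ/(1−ρ)` with ρ the observed
contraction ratio — falls below 1e−10. Eigenvectors are sign-ambiguous; the
Perron vector of the shifted matrix is already nonnegative and entries below
1e−12 are clamped to 0. On connected supra-graphs (guaranteed with spanning
tree layers and ω > 0) the aggregated scores are strictly positive by
Perron–Frobenius; disconnected inputs are an error since the leading
eigenvector is then neither positive nor unique. The implementation agrees
with a dense eigendecomposition to 1e−9 on all test instances, and for `L`
identical layers it reproduces the analytic structure: leading eigenvector
`uniform ⊗ u` with eigenvalue `λ_max(A) + ω(L − 1)`.

## Edge significance

To check that backbone links are statistically real rather than noise, each
weighted layer is compared with an ensemble of 100 null matrices obtained by
shuffling the existing edge weights among the existing edge positions: the
binary topology (hence the degree sequence) and the weight multiset are
preserved exactly. Node strengths are preserved approximately by a
randomized sequential rank-matching pass: edges are visited in random order,
and each receives the still-unassigned weight whose descending rank equals
the rank of the edge's residual strength product, the assigned weight being
subtracted from both endpoints' residual strengths. A deterministic
whole-matrix rank pass would collapse all replicates onto nearly the same
assignment and destroy the null variability the test needs, which is why the
pass is randomized and sequential, mirroring the behaviour of the classical
connectivity-toolbox implementation of this null model. Replicate seeds fan
out as `seed + replicate index`.

A one-sample Kolmogorov–Smirnov test of a single observed value against 100
null values is ill-posed, so the default per-edge test is a two-sided
empirical rank test around the null median with add-one correction,
`p = (1 + #{nulls at least as extreme}) / (n + 1)`, flagged at α = 0.05;
a literal KS variant (`method = "ks"`, the observed weight as a degenerate
distribution) is selectable for comparison. Two-sidedness around the null
median treats unusually strong and unusually weak edges symmetrically. With
an observed matrix that is itself a draw from the null family the flagged
fraction calibrates at `⌊α(n+1)⌋/(n+1) ≈ 4.95%`, below the 5% mark; on
heavy-tailed modular matrices the MST concentrates extreme weights, and its
significant fraction is far higher — the package's acceptance script
recomputes both numbers.

## The statistical layer

Cognition composites are plain means of component z-scores (missing
components yield a missing composite, never an imputation). Collinearity
diagnostics report tolerance `1 − R²` and VIF `1/(1 − R²)` per predictor,
flagging tolerance < 0.2. The main analysis is a blockwise stepwise OLS
regression: the eight single-layer subnetwork centralities enter as a
selectable first block (backward removal at F-probability 0.10, or forward
entry at 0.05), with the multilayer centrality as a forced second block.
Whether the original two-block procedure re-ran elimination with the forced
block present or froze the first-block outcome is not recoverable; the
default enters the forced block before selection (so elimination proceeds
with the multilayer term present, consistent with a reported two-predictor
penultimate model), and `block2_entry = "after"` provides the other
ordering. Partial-F p-values come from drop-one sums of squares, equivalent
to squared t-tests in OLS; standardized betas follow the z-scored-variables
convention, so a single-predictor standardized beta equals the Pearson
correlation. The hierarchical age model fits `y ~ age` then
`y ~ age + age²` and reports the R²-change F-test. Leave-one-out
cross-validated R² uses the uncentered percent-scale formula
`100·(1 − Σ(yᵢ−ŷᵢ)²/Σyᵢ²)`, implemented literally; note the uncentered
denominator makes it incomparable to an ordinary centered R².

## What the synthetic cohort emulates

Real multimodal cohorts of this kind are small and not redistributable, so
the package ships a generator that reproduces the statistical structure the
analysis assumes, making every downstream stage testable end-to-end:

* Ages uniform on 20–70 (the emulated cohort was deliberately spread in
  age); a latent "FPN integration" factor with an inverted-U age trend,
  `g = a0 + a1·age + a2·age² + N(0, σ)`, defaulting to a peak at age 45,
  a range of about 1 across the age span (`a0 = −3.24, a1 = 0.144,
  a2 = −0.0016`), and σ = 0.4.
* An executive-functioning z-score coupled to the standardized latent
  factor with slope 0.8 (σ = 0.4 noise). No reliable empirical effect size
  exists for the centrality–cognition link beyond small-sample estimates, so
  these are calibration choices: strong enough that a 40-subject cohort
  recovers the planted slope reliably, weak enough that the recovery is not
  trivial. Cognition scores are generated directly as z-scores; norming of
  raw test scores is out of scope.
* Six band-specific layers of phase-coupled oscillators. Each region's
  phase is the argument of a mixture of its own noisy phase walk (Wiener
  phase noise at 4 rad²/s plus 0.4 rad per-sample jitter) and a shared
  reference with mixture weight 0.85; fixed nonzero per-region phase lags
  keep PLI away from zero under coupling. Because two drifting oscillators
  only hold a consistent phase lag while both track the same reference,
  integration is modelled as an epoch-level regime: per epoch, a module's
  reference is either its own rhythm or a global integration rhythm — with
  probability 0.35 for non-FPN modules and `0.15 + 0.6·plogis(1.5·g)` for
  the FPN. The FPN-to-other PLI therefore grows monotonically with the
  latent factor, and the effect propagates through PLI estimation, MST
  construction and centrality realistically rather than by direct edge
  injection.
* A BOLD-like layer from a module factor model whose FPN loading on a
  global factor likewise grows with the latent factor, and a heavy-tailed
  structural layer with log-normal weights (sdlog 1) boosted within modules
  (meanlog +1.1), symmetric, hollow and connected.

What the generator does **not** emulate: source leakage and field spread,
forward models, realistic tractography biases, scanner drift or motion, and
spatially varying interlayer correspondence. Passing tests on this cohort
therefore demonstrate that the pipeline recovers planted effects of the
assumed form through the full estimation chain — not that such effects are
detectable in any particular real dataset.

A note on the PLI floor: independent band-limited signals carry roughly
`2·bandwidth·T` independent sign samples per epoch, so epoch-averaged PLI
has a nonzero floor of about `sqrt(2/(π·2·bw·T))` that averaging across
epochs does not reduce (the absolute value is taken per epoch). For wide
bands (beta, gamma) the floor sits below 0.1; for narrow slow bands (delta)
it is about 0.17 at 3.28 s epochs. Tests of the uncoupled generator
therefore check the sub-0.1 bound in the beta band, where the
independent-phases oracle supports it.

## Problem sizes used by the test-suite and acceptance script

Structural and analytic checks run at the full 197-region scale (196-edge
backbones; 1568 intralayer plus 5516 interlayer links at `L = 8`). The
replicate suites that re-run the whole pipeline use cohorts of 40 subjects
at 35 regions, 6 epochs of 256 samples at 128 Hz, and 120 BOLD volumes —
sizes chosen so that a few dozen replicate cohorts run comfortably on a
single CPU while keeping every band below Nyquist and at least several
Fourier bins wide. The edge-inference quantities are recomputed at 60
regions, 5 subjects and 100 nulls, with 306-volume BOLD-like series
matching the emulated acquisition. Cohort size (n = 40) and all effect
sizes stay at their defaults in every replicate suite.

## Known limitations

* Interlayer weights are fixed at ω = 1 (as in the emulated analysis);
  no ω optimization or weighted interlayer links.
* Strength preservation in the null model is approximate by construction;
  exact joint preservation of degree, weight multiset and strengths is
  generally infeasible.
* Stepwise selection inherits the usual instability of stepwise methods in
  small samples; the package reports the full model sequence, ΔR² and
  F-change so that no single final model needs to be over-interpreted.
* The multiplex is binary; layer-dominance information is deliberately
  discarded with the weights.
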