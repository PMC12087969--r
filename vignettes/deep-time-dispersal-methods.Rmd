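---
title: "Methods: deep-time niche dynamics and dispersal in deepniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-time niche dynamics and dispersal in deepniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`deepniche` chains the quantitative stages used to study how a clade with
a deep fossil record — beaded lacewings are the motivating case — moved
and adapted across ~170 My: where its niche lay and how wide it was, how
strongly niche and morphology track the phylogeny, whether global climate
drove diversification, how ranges moved between biogeographic realms, and
whether wing elongation paid off in dispersal. This vignette explains the
models behind each stage, the parameters that matter, the synthetic data
the package generates to test itself, and the numerical and design
choices that were genuinely open.

## The synthetic scenario and what it does (and does not) emulate

All stages are exercised end to end on generated data with known ground
truth. `sim_config()` fixes the study conditions:

* **Tree.** A forward birth–death simulation from the root age
  (default 175 Ma; speciation 0.035/My, extinction 0.015/My, aiming at
  ~25 extant genera) with constant-rate Poisson fossil sampling along
  every branch of the complete tree — the simplest scheme consistent
  with a fossilized birth–death process. Every Poisson sample becomes a
  dated fossil tip; a sample on a lineage with surviving descendants is
  attached on a 1e-8 My stem so branch lengths stay strictly positive
  while the sample age is kept exactly. The total branch length of the
  complete tree is stored so the Poisson sample count can be checked
  against its analytic expectation.
* **Traits.** Brownian motion along branches, with internal-node values
  retained as ground truth for ancestral-state recovery. Wing length
  adds a directional trend of 0.05 mm/My (root ~3 mm, so roughly 3 →
  12 mm over the full span — inside the observed 1.7–15 mm forewing
  range). The trend is deliberately strong relative to the Brownian
  standard deviation over the tree depth (~3 mm): the generator's task
  is to *plant* a positive wing-length/dispersal coupling, and with a
  weaker trend the clade-mean wing-length series can decline whenever a
  short-winged subclade radiates late, which erases the planted signal
  regardless of the branch-level coupling. Wing shape (oval/falcate)
  follows a symmetric two-state Mk process.
* **Climate.** 36 × 18 (10°) grids, one per 10-My slice. Temperature is
  a latitudinal gradient plus a secular cooling trend
  (`cooling_slope`, default 0.05 °C/My, so the global mean cools by
  8.75 °C over 175 My); precipitation and elevation are smoothed-noise
  fields (spatially autocorrelated by a moving-average kernel — the
  spatial covariance of real palaeoclimate fields is unknown to us, and
  this choice is flagged as free). Eleven variables (MAT, TS, MAP, WMP,
  DMP, PS, EQ, CI, WMT, CMT, EL) are derived with enough mutual
  correlation that variable screening has something to do.
* **Occurrences.** Presences are sampled per slice with probability
  proportional to a planted suitability surface. The default is a
  *restrictive, monotone* cool-preference curve, `plogis((6 − MAT)/2)`
  (~16% of grid cells clearly suitable). Two considerations fix this
  shape: the modelled family is cool-adapted with an
  anti-latitudinal-gradient distribution, and the niche model uses
  linear features only, so a mid-range optimum would be both unlearnable
  and — we verified by computing the ideal-ranker AUC on these grids —
  statistically incapable of supporting the AUC > 0.8 power property the
  generator/model pair is required to have. Each record copies its grid
  cell's environment vector exactly.
* **Realms and ranges.** Up to eight realms (PA, OR, IN, SA, AT, AU,
  NA, NT) with a three-epoch synthetic adjacency history (two connected
  blocks, then fragmentation, then modern reconnection) using the three
  multiplier classes 0.75 (adjacent), 0.5 (one barrier), 1e-6 (two or
  more barriers). Range histories are simulated forward with
  cladogenesis, and the per-branch dispersal rate is multiplied by
  `exp(coupling_beta · (WL − mean WL))` (default 0.4 per mm): the
  planted coupling the dispersal stage must recover.
* **Not emulated:** real plate rotations, real WorldClim layers,
  coastlines, and any spatial structure of palaeoclimate uncertainty.
  Passing tests therefore demonstrate statistical correctness of the
  machinery, not fidelity of any particular palaeogeographic
  reconstruction.

## Niche modelling

The niche model is the maximum-entropy (Gibbs) distribution over
background cells with **linear features only**: weights `w` minimize
`log Z(w) − w·p̄ + Σ β_f |w_f|`, where `p̄` is the presence feature mean.
Features are the selected variables scaled to [0, 1] by background
min/max and **clamped** to that range (standard MaxEnt behaviour;
without clamping, fossil presences projected on a modern background can
make the feature-matching target unattainable). The convex objective is
solved by L-BFGS-B on the split `w = a − b`, `a, b ≥ 0`, with analytic
gradients; at the optimum the KKT conditions
`|E_model[f] − p̄_f| ≤ β_f` hold and are asserted in tests.

Parameters: `reg_multiplier` (default 1.5, the study setting);
`β_f = reg_multiplier · sd_f(presences)/√n`, floored at
`0.02 · reg_multiplier` so near-degenerate presence means at a feature
extreme cannot force unbounded weights; weights live in a ±60 box that
only binds under complete separation (on the unit feature scale a weight
of 60 is an e^60 density ratio). Evaluation uses a 20% random presence
split, ten replicates, and the rank-based (Mann–Whitney) AUC against the
background. The default output transform is the complementary log-log of
the cell density scaled by the fitted distribution's entropy; raw
density is a config switch. Class bounds follow the strict reading of
the three-class map: P = 0.5 → less suitable, P = 0.3 → unsuitable.
Variable screening groups variables with pairwise |r| ≥ 0.8 (the cutoff
is configurable and logged; the source analysis states grouping but not
the threshold) and keeps the variable with the largest variance-weighted
PCA contribution per group.

Spatial thinning is greedy in input order (first kept wins) with
great-circle distances; the 6-km default mirrors the study's buffer.

## Niche position and breadth (OMI)

Sites are weighted by total abundance; the environment table is centred
and standardized under those weights. For species *s* with site profile
`p_s`, the niche position is `NP_s = ‖Σ_i p_si z_i‖²` (squared
marginality — the OMI convention) and the niche breadth
`NB_s = Σ_i p_si ‖z_i − c_s‖²` (total weighted variance; the split into
variance along the first canonical axis and the residual is also
returned). `NP + NB` equals the species' total inertia, asserted to
1e-8. Presence-only records are converted to abundances by counting
records per grid cell. Two bin schemes are provided: five
geochronological intervals (default edges root/145/100/66/23/0 — the
study's exact interval table is supplementary and unavailable, so these
period boundaries are a documented default) and the 10-My scheme whose
10-My edges are anchored at …115, 105 and 65, 55, …, 5, 0 around two
20-My bins spanning 105–65 Ma (the sparse-record window); for a 170-Ma
root this yields exactly 16 bins. Bins are half-open `[older, younger)`
and a record at an edge belongs to the bin whose older edge it sits on.

## Comparative methods on trees with fossil tips

Everything is built on the Brownian shared-path covariance `C` (and so
never assumes ultrametricity — fossil tips simply have shorter root
paths). The root mean and rate σ² are always profiled analytically.

* **Pagel's λ** rescales off-diagonal covariances; the search runs on
  `[0, λ_max]` where `λ_max` is found by bisecting the
  positive-definiteness boundary. On non-ultrametric trees `λ_max > 1`,
  which matters because empirical estimates slightly above 1 do occur.
  The profile can be multimodal on small trees, so a 41-point scan
  precedes local refinement. Significance is a likelihood-ratio test
  against λ = 0.
* **Blomberg's K** uses the standard MSE0/MSE ratio around the GLS root
  estimate, normalized by its Brownian expectation
  `(tr C − n/Σ C⁻¹)/(n − 1)`; the permutation test shuffles tips
  (default 10,000 permutations, so the smallest reportable p is 1e-4).
* **Ancestral states** are GLS conditional expectations; prediction
  variances include the root-uncertainty correction term
  `h² / 1'C⁻¹1`, which is what makes the 95% intervals calibrated
  (checked by simulation: coverage within [0.92, 0.98] on 128-tip
  trees). Discrete states use a single-rate symmetric Mk model with
  closed-form transition probabilities and marginal posteriors from an
  inside–outside pass (equivalent to rerooting).
* **The nine-model suite** (WN, BM, RT, MT, DT, LB, KP, EB, OU) is fit
  by transforming `C` (or branch lengths, for kappa) and profiling; the
  rate-trend model takes σ²(t) = σ²(1 + b·t/T) and the mean-trend model
  adds a drift regressor on tip depth — identifiable only because
  fossil tips break ultrametricity. AICc uses the standard small-sample
  correction. A model whose optimizer fails is reported as a failed row
  rather than aborting the table.
* **Rate through time** is a deliberately simple proxy for full
  rate-shift inference (which is out of scope): squared standardized
  contrasts, each anchored at its node's age (a contrast is a node
  quantity, so the node age — not a branch midpoint — is the natural
  anchor), averaged per bin with a bootstrap CI. Under constant-rate BM
  the curve is flat at σ²; an early burst declines. The output is
  labelled as a proxy.
* **Branch–bin summaries** interpolate each branch linearly between its
  endpoint values; per-bin means are length-weighted, and per-bin
  thresholds (the "ecological threshold" min/max) are exact because a
  linear segment attains its extremes at interval endpoints.

## Causal inference (CCM)

Cross-mapping direction "x causes y" embeds the *effect* y with lag
vectors (E, τ) and predicts x by simplex projection (E + 1 nearest
neighbours, exponential weights). Skill is the Pearson correlation of
predictions with observations; the curve over library sizes, a
phase-preserving surrogate null (default 100 surrogates), and three
convergence conditions — monotone rise (Spearman ≥ 0.8 over the curve),
final skill above the surrogate null quantile (default 99th percentile)
and above a minimum meaningful skill of 0.2 — define the `convergent`
flag. The last two conditions deserve a note: for independent noise the
skill curve rises toward its realization-specific final correlation *by
construction*, so curve shape plus a rank-based surrogate cutoff alone
misfires on a few percent of noise pairs; the 0.2 floor (under 4%
explained variance) is the conventional noise-level benchmark. E and τ
default to 2 and 1; `select_embedding()` offers the first-1/e
autocorrelation lag and a simplex self-prediction sweep, and the values
used are always logged in the result.

## Historical biogeography

States are nonempty realm subsets up to `max_range_size` (default 2,
keeping the 8-realm space at 36 states; configurable to the full 255).
The anagenetic generator gains realm *b* from range *R* at rate
`d · Σ_{a∈R} m(a, b)` with the epoch's multiplier matrix `m`, and loses
resident realms at rate `e` (single-realm ranges cannot vanish — the
null range is excluded). Likelihoods are computed by pruning with
per-epoch matrix exponentials spliced along branches that cross epoch
boundaries; cladogenesis applies the scheme's weight table (DEC: narrow
and subset sympatry plus narrow vicariance; DIVALIKE: narrow sympatry
and vicariance only; BAYAREALIKE: identical inheritance; +j adds
founder events with weight j against unit weights for the allowed
events), and the root prior is uniform. Stochastic maps draw the root
state from the conditional likelihoods, cladogenetic outcomes from the
weighted table, branch endpoints from the spliced transition matrices,
and branch paths by rejection sampling with a uniformization fallback
after 1,000 rejections (exactness with a bounded-runtime guarantee).
Dispersal events are anagenetic gains plus founder events; the source
realm of a gain is drawn proportionally to the epoch multipliers from
the occupied realms, and events are binned per My. The unconditional
forward simulator uses the same uniform root prior so that pattern
frequencies converge to pruning likelihoods — the package's
simulation–likelihood agreement check.

## Dispersal frequency and wing length

The per-My dispersal-event series is binarized at its mean (strictly
above = "frequent"). The hidden Markov model has two hidden regimes;
each emits the observed 0/1 category (Bernoulli) *jointly* with a
Gaussian wing length. The joint emission is our reading of "integrating
the categorized dispersal data and the wing-length data": with Gaussian
emissions alone, Baum–Welch drifts to an unsupervised wing-length
mixture and the hidden states lose their regime meaning (the alternative
reading — regimes as fully observed states with WL as a covariate — is
noted but not implemented). EM is initialized from the observed regimes,
its log-likelihood is asserted non-decreasing at every iteration, and
zero-variance clusters are floored with a warning. The logistic stage
simulates 10,000 sequences from the fitted model, pools them, fits
`regime ~ WL` by IRLS (`glm`), reports the threshold `−β₀/β₁` in mm,
and flags perfect separation (falling back to the separating-gap
midpoint). Kernel densities use Silverman's rule. Group contrasts
report Welch's t and the rank-sum test with an exact enumerated null
when both groups have ≤ 10 observations (average ranks under ties).

## Atmosphere

Humid-air density is the Dalton decomposition
`ρ = (P − Pv)/(R_d·T) + Pv/(R_v·T)` with R_d = 287.1 and
R_v = 461.5 J/(kg·K); viscosity is Sutherland's law with S = 110.4 K and
the standard air reference μ_ref = 1.716e-5 Pa·s at 273.15 K (the
reference point is a package default; only the Sutherland constant is
fixed by the source analysis). Vapour pressure is taken as an input
directly — whether it derives from relative humidity or dew point in any
particular climate source is upstream of this package. The CFD
field-condition builder enumerates the six transient sets ({v, ρ, μ} ×
{max, min}, others at their means), the steady set (mean v, mean μ,
minimum ρ — a relatively adverse circumstance), and per-wing-shape
median habitat temperatures. The aerodynamic simulations themselves are
out of scope.

## Habitability

Per-bin thresholds projected on a slice give a habitable mask (single
variable — habitat MAT — by default, intersection of several variables
as an option; both modes exist because the figure being emulated is
explained by the MAT pattern but the underlying thresholds are
multivariate). Accessibility is graph reachability over the epoch's
dispersal-multiplier graph from the occupied realms, with edges at or
below the 1e-6 barrier class severed — the figure's
"habitable-but-inaccessible" has no published algorithm, so this
concretization is recorded in the output metadata.

## Orchestration and reproducibility

`run_pipeline()` runs the stages in dependency order from one config in
which every study-level constant (1.5 regularization, 20% test split,
10 replicates, 200 stochastic maps, 10,000 HMM sequences, 10-My bins)
is a default, never a hard-coded value. Each stage's manifest entry
records status, timing and an md5 checksum of its results; a rerun of
the same config is checksum-identical. A stage whose dependency is
toggled off halts the run with both names in the error.

## Problem sizes used by the test suite

The suite checks exact oracles on tiny instances (≤ 6 tips, ≤ 9 cells,
length-4 HMM sequences) and statistical properties at sizes chosen to
keep the full run around six minutes on one CPU: 200 Brownian
simulations on 128-tip trees for λ/K calibration and ASR coverage; 50
replicates of 64-tip range simulations for dispersal-rate recovery
(median relative error under 30%); 2,000 unconditional simulations for
the 3-tip simulation–likelihood agreement; 20 seeded replicates each for
the coupled-logistic-map CCM benchmark and the white-noise control; and
50 end-to-end pipeline replicates (15 extant + ~10 fossil tips, 120-Ma
root, four realms, 8 stochastic maps) for planted-signal recovery. The
acceptance script uses a larger single scenario (25 extant + ~15 fossil
tips, 175-Ma root, six realms, 50 maps, 2,000 HMM sequences).

## Known limitations

* The rate-through-time proxy is not a rate-shift model; it answers
  "is the average rate higher early than late", nothing finer.
* DEC-family fits use `max_range_size = 2` by default; widespread
  ranges beyond two realms are truncated unless the limit is raised.
* The HMM has exactly two regimes by design.
* The synthetic climate fields are statistically, not physically,
  realistic; conclusions about real palaeoclimate data require real
  layers.
* CCM on the short (~18-point) per-slice series the pipeline produces
  has little power; the pipeline logs the result but the benchmark
  properties are established on longer series.
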