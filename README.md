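# deepniche

Deep-time niche dynamics, historical biogeography and dispersal analysis
for clades with both fossil and extant members.

`deepniche` re-implements, as a single tested R pipeline, the analysis
chain used to ask how an insect family that spans ~170 My of geological
history — the model here is the beaded lacewings (Berothidae), with fossil
genera from the Middle Jurassic onward and extant genera on every
zoogeographic realm — tracked a changing Earth. It is written for
comparative biologists and palaeobiogeographers who want every stage of
such an analysis (niche models, niche position/breadth, phylogenetic
signal, causal inference, biogeography, dispersal-vs-morphology) runnable,
testable and reproducible on synthetic data with known ground truth.

## What it computes

* **Scenario generation** — fossilized birth–death trees with Poisson
  fossil sampling, Brownian niche traits and trended wing lengths (node
  values kept as ground truth), Mk wing shapes, latitudinally structured
  climate grids with a secular cooling trend, presence records sampled
  from a planted suitability surface, an epoch-stratified realm adjacency
  history, and a planted wing-length → dispersal-rate coupling.
* **Ecological niche modelling** — Pearson/PCA variable screening, 6-km
  great-circle thinning, linear-feature maximum-entropy fitting (the
  regularized Gibbs distribution over background cells, solved as a convex
  problem with analytic gradients), replicate-averaged AUC with a 20%
  random test split, projection across eras and the three-class
  suitability map (P > 0.5 suitable, 0.3 < P ≤ 0.5 less suitable,
  otherwise unsuitable).
* **Niche position and breadth** — an Outlying Mean Index analysis:
  marginality (NP) as the squared distance of a species'
  abundance-weighted centroid from the mean environment in standardized
  space, tolerance (NB) as the weighted variance, canonical variable
  weights from the marginality cross-product; two time-binning schemes
  (five geochronological intervals, and 10-My bins with two 20-My bins
  across the sparse 105–65 Ma window).
* **Phylogenetic comparative methods** on dated, non-ultrametric trees:
  GLS ancestral states under Brownian motion with calibrated prediction
  intervals, marginal Mk ancestral states, Pagel's λ with a
  data-dependent upper bound (λ > 1 is reachable on trees with fossil
  tips), Blomberg's K with a 10,000-permutation test, a nine-model
  evolutionary suite (WN, BM, rate trend, mean trend, delta, lambda,
  kappa, early burst, OU) compared by AICc, PGLS, length-weighted branch
  means and min/max niche thresholds per time bin, LTT curves, and a
  contrast-based rate-through-time proxy.
* **Causal inference** — convergent cross-mapping (simplex projection on
  time-delay embeddings, library-size convergence, phase-surrogate null)
  plus plain Pearson/Spearman tests.
* **Historical biogeography** — time-stratified
  dispersal–extinction–cladogenesis likelihoods (DEC, DIVALIKE,
  BAYAREALIKE, each ± founder-event j) over realm subsets, with epoch
  multiplier matrices using the 0.75 / 0.5 / 1e-6 barrier classes, ML
  fitting with AICc, and biogeographic stochastic mapping that counts
  dispersal events per My and per realm pair.
* **Dispersal vs wing length** — mean-split binarization, a two-regime
  hidden Markov model whose states emit the dispersal category jointly
  with a Gaussian wing length (Baum–Welch), logistic regression over
  10,000 HMM-simulated sequences with the P = 0.5 wing-length threshold,
  kernel densities, and Welch/exact rank-sum wing-shape contrasts.
* **Atmosphere** — humid-air density by Dalton's partial-pressure
  decomposition, Sutherland viscosity, and the six transient + one steady
  CFD field-condition sets derived from habitat records.
* **Habitability** — per-bin niche thresholds projected onto climate
  slices and partitioned into habitable / habitable-but-inaccessible /
  uninhabitable cells by realm reachability through the epoch's dispersal
  graph.

## Worked example

```r
library(deepniche)

cfg <- pipeline_config(
  seed = 1,
  sim  = sim_config(seed = 1, n_extant = 25, n_fossil = 15,
                    root_age = 175, n_realms = 6),
  n_bsm = 50, hmm_n_iter = 2000)
res <- run_pipeline(cfg)

res$results$enm$evaluation$auc_train
#> [1] 0.9171157
res$results$comparative$signal$niche$lambda$lambda
#> [1] 1.001914
res$results$comparative$signal$niche$K$K
#> [1] 1.360725
res$results$dispersal$spearman$r
#> [1] 0.8421541
res$results$dispersal$threshold$wl_threshold
#> [1] 7.438708
air_density(101325, 0, 288.15)   # dry air at standard conditions, kg/m^3
#> [1] 1.224799
```

Reading the output: the niche model separates the planted cool-adapted
niche from the background with a training AUC of 0.92; the simulated niche
trait carries strong phylogenetic signal (λ ≈ 1.0, K ≈ 1.4, as expected
for a Brownian trait on this tree); the per-My dispersal-event series
recovered by stochastic mapping correlates positively with mean wing
length (Spearman ρ = 0.84) — the coupling the generator planted — and the
logistic threshold puts the shift to frequent dispersal at a forewing
length of ≈ 7.4 mm for this scenario. Every stage's manifest entry
(`res$manifest`) records its seed, parameters and an md5 checksum, so a
rerun of the same config is verifiably identical.

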