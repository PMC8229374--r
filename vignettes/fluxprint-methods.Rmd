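---
title: "Methods: context-specific model extraction and flux-pattern heterogeneity"
author: "fluxprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-specific model extraction and flux-pattern heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

fluxprint benchmarks how expression-data integration algorithms shape the
metabolic phenotype of context-specific models (CGEMs).  The workflow is:
load a genome-scale metabolic model, reduce it to its flux-consistent
subnetwork, map per-sample expression onto reactions through
gene-protein-reaction (GPR) rules, extract a context-specific submodel per
sample with one of four algorithms (GIMME, iMAT, INIT, FASTCORE), compute
each submodel's flux state by parsimonious FBA, and quantify heterogeneity
across samples: Warburg-effect flux ratios, hallmark gene-set activation,
subsystem-averaged Jaccard overlap of kept reactions, Bland-Altman
agreement of flux states, PCA clusterability, and random-forest selection
of discriminative fluxes aggregated into subsystem barcodes.

Everything runs at desk scale on a synthetic, flux-consistent Warburg
network with simulated multi-platform expression data whose ground truth
is known, so that every downstream claim can be tested against an
independent oracle.

# The linear-programming core

All constraint-based computations reduce to linear programs over the
steady-state polytope \(\{v : S v = 0,\ lb \le v \le ub\}\).  The package
ships its own bounded-variable two-phase primal simplex (compiled code)
plus a depth-first branch-and-bound layer for the mixed-integer programs
that iMAT and INIT require.  Design points that matter for correctness:

* **Determinism.** Fixed pivot rules (largest reduced-cost violation with
  a permanent switch to Bland's rule after a run of degenerate pivots),
  fixed variable order, no randomized restarts.  Identical inputs give
  identical flux states, which the reproducibility contract of
  `run_benchmark()` relies on.
* **Row equilibration.** Indicator constraints mix activity thresholds
  (\(10^{-4}\)) with capacity bounds (\(10^2\)); every row is normalized by
  its largest coefficient before the solve, which keeps the basis
  well-conditioned.
* **Exact ratio test.** The blocking step is the exact minimum over all
  blocking ratios; the leaving variable is chosen among near-minimal
  blockers by pivot magnitude only.  This prevents bound overshoot, which
  would otherwise surface as spuriously "fractional" binaries in
  branch-and-bound.
* **Big-M integrality.** With indicator constraints of the form
  \(v \ge \varepsilon - M(1-y)\), a binary at \(1-5\times10^{-7}\) already
  nullifies its constraint; the branch-and-bound therefore uses a strict
  integrality tolerance (\(10^{-9}\)) and, before accepting an incumbent,
  re-solves the LP with all integers fixed so the continuous part is
  exactly consistent with the rounded assignment.
* **Tolerances.** Pricing tolerance \(10^{-9}\); solutions are asserted
  downstream to satisfy \(|Sv| \le 10^{-6}\) and bounds within
  \(10^{-6}\).  All tolerances live in one `solver_config()` object.

The solver is validated in the test suite against scipy's HiGHS
implementation (reached through the system `python`) on random LPs, and
the branch-and-bound against exhaustive enumeration of binary
assignments; the oracle never shares code with the implementation.

# Flux balance analysis and consistency

`fba()` maximizes the objective (biomass) flux and then fixes the
reported flux vector by a secondary minimization of total absolute flux
at the fixed optimum (the parsimonious tie-break).  FBA optima are
massively degenerate; downstream statistics consume flux vectors, so an
arbitrary optimal vertex would make every heterogeneity measure
solver-dependent.  Parsimonious selection is the field's standard
resolution.  Infeasibility and unboundedness are reported as statuses,
not errors, because the benchmark must survive per-sample failures.

`fastcc()` partitions reactions into those that can carry at least
\(\varepsilon\) flux in some steady-state distribution and their blocked
complement.  The implementation batches LP-7-style support maximization
over direction-safe sets (irreversible forward, reverse-only backward),
certifies any reaction a feasible optimum happens to drive above
\(\varepsilon\), and resolves stragglers (typically reversible exchanges)
with exact per-reaction flux variability.  The resulting partition
depends only on the model, never on solve order, and equals the
FVA-derived set \(\{r : \max |v_r| \ge \varepsilon\}\) by construction --
the property the acceptance suite checks on random networks.

The default activity threshold is \(\varepsilon = 10^{-4}\).  A
literature value of \(10^{-10}\) is accepted but clamped with a warning:
an LP cannot certify a flux below its own feasibility tolerance, so
thresholds under the solver floor are meaningless.

# Expression preprocessing and GPR mapping

Replicates are averaged with missing entries ignored, then each profile
is min-max scaled, \((x - \min)/(\max - \min)\), independently per
sample.  The scaling scope (per sample across genes, rather than per gene
across samples) is a package choice: every downstream threshold is a
quantile *within* a profile, so cross-sample comparability of raw scales
is never needed, while per-gene scaling would be undefined for the
platform-dependent gene sets the simulator produces.

GPR evaluation is recursive: AND nodes (enzyme complexes) take the
minimum of their children, OR nodes (isozymes) the maximum.  Genes
without data are dropped at each node; a node whose children are all
unmeasured is missing; a reaction with no GPR or no measured gene gets no
value.  Evaluating over the measured children only (rather than failing
the whole rule) matches common COBRA mapping behavior and keeps proteome
profiles, which miss many genes, usable.  Mapping is monotone: raising
any gene's expression never lowers any reaction's activity.

# Extraction algorithms

All four algorithms receive the flux-consistent model, a mapped activity
vector, and an `extraction_config()`.  The published algorithm
descriptions fix none of the thresholds; the defaults here are package
choices, recorded in every result:

| parameter | default | role |
|---|---|---|
| `expression_threshold` | 0.25 quantile | GIMME penalty threshold, INIT weight zero point |
| `high_quantile` / `low_quantile` | 0.75 / 0.25 | iMAT classification; FASTCORE core membership (high) |
| `epsilon_active` | \(10^{-4}\) | flux level that counts as "active" |
| `biomass_fraction` | 0.9 | GIMME: retained fraction of the biomass optimum |

* **GIMME** solves FBA for the biomass optimum \(z^\*\), then minimizes
  \(\sum_r w_r |v_r|\) with \(w_r = \max(0, \theta - a_r)\) subject to
  biomass \(\ge 0.9 z^\*\).  Kept: protected, above-threshold, and
  flux-carrying reactions.
* **iMAT** classifies mapped reactions into highly and poorly expressed
  sets by activity quantiles and maximizes agreement by MILP: a high
  reaction agrees when \(|v| \ge \varepsilon\) (either direction via two
  indicators for reversible reactions), a low reaction when its flux is
  pinned near zero.  The low-side indicator window is \(\varepsilon/2\):
  the low reward is strict (\(|v| < \varepsilon\)), so a flux of exactly
  \(\varepsilon\) must not satisfy a high and a low classification at
  once, and the window must clear the solver's feasibility noise.
  Unclassified reactions are retained.
* **INIT** maximizes \(\sum_r w_r y_r\) with \(w_r = a_r - \theta\)
  (negative for unexpressed, zero for unmapped) where \(y_r = 1\) forces
  \(|v_r| \ge \varepsilon\).  Indicators carry a \(10^{-9}\) negative
  bias so unused ones stay off deterministically; with no informative
  weights the result is exactly the protected set's closure.  A
  steady-state relaxation (bounded net accumulation \(0 \le b_m \le
  b_{\max}\) for listed metabolites) is available and off by default.
* **FASTCORE** grows a small flux-consistent superset of a
  high-confidence core by alternating support maximization over
  unsatisfied core reactions with L1-sparse mode finding that penalizes
  non-core flux, followed by a greedy redundancy-pruning pass (any added
  non-core reaction whose removal leaves the submodel consistent is
  dropped).  The activity-driven core is the *upper* activity quantile
  (default 0.75), not the generic 0.25 expression threshold: the
  algorithm family's contract is a confidently-active core plus its
  minimum essential support, and a 0.25-quantile core (three quarters of
  all mapped reactions) would make FASTCORE return near-complete models,
  inverting the characteristic size ordering in which GIMME and INIT
  produce the largest submodels and iMAT/FASTCORE the leanest.

Every algorithm guarantees two invariants.  First, the protected set
(the six reserved reactions, plus always the model objective) is kept.
Second, the context model is flux-consistent at `epsilon_active`: the
candidate kept set is reduced by `fastcc()`, and if that reduction would
evict a protected reaction -- or the candidate submodel is outright
infeasible because a demand reaction lost its producers -- the sparse
support search re-grows the candidate's minimal support on the parent
model instead.  This closure is the only repair consistent with both
invariants; it can add a handful of support reactions beyond the
algorithm's nominal kept set.

# Scores

The Warburg indices are plain flux ratios at the parsimonious FBA
optimum of the extracted model: AFR = flux(GAPD)/flux(ATPS4mi)
(glycolytic over oxidative ATP route) and EOR =
flux(D_LACt2)/flux(O2t).  Transporters are oriented so that positive
flux is uptake; a fermenting, respiring model therefore shows AFR > 0
and EOR < 0 (lactate out, oxygen in).  Zero denominators yield `NaN`
flagged with an attribute, never a silent zero.  Reaction ids are
configurable so any model can alias the marker reactions.

Hallmark activation is the percentage of hallmark genes retained: the
denominator counts hallmark genes present in the parent model's gene
universe, the numerator those referenced by at least one kept reaction's
GPR.  The measure is monotone in the kept set.

# Pattern metrics

The subsystem-averaged Jaccard index computes
\(|A \cap B| / |A \cup B|\) per subsystem over the two kept-reaction
sets and averages over subsystems touched by at least one of the two
models.  Reactions without annotation live in the sentinel subsystem
"unassigned", so the average is always total.

Bland-Altman agreement pairs two flux vectors over the union of their
reactions, imputing zero for reactions absent from one model (an absent
reaction carries no flux; the intersection-only alternative is available
by subsetting beforehand).  Differences are raw (\(a - b\)) or
percentages of the pairwise mean with zero-mean pairs dropped and the
drop count reported.  The summary is the classical mean difference,
standard deviation, limits of agreement mean \(\pm 1.96\) SD, and a
two-sided one-sample t-test of the differences against zero (a Wilcoxon
signed-rank alternative is available for heavy tails).
`disagreement_matrix()` applies the test to every unordered pair and
reports the percentage significant at \(\alpha\).

The t-test's nominal level holds when the per-reaction differences are
independent.  That is true under flux-level measurement noise, and the
null-calibration check in the acceptance suite is therefore formulated
at the flux level: two states are the same parsimonious FBA flux vector
plus independent per-reaction Gaussian noise.  Expression-level noise
propagated through the LP produces *correlated* flux differences (whole
pathways move together) for which no fixed-level guarantee exists; on
such pairs the test is a descriptive screen, exactly as in the original
use on real data.

# Clusterability and feature selection

`pca_cluster()` centers the flux matrix (no unit-variance scaling: flux
magnitude is the signal of interest; scaling is available), decomposes by
SVD, runs k-means on the first two component scores for each candidate
cluster count, and keeps the count with the best mean silhouette.  A
configuration is declared unclustered when even the best silhouette is
below 0.5, the Kaufman-Rousseeuw "reasonable structure" rubric.  The
floor matters: k-means imposes a partition on any two-dimensional point
cloud, and the silhouette such imposed partitions reach on isotropic
noise is roughly 0.35-0.48, while genuinely planted group structure
clears 0.7 under the study conditions.  A floor low enough to accept
noise partitions would make the null case (no planted effect) report
spurious clusters.

`rf_importance()` fits a random forest (500 trees,
\(\lfloor\sqrt{p}\rfloor\) candidate predictors per split -- the
classical defaults) on the flux matrix against cluster labels (or known
group labels for validation), ranks reactions by mean Gini impurity
decrease with deterministic tie-breaking, takes the top 15 (the scale of
reported discriminative-reaction sets per dataset-algorithm cell), and
aggregates their subsystems.  Cells whose PCA stage found fewer than two
clusters are excluded, mirroring the original analysis rule.
`subsystem_barcode()` sums the subsystem frequencies across cells: the
data behind the barcode display of which cellular subsystems concentrate
discriminative flux features.

# The synthetic data generator

`make_toy_model()` builds a deterministic, flux-consistent network of
about 50 reactions (default spec) in 14 subsystems:

* a **Warburg core**: glucose uptake (cap 10) into lumped glycolysis
  (GAPD analogue, net +2 ATP, +2 NADH per glucose), a fermentation
  branch (lactate dehydrogenase, lactate transporter, secretion-only
  lactate exchange), an oxidative branch (pyruvate dehydrogenase, lumped
  TCA, an ATP synthase consuming oxygen at P/O-like stoichiometry), an
  oxygen exchange *capped at 5*, an ATP maintenance demand (lower bound
  1), and a biomass reaction consuming precursors plus 20 ATP.  The
  oxygen cap is the Warburg switch: oxidative ATP is cheaper per carbon,
  so the biomass optimum saturates oxygen first and ferments the excess
  glucose -- GAPD and the synthase both run and lactate is secreted
  while oxygen is taken up, the flux-sign structure the Warburg indices
  measure.  With `include_warburg_core = FALSE` the cap is lifted and
  the optimum abandons overflow.
* **eight peripheral nutrient pathways**, one subsystem each (pentose
  phosphate pathway, fatty acid synthesis, ...), comprising a dedicated
  uptake, transporter and a 2-3 step chain ending in a
  substrate-level-phosphorylation step feeding pyruvate.  Uptake caps
  (3-6) and ATP yields (1-3) differ per pathway, so which pathways an
  extracted model retains shifts its flux state asymmetrically.  The
  dedicated uptake and transporter carry the pathway's subsystem label,
  making a planted pathway difference attributable to one subsystem.
* **GPRs** over a synthetic gene universe (~60 genes) with single-gene,
  isozyme (OR), complex (AND) and mixed shapes assigned deterministically
  given the seed.  Exchanges and demands carry no GPR, as in real
  reconstructions.

Capacity bounds are \(\pm 200\) (uncapped reactions): generous relative
to every attainable flux (< 80) yet small enough to keep indicator
big-Ms well-conditioned.

`simulate_expression()` draws a log-normal baseline per gene (median
\(e^2\), sdlog 0.6), applies group effects, adds per-replicate Gaussian
noise (sd 0.5, truncated at zero), and removes a platform-dependent gene
fraction *per sample* (5% RNA-seq, 10% microarray, 40% proteome).
Per-sample coverage is deliberate: stable platform-wide coverage would
add no between-sample variance, whereas detection dropout in proteomics
varies from run to run, and that variation is what makes proteome-based
context models the noisiest -- the qualitative platform ordering the
acceptance suite verifies.  The default group design has four groups:
group 1 is the reference and each later group *silences* one distinct
peripheral pathway (expression divided by 4, about 2.3 baseline standard
deviations on the log scale) -- a knockout-like, well-powered contrast.
Effects are planted at the gene level and propagate through GPR mapping,
so the extraction algorithms, not the generator, decide reaction fates.
All ground truth (planted subsystems, genes, reactions, per-sample
unmeasured genes) is returned alongside the matrix, and identical seeds
give byte-identical output.

`simulate_flux_matrix()` generates the FBA-based feature matrix directly:
each sample is the model's parsimonious flux vector plus iid Gaussian
noise, and each group offsets a small planted reaction set within one
subsystem.  This is the calibrated input for the clusterability stage.
The separation of layers is deliberate: flux states obtained through
extraction are piecewise-constant functions of expression (LP vertices),
so within-group flux variance collapses to zero under replicate noise,
and any between-group difference -- including numerically tiny
threshold-shift artifacts -- separates groups perfectly.  Feature
selection on such degenerate geometry is uninformative about the
method's behavior on real, noisy flux data; the flux-level generator
restores a calibrated signal-to-noise setting in which recovery of the
planted reactions is a meaningful yardstick.  The expression-level
pipeline is instead tested on what it does guarantee: each group's
extracted models lose exactly their silenced pathway while the reference
keeps it, and between-group flux differences concentrate on planted
subsystems.

# Orchestration

`run_benchmark()` executes the full grid (datasets x algorithms):
consistency reduction, preprocessing, mapping, extraction, parsimonious
FBA, scoring, pairwise Jaccard and Bland-Altman, PCA clusterability, and
random-forest selection (skipped with a log entry when fewer than two
clusters emerge).  Per-sample failures are recorded in the report and do
not abort the run.  One master seed fans out deterministically to the
stochastic stages (k-means restarts, forest growth), and all written
tables are plain text without timestamps, so a rerun with the same
configuration reproduces every output byte for byte.  The configuration
is echoed into the report and the output directory.

A thin command-line wrapper (`inst/scripts/fluxprint-cli.R`, verbs
`make-toy`, `simulate`, `extract`, `run-all`) exposes the same functions
for shell use; the package functions are the primary interface.

# Problem sizes

The validation suite uses: 20 random networks (15-30 reactions) for the
consistency oracle; 50 networks (8-12 reactions) for the FASTCORE
near-minimality bound (brute-force minimal supersets by exhaustive
subset search); enumeration oracles on networks of at most 10 reactions
for the iMAT/INIT optima; 80 extractions (4 algorithms x 20 profiles)
for the Warburg sign check; 1000 randomized fixtures for the
Jaccard/Bland-Altman closed forms; 300 flux-state pairs for the null
calibration; 20 simulation seeds each for planted-structure recovery and
the platform variance ordering.  These sizes keep each property check
well-powered at interactive runtimes.

# Limitations

* The toy network abstracts redox and energy carriers into single pools
  and ignores compartments, carbon accounting (no CO2) and byproduct
  chemistry; it is a testbed for integration behavior, not a model of
  human metabolism.
* Platform emulation is reduced to coverage and noise scale; probe
  effects, batch structure and intensity-dependent biases of real
  microarray/MS data are not modeled.  Passing the variance-ordering
  check shows the coverage mechanism is sufficient for the qualitative
  claim, not that real proteome integration behaves identically.
* Within-group expression noise largely vanishes through quantile
  thresholds, so extracted flux states are nearly identical within a
  group -- tight clusters that make clustering *easier* than on real
  data (see the layer discussion above).
* Bland-Altman disagreement percentages depend strongly on the number of
  reactions compared; at 50 reactions the t-test rarely reaches
  significance for sparse pathway differences, unlike on genome-scale
  models with thousands of reactions.  The package reports the statistic
  faithfully at both scales.
* Thermodynamic (loopless) constraints are out of scope; parsimonious
  selection suppresses most futile cycles but does not forbid them.
* iMAT and INIT are exact MILPs; past the node limit the best incumbent
  is returned and flagged in the diagnostics rather than silently
  treated as optimal.
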