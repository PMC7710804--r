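---
title: "Curvature-based robustness analysis of structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-based robustness analysis of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcnet)
```

## The problem

Cognitive impairment in multiple sclerosis has been linked to structural
disconnection: demyelination and axonal loss degrade the white-matter
network that couples cortical areas. One way to quantify how much such a
network can absorb damage is its *robustness* — the degree to which its
topology withstands the weakening or removal of nodes and edges. orcnet
implements a complete two-cohort robustness analysis of streamline-count
connectomes: per-subject network measures, a cognitive-impairment index
that splits a patient cohort into non-impaired (MSNI) and impaired
(MSCI) groups, nodewise and whole-brain group comparison with
family-wise error control, and correlation of network measures with the
impairment index. Because patient diffusion data typically cannot be
shared, the package also contains a first-class synthetic cohort
generator, so that every stage of the pipeline can be exercised,
calibrated and validated end to end.

The input boundary is the connectivity matrix: an N x N symmetric
non-negative matrix of streamline counts over a fixed parcellation
(N = 333 areas in the default, Gordon-style layout, with functional
community and hemisphere labels per node). Tractography, registration
and atlas construction are upstream of this package.

## Ollivier-Ricci curvature

The centrepiece measure is the Ollivier-Ricci curvature (ORC) of an
edge. Each node $i$ carries a lazy random-walk probability measure
$m_i$: mass $\alpha$ (the *idleness*) stays at $i$ and the remaining
$1-\alpha$ spreads over neighbours proportionally to edge weights,
$m_i(j) = (1-\alpha)\, w_{ij}/s_i$ with $s_i = \sum_j w_{ij}$. The edge
curvature compares the optimal-transport (Wasserstein-1) distance
between the endpoint measures with the ground distance between the
endpoints:

$$\kappa_{ij} \;=\; 1 \;-\; \frac{W_1(m_i, m_j)}{d(i,j)}.$$

When the neighbourhoods of $i$ and $j$ overlap, little mass has to move
and $\kappa_{ij}$ is positive — a perturbation at one endpoint is
quickly absorbed (robustness). Tree-like edges with disjoint
neighbourhoods give negative curvature (fragility). Node curvature is
the strength-weighted mean of incident edge curvatures,
$\kappa_i = \sum_j (w_{ij}/s_i)\,\kappa_{ij}$, which keeps it on the
edge-curvature scale; global curvature is the unweighted mean of node
curvatures over non-isolated nodes.

Four choices are not forced by the definition and are therefore
explicit, config-exposed parameters (the group *differences* the
pipeline reports should be, and in our simulations are, robust to
them):

* **idleness** — default 0.5 (the standard lazy walk; 0 gives the
  classical non-lazy construction used in the closed-form test cases);
* **ground metric** — default `"hop"` (unweighted shortest-path count;
  makes curvature invariant to uniform weight rescaling, so arbitrary
  streamline-count units cancel), with `"weighted"` ($1/w$ geodesics) as
  the alternative;
* **node aggregation** — strength-weighted mean;
* **global aggregation** — unweighted mean over non-isolated nodes.

$W_1$ is computed *exactly* by an in-package min-cost-flow solver
(successive shortest augmenting paths with node potentials; a Dial
bucket queue when ground costs are small integers, as they are for the
hop metric). Two reductions keep the per-edge linear programs small
without any approximation: shared mass between the two measures is
cancelled first (valid because the ground cost is a metric, so an
optimal plan exists that leaves common mass in place), and each
Dijkstra terminates at the nearest sink still carrying demand, with the
standard capped potential update. The solver is validated in the test
suite against exhaustive enumeration of transportation-polytope extreme
points (supports up to 3) and against an independent simplex LP solver
on random instances. A 333-node connectome at ~15 % density (about
9,400 edges) takes a few seconds per subject on one core.

Two degenerate cases worth knowing: on a two-node graph at idleness 0
the endpoint measures are point masses *on each other*, so
$W_1 = d(i,j)$ and $\kappa = 0$; at idleness 0.5 the two measures
coincide and $\kappa = 1$. Both are computed normally, not treated as
errors.

## Classical graph measures

Alongside curvature the pipeline computes strength
($s_i = \sum_j w_{ij}$), betweenness centrality (Brandes accumulation
on the $d = 1/w$ length graph — more streamlines, shorter edge;
unnormalized by default since group comparisons are invariant to the
constant), and the Onnela weighted clustering coefficient on
max-normalized weights,

$$\hat c_i = \frac{1}{k_i(k_i-1)} \sum_{j,h}
  \left(\hat w_{ij}\hat w_{ih}\hat w_{jh}\right)^{1/3},
  \qquad \hat w = w / \max w,$$

which lies in $[0,1]$ and reduces to binary clustering for equal
weights (this is the Brain Connectivity Toolbox convention, chosen so
the implementation cross-validates exactly against it). Global
measures are density, global efficiency (mean inverse geodesic over
ordered pairs, 0 for unreachable pairs), characteristic path length
(mean finite geodesic over reachable pairs, with a `disconnected`
flag rather than an infinite value), diameter, mean clustering, and
small-worldness $\sigma = (C/C_{rand})/(L/L_{rand})$ against
degree-preserving Maslov-Sneppen surrogates in which each rewired edge
carries its weight (default 100 surrogates, 10 swap attempts per edge,
seeded). Note that with raw streamline counts nodal efficiencies are
$w > 1$, so global efficiency is *not* bounded by 1; the unit bound
only applies to unit-weight graphs.

Shortest-path tie counting uses a relative tolerance of `1e-12`.
Betweenness, geodesics and clustering are verified against exhaustive
path enumeration on hundreds of random weighted graphs with up to 7
nodes.

## The impairment index

Twenty battery parameters (MACFIMS-derived) are scored against
normative data. A parameter is *failed* when the direction-corrected
z-score is strictly below $-1$ — performance more than one standard
deviation below the normative mean; exactly one SD is not a failure.
The CI index is the failed fraction, $n_{failed}/20$, and the labels
are: index $< 0.2$ MSNI, index $> 0.35$ MSCI, and the closed interval
$[0.2, 0.35]$ borderline — borderline subjects are excluded before any
group statistic. Whether a parameter is "higher is better" is input
metadata (`higher_is_better` in the normative table), never guessed.
Both the fraction definition and the two thresholds are configurable,
because the literature states the operating points inconsistently; the
defaults here follow the printed numeric thresholds.

## Statistics

All group tests are pooled-variance (Student) t-tests, not Welch: the
analysis assumes cohorts sampled from normal distributions with equal
standard deviations, and the test suite checks the implementation
against `t.test(var.equal = TRUE)`. At the node level the comparison is
two-tailed, one test per node, with the family-wise error rate over the
$m = N$ tests (333 for the default parcellation) controlled by the
Holm-Šidák step-down procedure at $\alpha = 0.05$: the $i$-th smallest
p-value is compared against $1-(1-\alpha)^{1/(m-i+1)}$, stopping at the
first failure; adjusted p-values use the standard step-down max
construction so that rejection is equivalent to adjusted $p \le
\alpha$. Each local measure forms its own family of $m$ tests
(mirroring per-measure reporting); a single combined family is a
config flag away. Nodes with no variation in either cohort are dropped
and $m$ reduced, with a message.

At the whole-brain level the tests are one-tailed with a per-measure
expected direction — robustness-type measures are hypothesized higher
in the non-impaired cohort. For characteristic path length and
diameter "more robust" does not fix a tail a priori, so those two
directions are required config entries with no silent default.

Correlations between nodewise measures and the CI index are Pearson,
computed over all included subjects of both cohorts pooled (borderline
excluded), two-tailed via the $t = r\sqrt{(n-2)/(1-r^2)}$ transform,
and uncorrected by default — they mirror per-node scatter plots of the
significant nodes; `correct_correlations = TRUE` adds Holm-Šidák over
the plotted set. Stepwise regression is deliberately absent from the
package: with many candidate network measures and modest cohort sizes
it overfits the sample and generalizes poorly.

## The synthetic cohort generator

The generator is hierarchical, mirroring how tractography count
matrices actually vary across subjects:

1. **Anatomy (study level).** Node centroids sit on a cortical-shell
   sphere (radius 70 mm ± 10 % jitter); hemispheres by the sign of x;
   communities assigned round-robin from the standard functional
   network names. An edge exists with probability
   $\exp(-\lVert c_i - c_j\rVert / \lambda)$, drawn once per study, and
   carries a lognormal base weight (meanlog 3, sdlog 1: median ~20
   streamlines, heavy upper tail). Every subject of a study shares this
   backbone — subjects share anatomy; resampling the topology per
   subject would (unrealistically) make edge existence the dominant
   variance component of every nodewise measure.
2. **Subject level.** Each edge weight is the base weight times a
   per-subject, per-edge lognormal noise factor (sdlog 0.35, inside the
   range of reported scan-rescan variability of streamline counts) and
   a per-subject global scale factor (sdlog 0.1 — tractography fixes
   the total streamline budget, so between-subject scale variation is
   modest), rounded to integer counts.
3. **Impairment.** Impaired subjects draw a latent severity in
   $[0.5, 1]$ (scaled Beta(2,2); bounded away from 0 so every impaired
   subject carries a deficit, spread out so the correlation stage has a
   graded signal). All edges incident to the planted nodes (default
   nodes 5 and 17) are attenuated by $1 - \delta\,\times$ severity with
   $\delta = 0.5$ — graded loss rather than deletion, though attenuated
   weights can round to zero and vanish. The CI index is a logistic
   function of the same severity (coupling 2, logit noise 0.2),
   anchored so controls land below the MSNI threshold and impaired
   subjects above the MSCI threshold at defaults; group labels are then
   assigned *from the index* through the classifier, never from the
   latent assignment, so the borderline-exclusion path is exercised
   exactly as with real data (widen the index noise to actually produce
   borderline subjects).

Default cohort sizes are 10 MSNI vs 31 MSCI on 333 nodes with decay
length $\lambda = 45$ mm (~15 % density, matching 333-area
streamline-count connectomes). When the generator is scaled down for
simulation studies the decay length should scale up: coarser
parcellations are empirically much denser (a 68-area atlas connectome
commonly sits near 50 % density). The packaged simulation studies at
60 nodes use $\lambda = 120$ (~40 % density) for this reason.

The noise defaults were calibrated — within the realistic ranges above
— so that the generator meets its design contract: at the default
planted effect the full pipeline recovers the planted nodes in ≥ 90 %
of replicates with a median of zero false positives, and the sign of
the measure-index correlations at planted nodes matches the planted
direction. These recovery rates are themselves asserted by the test
suite (100 replicate studies at 60 nodes), alongside a 1,000-replicate
complete-null simulation confirming that the nodewise stage's
family-wise error rate stays at or below the nominal 0.05.

### What the generator does not emulate

Real diffusion data bring distance-dependent tractography biases,
hemispheric asymmetries, lesion-load-dependent missingness and
non-multiplicative noise, none of which are modelled. Passing recovery
tests therefore demonstrate that the *pipeline* is correct and
calibrated under its stated assumptions, not that those effect sizes
are attainable in patients.

### A structural limitation worth knowing

A deficit planted at two nodes moves *global* mean curvature by only
about $2/N$ of the local change, and simulations show the sign of that
global response varies with the realized backbone (standardized group
differences from −0.6 to +0.9 across backbones at the default effect).
Whole-brain curvature separation between cohorts is therefore *not* a
reliable consequence of a node-localized deficit: in our simulations
the one-tailed global test reaches significance in only ~10–25 % of
replicates, and no noise setting fixes this without simultaneously
making neighbour spillover significant nodewise (the corresponding
expectation in the acceptance suite is left failing, by design, as an
honest record). Detecting a global curvature difference, as reported
in patient cohorts, plausibly requires diffuse pathology — many
affected nodes — rather than a localized one; users simulating global
effects should plant accordingly.

## Numerical and engineering choices

* Matrix symmetry tolerance is `1e-9`; larger asymmetry is an error
  (count matrices are exactly symmetric — asymmetry signals a wrong
  file), and sub-tolerance asymmetry is averaged away. Non-zero
  diagonals are zeroed with a warning.
* Node order is defined by the node table, not by ids; all matrices of
  a study must follow it. Text I/O is UTF-8, decimal point only.
* All randomness flows from one root seed, fanned out per subject and
  stage by a fixed integer mix, so a study re-runs byte-identically and
  single subjects can be regenerated in isolation.
* The analysis stage is separated from the measurement stage
  (`compute_measure_tables()` / `analyze_measures()`); reports can be
  regenerated from saved measure tables and are identical up to the
  6-significant-digit table format.
* Results tables are TSV with 6 significant digits; the JSON summary
  carries the significant nodes with community/hemisphere labels,
  left/right asymmetry counts, and the full run manifest (parameters,
  seeds, versions).

## Worked example

```{r example, eval = FALSE}
cfg <- study_config(
  generator = generator_config(n_nodes = 60, decay_length = 120,
                               seed = 421),
  global_directions = global_test_directions(
    characteristic_path_length = "msci_greater",
    diameter = "msci_greater"),
  seed = 421)
report <- run_study(cfg)
print(report)
report$summary$significant_nodes
```

The simulation studies shipped with the package use 40–80 nodes and
cohorts of 10 vs 31 (100 replicates for recovery, 1,000 for the null
calibration); the full-size 333-node path is exercised with minimal
cohorts. These sizes were chosen to keep the whole validation suite in
the minutes range on a single core while still covering the full-size
parcellation code path.
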