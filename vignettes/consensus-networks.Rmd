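---
title: "Quantifying consensus between connectome reconstruction pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying consensus between connectome reconstruction pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netconsensus)
```

## The problem

Structural brain networks are reconstructed from diffusion MRI by a long
chain of processing choices: parcellation atlas, registration scheme, fiber
model, tractography algorithm. Two reasonable pipelines applied to the same
scans produce different weighted connectomes, and there is no agreed way to
decide which connections to keep. `netconsensus` implements a comparison
framework that treats this disagreement as signal: it thresholds each
subject's two pipeline networks across *every* possible density, measures
their Dice overlap against what identical-density random networks would
share, and locates the density at which agreement beats chance most
reliably across subjects. The binary networks at that peak — and especially
their within-subject intersection — form a "consensus network" of
connections that survive both reconstructions.

## The model, step by step

**Weights.** For parcels $i \neq j$ the connection weight is a fiber
density: $w_{ij} = C_{ij} / \bigl((V_i + V_j)/2\bigr)$, where $C_{ij}$
counts fibers whose two end-points terminate in $i$ and $j$, and $V_i$ is
the total seed (boundary) voxel volume of parcel $i$ in mm³. Fibers that
start and end in the same parcel connect nothing and are discarded (the
count is reported). We read "mean volume of the seed voxels adjacent to the
two parcels" as the pair mean of the total volumes: the alternative
per-voxel-mean reading would make weights independent of parcel size, which
defeats the purpose of a density normalisation. Repeat scans are averaged
elementwise into one subject network per pipeline.

**Node merging.** When the two pipelines use different atlases, parcels are
merged to a common node scale through a correspondence table. Two modes
exist. With parcel volumes available, fiber counts are recovered from the
density weights, pooled between merged groups, volumes summed within
groups, and the weight formula re-applied — this commutes exactly with
building the network from pre-merged endpoint records (a property the test
suite verifies). Without volumes, weights are summed, an approximation that
is documented rather than hidden. Connections internal to a merged group
become self-connections and are dropped, with the lost count reported. The
packaged Desikan-Killiany (68 parcels) to common-scale (34 nodes, 17 per
hemisphere) table follows the published merge pattern where stated — the
three inferior-frontal subdivisions map to the inferior frontal gyrus, all
temporal parcels collapse to a single temporal-lobe node, and the pattern
is hemisphere-symmetric; assignments not spelled out anywhere are fixture
conventions of this package, not anatomical claims.

**Thresholding.** The binary network at edge count $k$ keeps the $k$
highest-ranked of the $T = N(N-1)/2$ possible connections. Equal weights —
predominantly the exact zeros of probabilistic tractography matrices — are
randomly ranked. One complete tie-broken ranking is drawn per network and
seed and reused across all $k$, so the thresholded networks are *nested*
across densities; redrawing ties at each density independently would
violate nestedness and make density sweeps noisier. Each
subject-by-pipeline combination draws its ranking from an independent
substream of the cohort master seed.

**Dice versus chance.** At density $d = k/T$ the Dice coefficient is the
fraction of the $k$ connections shared by the two pipelines. Two
independent random networks of equal density share $k^2/T$ connections in
expectation, so the chance-level Dice equals the density itself — a fact
the test suite validates by Monte-Carlo. At every interior density a
one-sample two-tailed t-test compares the subjects' Dice values to this
expectation; subjects are bootstrapped (1000 resamples by default, the same
resample draws reused across densities) to attach a standard error to the
$-\log_{10} p$ curve. The peak of that curve is the peak-convergence
density. At $k = 0$ both thresholded networks are identically empty and the
Dice coefficient is 1 by convention, but the density is excluded from
significance analysis because its chance expectation of 0 makes the null
degenerate; $k = T$ is excluded for the mirror-image reason.

**Consensus extraction.** At the peak density, each subject's convergent
edges are the intersection of the two pipelines' edge sets; the per-edge
prevalence is the fraction of subjects whose convergent set contains the
edge; and the group intersection network keeps the edges with prevalence
exactly 1. The thresholded subject networks are characterised by five
binary graph metrics: characteristic path length, clustering coefficient,
global efficiency, local efficiency and assortativity.

## Numerical choices

* **p-values in log space.** Near the convergence peak $|t|$ easily exceeds
  30 with 28 subjects, where $1 - \mathrm{CDF}$ subtraction underflows to
  zero. All p-values are computed as
  $\log p = \log 2 + \log S(|t|)$ via the log survival function, so
  $-\log_{10} p$ values of 50 and far beyond are exact. The logarithm base
  is 10 (configurable).
* **Degenerate samples.** If all subjects have the same Dice value and it
  equals the expectation, $t = 0$ and $p = 1$. If it *differs* from the
  expectation the t statistic is infinite; the value is floored at
  $-\log_{10} p = 350$ (beyond any representable double) and flagged. A
  flagged value is not a t-test outcome, so flagged densities are excluded
  from peak detection and from type-I-calibration summaries; with few
  subjects such degeneracies are routine at extreme densities (e.g. every
  subject's Dice is 0 at $k = 1$). Sample standard deviations at or below
  $10^{-12}$ are treated as exactly zero: genuine across-subject spread of
  Dice values is bounded below by $1/(k \cdot n)$, many orders of magnitude
  larger, while accumulated rounding in a constant column is smaller.
* **Variance computation.** Column variances of the Dice table use the
  two-pass (centered) formula; the one-pass formula leaves cancellation
  residues around $10^{-8}$ on constant columns, which a t statistic then
  amplifies into spurious astronomical significance at near-boundary
  densities.
* **Peak ties** break toward the lower density: the sparser network is the
  more specific consensus, and a warning is raised so flat curves are never
  silently resolved. Peak detection uses the point-estimate curve; the
  bootstrap mean is emitted alongside for plotting.
* **Symmetrisation.** Weight matrices must be symmetric within $10^{-9}$
  (then exactly symmetrised as $(W + W^\top)/2$); larger asymmetries are an
  error, never silently repaired.

## The synthetic cohort generator

No imaging data ships with the package, so every downstream stage is
exercised on synthetic cohorts that emulate the statistical structure the
analysis assumes:

* a **planted core** of true connections (default density 0.196 on 34
  nodes, the scale and peak density typical of merged-atlas analyses),
  hemisphere-symmetric by construction because consensus connections in
  real cohorts show high hemispheric symmetry;
* per-subject **latent weights**, lognormal with meanlog 3 / sdlog 0.5 for
  core edges versus meanlog 0 / sdlog 0.3 for the background — tractography
  fiber densities are non-negative and right-skewed, and the wide
  separation makes the core recoverable while the homogeneous background
  keeps non-core ranks weakly informative;
* **pipeline noise**: each pipeline observes the latent weights through
  independent multiplicative log-normal noise (default SD 0.22, set once by
  running `calibrate_noise()` at a target inter-pipeline Spearman of 0.675,
  the rank correlation scale reported for independent state-of-the-art
  pipelines) and independently zeroes a fraction (default 0.15) of non-core
  pairs, reproducing the tie mass at zero;
* **scan noise**: per-scan multiplicative log-noise (SD 0.3) *shared by the
  two pipelines*, because both pipelines reconstruct the same repeat
  acquisitions — with pipeline noise and zeroing switched off, the two
  pipelines' outputs are bitwise identical;
* **counter-based substreams**: every subject, scan and pipeline derives
  its own seed from the master seed, so enlarging a cohort never perturbs
  existing subjects.

What the generator does *not* emulate: spatial structure (distance-
dependent weight decay, lobe-level block structure), between-subject
anatomical variability of the core, correlated neighbouring-node
connectivity profiles, and heavy-tailed subject outliers. Passing tests
therefore demonstrate that the statistical machinery is correct and that
the pipeline recovers planted structure under realistic noise — not that
any particular real cohort would show the same peak.

A note on nulls: within one cohort the two pipelines share each subject's
latent weights, so even with zero core contrast they remain correlated —
that configuration is *not* a null. Null calibration uses two fully
independent random-weight cohorts (iid lognormal weights, no zeroing),
under which the thresholded networks are uniformly random equal-density
edge sets and the chance null holds exactly. Conversely, planted-core
cohorts are unsuitable for type-I checks because the fixed overlap between
two independently planted cores acts as a cohort-level random effect.

## Graph metric conventions

Metrics are computed directly on the adjacency matrix with pinned
conventions, because published implementations differ exactly in the
degenerate cases that sparse consensus networks hit:

* path length averages over *finite* ordered pairs and reports the number
  of unreachable pairs (consensus networks at density 0.1–0.2 can be
  disconnected);
* nodes of degree < 2 contribute 0 to clustering and local efficiency;
* assortativity is the Pearson correlation of end-point degrees with every
  undirected edge counted in both orientations, and is undefined (NaN, with
  a warning) for regular graphs;
* global efficiency averages $1/d_{ij}$ with $1/\infty = 0$; local
  efficiency is the mean over nodes of the global efficiency of the
  neighbour-induced subgraph.

The test suite checks all five metrics against independent brute-force
oracles (igraph BFS distances, explicit triangle enumeration, direct
edge-list correlation) on 100 random graphs to $10^{-12}$, plus closed
forms on $K_4$, $C_5$, the 4-node star and disconnected unions.

## Problem sizes used by the test suite

The packaged checks run at the scales the method targets while staying
desk-sized: 34-node schemes (T = 561 densities) for cohort-level
experiments, 10 subjects with 3 scans for recovery experiments (100 seeded
cohorts), 200 independent null cohorts for type-I calibration, 2000
Monte-Carlo repetitions for the chance-null validation, and
$n \le 15$ graphs for metric oracle equivalence. The full pipeline example
in the tests runs 6 subjects on 20 nodes with 25 bootstrap resamples.

## A worked run

```{r example, eval = FALSE}
out <- file.path(tempdir(), "demo_run")
manifest <- run_pipeline(run_config(
  mode = "synthetic", out_dir = out, seed = 7,
  synth = synth_config(n_nodes = 34, n_subjects = 10, n_scans = 3),
  n_boot = 1000))
manifest$peak_density      # detected peak-convergence density
curve <- read_result_json(file.path(out, "convergence_curve.json"))
plot(curve$densities, curve$neglogp, type = "l",
     xlab = "network density", ylab = expression(-log[10] ~ p))
```

## Known limitations

* The significance curve performs no multiple-testing correction across
  densities; a single global maximum is selected, mirroring the framework
  it implements, and the curve should be read as exploratory.
* Whether published analyses redrew tied ranks per density or once per
  network is not stated anywhere we know of; this package pins the
  once-per-network convention for its nestedness guarantee.
* The exact handling of disconnected graphs and degree-deficient nodes in
  published metric tables is likewise unstated; our conventions are pinned
  and reported, not asserted to match any specific publication numerically.
* Image-domain processing (parcellation, registration, fiber modelling,
  tractography) is out of scope: inputs are endpoint tables or weighted
  matrices.
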