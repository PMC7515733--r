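---
title: "Quantifying transition cells: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transition cells: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(transitr)
```

transitr addresses a question that hard clustering cannot: which individual
cells in a single-cell expression snapshot are *in transit* between cell
states, which states are genuine intermediates on the path between two
terminal states, and which genes change monotonically as cells move. This
vignette explains the models behind the package, the parameters that matter,
and the choices we made where the design was genuinely open.

## The analysis pipeline

### Filters and feature selection

Cells expressing fewer than 5% of genes are removed, then genes expressed in
under 10% of cells or with population variance below 0.005. These are the
conventional low-quality/uninformative cutoffs for mixed qPCR/UMI input and
are exposed as arguments.

`select_informative_genes()` looks for bimodality: each gene is modeled as a
three-component univariate Gaussian mixture. A gene whose near-zero
component carries more than 90% of the weight is a dropout-dominated gene
and is discarded. The rest are ranked twice — by the separation of the means
of the two heaviest components (large separation first) and by the
difference of their weights (balanced modes first) — and the two ranks are
summed; the 3000 best genes are kept. Two practical notes:

* Expression with a sizeable point mass at exactly zero is not a Gaussian
  mixture; when more than 10% of values are exactly zero we treat that mass
  as the zero-mean component directly and fit the two remaining components
  to the positive part. This is the same model evaluated sensibly rather
  than asking EM to approximate a point mass.
* Whether to `log1p` the data before fitting is input-dependent (qPCR-style
  input is already log-like); it is a flag, off by default.
* "Top two components" is interpreted as the two *heaviest* components; an
  interpretation by extreme means is equally defensible, but weight ordering
  is what makes the balanced-bimodal criterion meaningful. Rank ties break
  by gene name for determinism.

### Consensus matrix

The cell-cell similarity is a consensus over many base clusterings: each
clustering contributes a binary co-membership matrix and the consensus `M`
is their element-wise mean, so `M[i, j]` is the fraction of runs in which
cells i and j were co-clustered. The base family — k-means on the top
principal components over a grid of depths (5..30), cluster counts (2..10)
and three seeded restarts — mirrors standard single-cell consensus practice;
the averaging step is what defines the method and is exact. The ensemble is
fully configurable.

The number of clusters comes from the spectrum of the symmetric normalized
graph Laplacian `L = I - D^{-1/2} M D^{-1/2}`: eigenvalues are sorted
ascending and `k` is the position of the largest consecutive gap, searched
from 2 (a transition analysis needs at least two states; ties resolve toward
smaller k) to `k_max = 10`. `k` can always be overridden, as one would for a
dataset with known structure.

### Soft clustering and the plasticity index

`sym_nmf()` factorizes `M ~ H H'` with `H >= 0` (n cells x k clusters). We
use the classic damped multiplicative update (damping 1/2), which provably
never increases the objective, initialized from the absolute top-k
eigenvectors and perturbed across 10 restarts. Multiplicative updates
crawl near a stationary point, so each run finishes with a projected
gradient polish (Barzilai-Borwein steps, Armijo safeguard); on exactly
factorable matrices this reaches machine-precision residuals. Cluster
columns are ordered by their highest-membership cell so output is
deterministic up to numerical noise.

Row-normalizing `H` gives each cell a probability vector over clusters, and
the Cell Plasticity Index is its normalized entropy:

$$\mathrm{CPI}_i = -\frac{1}{\log k}\sum_{j=1}^k P_{ij}\log P_{ij}.$$

CPI is 0 for a committed cell and 1 for a maximally ambiguous one. Cells
above a CPI threshold are transition cells (TC). Published thresholds are
dataset-specific (e.g. 0.34 for a hematopoietic dataset), so the default is
automatic: Otsu's between-class-variance threshold on the CPI sample. When
the CPI distribution has an empty gap between modes the between-class
variance is flat across the gap and we return its first maximizer; any
value in the gap yields the same partition.

### Embedding

Cluster centers are placed by classical MDS on distances derived from the
cluster-cluster similarity `H'H` (normalized to a cosine-like similarity
`s`, distance `sqrt(2 - 2s)`). The projection method behind the original
center layout is not specified in detail anywhere we could follow, so MDS —
the canonical Euclidean embedding of a dissimilarity — is used and flagged
as configurable. Orientation is fixed (center 1 at the origin, center 2 on
the +x axis, center 3 in the upper half-plane) so runs are comparable.

Cells are placed by minimizing

$$\sum_{i,j} p_{ij}\lVert x_i - a_j\rVert^2 -
  \frac{\lambda_1}{n}\sum_{i,l}\lVert x_i - x_l\rVert^2,$$

attraction to the centers a cell belongs to, minus a pairwise repulsion that
keeps cells visible. The objective is quadratic with the exact stationary
point $x_i = (c_i - 2\lambda_1\bar c)/(1-2\lambda_1)$, $c = Pa$ — no
iteration, no local minima. It is bounded below only for
$\lambda_1 < 1/2$; `embed_cells()` refuses larger values. The default
$\lambda_1 = 0.3$ gives a well-spread cloud. One consequence worth knowing:
the repulsion acts as a dilation about the cloud centroid, so at large
$\lambda_1$ even fully committed cells sit off their centers; the
qualitative signature "plastic cells lie farther from their cluster center"
is cleanest at small $\lambda_1$ (the tests check it at 0.05).

### Trajectories, cell ordering, pseudotime

Every TC is assigned to the unordered pair of clusters holding its two
largest memberships; the pair counts define the transition graph. Clusters
with TC toward every other cluster are candidates for intermediate cell
states; an endpoint state — used as the default start — is a non-ICS
cluster with the fewest TC around it (little transition happens at a
terminal state). Trajectories are simple paths from the chosen initial
cluster through the neighbor graph (capped at k clusters); each collects the
cells whose top cluster lies on the path plus the TC aligned between
consecutive path clusters, and its occurrence probability is the collected
fraction of all cells. Cells with an off-path top-two pair still join
through their top cluster.

Along a path, cells are laid out leg by leg: cells of the current cluster in
ascending CPI (committed first), then the aligned cells already leaning to
the next cluster in descending CPI, ending with the final cluster's
remaining cells in descending CPI; the cell with the largest probability of
the initial cluster starts the ordering. Pseudotime is the cumulative
embedding distance along this ordering — cumulative rather than straight-
line distance to the start, because straight-line distance is not monotone
along curved paths (a direct-distance mode exists). Each leg is min-max
scaled onto consecutive unit windows ([0,1], [1,2], ...) so positions are
comparable across trajectories, and a cell on several trajectories takes
its minimum scaled value. The per-leg unit window is our concrete reading
of "scale the range between neighboring clusters"; no formula is published.

### Marker and transition genes

For the cells of one trajectory, expression is factorized as
`D' ~ H_bar W` with both factors nonnegative and a penalty
$\frac{\lambda_2}{2}\lVert \bar H - H_s\rVert_F^2$ tying the cell factor to
the soft-clustering memberships of the same cells. A bare linear coupling
$-\lambda_2\,\mathrm{Tr}(\bar H' H_s)$ expresses the same pull but is
unbounded below — scaling $\bar H$ up and $W$ down by the same factor
improves it without limit, and alternating updates diverge; completing the
square adds the ridge that pins the scale and changes nothing else about
the intent. $\lambda_2 = 10$ by default; the marker structure is stable
across $\lambda_2 \in [5, 20]$ (tested).

After column-normalizing `W`, a gene marks the cluster holding its largest
entry if the margin over the runner-up exceeds 0.03. Intermediate states
typically keep few or no markers — their genes are shared — which is itself
a useful signature. Transition genes for a leg are the markers of its two
flanking clusters whose Spearman correlation with the aligned cell order
reaches |rho| >= 0.64; the sign gives the direction of change. Ties in
expression use average ranks; genes constant over an ordering are skipped.

## The agent-based EMT simulator

`run_emt_simulation()` is the package's ground-truth generator: a population
of cell agents, each carrying an 18-species gene-regulatory circuit,
dividing, dying and drifting stochastically.

The shipped circuit is the package's own default parameterization, built
around the canonical epithelial-mesenchymal regulators and verified to have
exactly four stable states. Its architecture is a cascade of three
positive-feedback switches: SNAIL with its miR-34 antagonist; ZEB with
miR-200/miR-1199 and the epithelial guards OVOL2/GRHL2, licensed only when
SNAIL is high; and an autocrine TGF-beta/SMAD loop licensed only when ZEB is
high. Gating each switch on its predecessor is what yields exactly four
attractors — off/off/off (E), on/off/off (I1), on/on/off (I2), on/on/on (M)
— rather than the eight of three independent switches. E-cadherin and
Vimentin are graded readouts: E has the highest ECAD, M the highest VIM, and
the intermediates express both, I1 ECAD-dominant and I2 VIM-dominant.
`steady_states()` verifies all of this numerically at run time (relaxation
from ~1000 random states, endpoint clustering, Jacobian eigenvalues), so a
user swapping in their own parameters inherits the same checks. Because ZEB
sits on from I2 onward it is *not* an M-specific marker in this circuit;
VIM and the TGF-beta loop species are.

Kinetics use unit-scale Hill dynamics multiplied by `timescale = 0.1`/h, so
expression relaxes over a few tens of hours — slow enough that cells recently
perturbed by division are still measurably off-attractor at snapshot time
(these are the ground-truth transition cells), fast relative to the ~700 h
cell cycle.

Population rules: cells divide after Normal(700, 200) h (negative draws
resampled — waiting times must be positive), daughters receive the mother
state plus/minus `state * Normal(0, 0.7)` per species (clamped at zero),
carry a division budget drawn uniformly from {2..7}, and die Normal(1000,
100) h after the budget is spent. Expression follows
`dI = f(I) dt + 0.01 I dW` between events (Euler-Maruyama, dt = 0.1 h,
negatives clamped). Five cycles are interpreted as 5 x 700 h of simulated
time with a snapshot at each 700 h mark. From the default 200 cells (50 per
phenotype) the population reaches the low thousands after five cycles. A
cell is labeled by its nearest attractor within 10% of the minimum
inter-attractor distance, otherwise TC. A variant flag makes I1 cells
non-proliferative (division deferred until the cell leaves I1).

## The intermediate-state population model

The second generative model is deliberately minimal: population fractions
E, I_1..I_N, M with the direct E->M rate as the time unit, reverse direct
rate `alpha > 1`, forward rate `gamma` along the E -> I_1 -> ... -> I_N -> M
chain and reverse chain rate `beta * gamma`, starting from pure E. The
system is linear; columns of the rate matrix sum to zero, so the total
fraction is conserved exactly. `simulate_population()` integrates with a
stiff-capable solver (lsoda, rtol 1e-10) — large `gamma` and `N` make the
system stiff — and `pop_steady_state()` gives the exact settled fractions
from the rate-matrix kernel. For N = 1 the chain equations are taken as
I_1 receiving `gamma E + beta gamma M` and the N = 0 case reduces to the
two-state pair dE = alpha M - E, dM = E - alpha M, which matches the
closed-form M(t) = (1 - e^{-(1+alpha)t})/(1+alpha).

Three emergent metrics summarize a trajectory:

* **Adaptation sensitivity** AS = (max_t M - M(inf)) / max_t M — the
  relative overshoot. It is provably zero with no intermediates (M(t) is
  monotone) and grows with N; with many intermediates M(t) rings through
  several peaks before settling (oscillatory adaptation — asserted in the
  tests at alpha = 8, beta = 0.01, gamma = 40, N = 12).
* **Transition efficiency** TE = M(inf), the settled mesenchymal fraction.
* **Noise attenuation** NA = std(M~)/mean(M~), the coefficient of variation
  of the mesenchymal fraction when white noise of amplitude sigma = 1 is
  injected into the epithelial equation (Euler-Maruyama, dt = 0.01,
  E reflected at zero — the equations do not otherwise keep E nonnegative).

Two numerical choices deserve explanation. First, the injected noise enters
only E, so the total fraction is not conserved pathwise: it performs a
reflected random walk. Over a late stationary window the CV of M is then
dominated by slow total-mass wander and barely depends on `gamma`; the
informative comparison is over the *response* — `noise_attenuation()`
therefore defaults to the CV over the whole path, with the sweeps using a
response-scale horizon (t = 20), and offers a final-half window as an
option. Second, `sweep_population_metrics()` reuses one seed across grid
points (common random numbers): the scientific content of a sweep is the
comparison between grid points, and sharing the noise realization removes
most of the Monte-Carlo variance from those differences at no cost in bias.

The study conditions ship as defaults: `alpha = 8`,
`beta = 0.01`, chosen (once) as a point where all the qualitative behaviors
of interest coexist — AS peaks at an interior `gamma` on the {5, 20, 80}
grid while NA falls and TE rises with `gamma`, and at `gamma = 80`
increasing N from 1 to 8 raises AS while lowering NA and TE. The trade-off
story is visible directly in the sweep table: tuning `gamma` alone buys
efficiency and noise attenuation but eventually loses adaptation; tuning N
alone buys adaptation and attenuation but starves efficiency; raising
`gamma` first and N second achieves all three.

```{r sweep, eval = FALSE}
sweep_population_metrics(gamma = c(5, 20, 80), n_ics = 2)
sweep_population_metrics(gamma = 80, n_ics = c(1, 4, 8))
```

## What the simulator does and does not emulate

The agent-based model produces expression snapshots with known phenotypes,
known transition cells (off-attractor cells), lineage and division history —
exactly the ground truth needed to validate transition-cell calling, cluster
recovery (adjusted Rand index of hard labels vs planted phenotypes), CPI
contrasts and trajectory topology (E-I1-I2-M). It does *not* emulate
sequencing depth effects, dropout noise, batch structure, doublets or
cell-cell signaling; a pipeline that passes on simulator output is validated
in its logic, not certified against every artifact of real scRNA-seq data.
Real-data thresholds (TC cutoff, rho, marker gap) remain dataset-dependent
choices.

## Problem sizes and tolerances

Defaults were chosen so a full validation cycle is desk-scale: attractor
search on ~1000 random initial states, one simulated division cycle of a
200-cell population (~300 cells at snapshot), consensus over ~100 base
clusterings, stochastic ensembles of 100 paths per sweep point. Key
numerical tolerances: symNMF stops at a relative objective change of 1e-6
(polish to 1e-12 of that), the eigengap uses exact symmetric
eigendecomposition, population solves run at rtol 1e-10 and settledness
demands relative drift below 1e-6 over the final 10% of the horizon.

## Known limitations

* The consensus ensemble family is a documented default, not a published
  prescription; different ensembles give slightly different consensus
  matrices (k and memberships are typically stable for separated states).
* Trajectory direction is the user's choice of initial cluster (biology in,
  biology out); the package only proposes endpoints by their lack of
  surrounding TC.
* The circuit parameterization is a verified stand-in satisfying the
  four-attractor specification, not a transcription of a published
  parameter table; the module treats the network as data, so a published
  set can be dropped in unchanged.
* With strong injected noise the population SDE is boundary-dominated;
  its ensemble mean is slightly above the deterministic solution (the
  reflection adds mass), which is why unbiasedness is only asserted in the
  mild-noise regime.
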