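---
title: "Cost-thresholded connectome topology and structure-function coupling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-thresholded connectome topology and structure-function coupling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In ageing cohorts with cognitive impairment no dementia (CIND — impairment in
one or more neuropsychological domains without dementia), both the anatomical
wiring of the brain and its functional coordination degrade, and the two do
not degrade independently. `costnet` implements the full analysis chain for
studying this at the whole-brain network level:

1. build a **structural connectome** (SC) per subject from probabilistic
   tractography connection probabilities,
2. build a **functional connectome** (FC) per subject from region-averaged
   task-free BOLD time series,
3. characterise the **weighted graph topology** of both across a sweep of
   proportional cost thresholds, integrating each metric over a
   criteria-selected cost window into one composite value per subject,
4. quantify **SC-FC coupling** — the edge-wise correlation between
   structural and functional connection strength over structurally present
   edges — at the group and the individual level, and
5. run the group and cognition **statistics**: covariate-adjusted linear
   models on composite measures, exploratory per-node contrasts, Fisher z
   comparison of group-level coupling correlations, cognitive-domain
   associations with Bonferroni control, and the cohort demographics tests.

Because no imaging data ship with the package, a synthetic cohort generator
produces all three inputs (probability matrices, BOLD series, cohort table)
with *known*, injected ground-truth effects, so every downstream stage can be
verified by recovery simulations rather than by eyeballing.

# Connectome construction

**Structural.** Raw tractography output is directional: the connection
probability from region $i$ to $j$ differs from $j$ to $i$. The pair's
connection probability is the mean of the two directions
(`symmetrize_probabilities()`). Subjects differ in overall connection
probability for uninteresting reasons (tract length, SNR), so weights are put
on a common scale by log min--max normalisation (`normalize_sc()`):

$$w_{ij} = \frac{\log P_{ij} - \min \log P}{\max \log P - \min \log P},$$

with the extrema taken over the positive off-diagonal entries. Two numerical
choices deserve attention. First, $\log 0$ is undefined: zero probabilities
are excluded from the extrema and stay weight-0 non-edges, which preserves
the sparsity structure of tractography. Second, the min--max form necessarily
maps the *smallest positive* probability to weight exactly 0 — one edge class
is removed by normalisation itself. Both are contracts of the implementation,
tested as such; the normalisation is invariant to global rescaling of the
probabilities because the logs cancel.

**Functional.** FC edges are the absolute Pearson correlations
$Z_{ij} = |r_{ij}|$ between regional time series (`build_fc()`), giving a
symmetric, unsigned, weighted network with zero diagonal. Folding negative
correlations is a deliberate modelling choice inherited from the analysis
this package operationalises; no signed-network option is offered.

# Graph topology

All metrics operate on weighted (never binarised) adjacency matrices, with
the reciprocal-weight length map $l_{ij} = 1/w_{ij}$ for path-based
quantities — the standard convention when weights encode connection strength.

* **Global efficiency** $E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/L_{ij}$,
  with $1/\infty = 0$ for disconnected pairs. Note the $1/(N(N-1))$
  normalisation: with the $1/(N-1)$ prefactor sometimes printed, the quantity
  would exceed 1 on a complete unit graph, so the per-ordered-pair mean (equal
  to the mean of nodal efficiencies, a tested identity) is used.
* **Nodal efficiency** $E_i = \frac{1}{N-1}\sum_{j \ne i} 1/L_{ij}$ and
  **weighted degree centrality** $D_i = \sum_j w_{ij}$.
* **Local efficiency** is the mean over nodes of the global efficiency of
  each node's neighbourhood subgraph (mutual weights retained, the node
  itself excluded); nodes with fewer than two neighbours contribute 0.
* **Weighted clustering** uses the Onnela geometric-mean triangle intensity
  (weights rescaled by the network maximum, per-node coefficient
  $\sum (\hat w \hat w \hat w)^{1/3} / k_i(k_i-1)$). Weighted clustering has
  several competing definitions; Onnela's is the common toolbox default for
  weighted undirected graphs and is the package's documented choice.
* **Characteristic path length** averages $L_{ij}$ over *connected* ordered
  pairs. Excluding disconnected pairs avoids infinities; disconnection is
  penalised through the efficiency metrics instead, and the cost-selection
  criteria separately enforce connectedness.
* **Small-worldness**
  $SW = (C_{net}/C_{rand}) / (L_{net}/L_{rand})$, where the null terms are
  means over 100 degree-preserving rewired networks (`rewire_null()`,
  double-edge swaps, 10 accepted swaps per edge, weights travelling with the
  swapped edges so the weight multiset is preserved). $SW > 1$ indicates
  small-world organisation. Null generation is seeded and reproducible; if
  the proposal budget (100 x target swaps) is exhausted — e.g. on a complete
  graph, which cannot be rewired — the current state is returned with a
  warning.

# Cost thresholding and composite measures

Networks of different subjects are compared at matched wiring **cost** (edge
density): `apply_cost()` retains the $k = \mathrm{round}(c\,N(N-1)/2)$
largest-weight edges. Ties at the cutoff are broken lexicographically by
$(i, j)$ — deterministic, so reruns are bit-identical. Candidate costs run
over $0.01 \le c \le 0.40$ in steps of 0.01.

The analysed window is chosen by `select_cost_range()`: for SC, every
subject's network must be fully connected, mean binary degree must exceed
$\ln N$ (the sparse-regime condition), and small-worldness must exceed 1.2;
for FC, at least 80% of nodes must lie in the largest component for at least
95% of subjects, with the same degree condition and $SW > 1$. Mean degree is
counted on binary edges after thresholding ($2k/N$). Whether small-worldness
should be screened per subject or on the group-mean network is genuinely
open; the package evaluates it on the group-mean connectome per cost with a
reduced 20-null ensemble (cheap, low-variance), reserving the full 100-null
ensemble for reported metrics, and records the choice in the run manifest.
The maximal contiguous run of passing costs is returned; if no cost passes,
the error lists the first failing criterion at every cost.

Each metric evaluated across the selected window is collapsed into a
**composite** by the trapezoidal rule (`composite()`). "Integral" admits many
quadratures; the trapezoid is the minimal-assumption choice, reduces to a
scaled mean on dense uniform grids, and is linear in its inputs (tested).

# SC-FC coupling

`coupling()` correlates structural and functional edge weights over the
upper-triangle positions where SC is non-zero — the mask comes from the
*unthresholded* normalised SC, since coupling is about structurally present
connections, not about any particular cost. At the group level the mask is
taken from the group-mean SC; at the individual level from each subject's own
SC. Group-level coupling correlations are compared with the Fisher z test
using the masked edge count as $n$; masked edges are not independent
observations, so `n_edges` is always reported alongside $r$ to keep that
caveat auditable. Individual-level coupling values are compared across groups
with the covariate-adjusted GLM instead.

# Statistics

`fit_glm()` is ordinary least squares of a per-subject measure on dummy-coded
group plus age, gender and handedness, with NCI as the reference level;
pairwise contrasts are read off by re-referencing the factor, so all groups
contribute to the error term. Covariates constant across the whole cohort are
dropped (a covariate uniform within a single group — e.g. a group with no
left-handers — is ordinary and retained); perfect collinearity among
predictors is an error. Nodal contrasts run one GLM per node at $p < 0.01$
uncorrected and are labelled exploratory. Domain associations regress each of
the seven cognitive z-scores on the measure plus covariates, declaring
significance at raw $p < 0.05/7$ (strict inequality). Demographics use
one-way ANOVA plus Levene's test; post-hoc comparisons switch between
pooled-SD t tests with Bonferroni adjustment (homoscedastic) and Tamhane's
T2, implemented as pairwise Welch t with a Sidak-type adjustment — an
approximation of the classical procedure, and documented as such. Categorical
items use the Pearson chi-square without continuity correction, with a note
recorded whenever an expected cell count falls below 5.

# The synthetic cohort generator

The generator (`sim_config()`, `simulate_cohort()`) emulates the *inputs* of
a three-group CIND-style cohort at the matrix level. Its defaults are the
study-scale conditions: 126 regions, 97/61/56 subjects (NCI/mild/moderate),
125 time points. Every draw is a pure function of `(config, seed)`, with
per-subject streams split from the cohort seed by counter so that one
subject's data are invariant to the other groups' sizes.

**Structural backbone.** Regions sit on a ring; connection existence decays
with ring distance with scale `lambda = N/10`, plus distance-independent
shortcuts with probability `p_far = 0.35` (jittered per subject,
SD 0.02, as the subject-level heterogeneity source). This yields ~50%
non-zero off-diagonal entries — the realistic tractography sparsity regime —
and guarantees that thresholded networks are in the small-world regime
(strong short-range edges, sparse long-range shortcuts), so the SW > 1.2
selection criterion is satisfiable. Connection probabilities follow a
logistic-normal model decaying with distance, with a small independent
directional perturbation (SD 0.05) so that $P_{ij} \ne P_{ji}$ and the
symmetrisation step is genuinely exercised. "Long-range" is defined as ring
distance $> N/8$ — a simple deterministic surrogate for anatomical distance —
and the impaired groups' long-range probabilities are multiplied by
`sc_deficit`.

**Functional signals.** Each subject's BOLD series are zero-mean Gaussian
draws with covariance $\alpha\,C_{SC} + (1-\alpha)\,\Sigma_0$, where
$C_{SC}$ is the subject's normalised SC rescaled into a valid correlation
matrix (eigenvalues clipped from below at 0.01 — a dense weight matrix plus
identity is generally indefinite, and a plain ridge repair would have to be
so large that it crushes the structural signal), and $\Sigma_0$ is a fixed
cohort-level low-rank-plus-diagonal correlation matrix, so groups differ only
through $\alpha$ and the structural deficit. $\alpha$ is the ground-truth
coupling knob: measured SC-FC coupling is strictly increasing in it, reaching
about 0.57 at $\alpha = 1$ with 125 time points (the attainable maximum is
limited by correlation estimation noise, exactly as in real data). A final
ridge repair to minimum eigenvalue $10^{-8}$ remains as a guard.

**Calibrated defaults.** Group `coupling_alpha` defaults (0.562 / 0.575 /
0.590) were calibrated once by simulation so group-level coupling lands near
the 0.43 / 0.45 / 0.48 ladder with the moderate group highest; `sc_deficit`
defaults (1 / 0.988 / 0.971) so the moderate-vs-NCI composite global
efficiency deficit is a Cohen's d of roughly 0.4 — the magnitude a t
statistic near -2.5 implies at these group sizes. Power studies in the test
suite use a stronger documented deficit (0.93 at 60 nodes, d ~ 0.8) and a
coupling offset of 0.05 in $\alpha$ (a true coupling difference of ~0.05).

**Covariates and cognition.** Ages are truncated-normal per group (means
67 / 71 / 74, echoing the demographic gradient of such cohorts); gender and
handedness are categorical draws with group-specific proportions. The seven
domain z-scores are a linear function of the subject's cohort-standardised
true global efficiency and true $\alpha$ (positive efficiency loadings on
executive function and visual memory; negative coupling loadings on visual
memory, executive function and visuoconstruction), plus Gaussian noise
(SD 0.6). Group differences in cognition therefore arise *only* through the
injected network effects — which keeps the null configurations exactly null —
at the price of not reproducing the full 1.5-2 SD cognitive separation seen
in real impaired cohorts.

**What the generator is not.** It makes no claim about the generative process
of diffusion or functional MRI: no hemodynamics, no head motion, no
acquisition noise, no spatial embedding beyond the ring surrogate, and
cognitive scores with a deliberately simple linear structure. Passing
recovery tests therefore demonstrates that the *pipeline* recovers effects of
known size from data of this shape — not that the generator reproduces brain
data.

# Problem sizes and numerical choices

The package's simulation studies use 60-node networks with 50 subjects per
group and 200 replicate cohorts for power and calibration checks, 100-node
ensembles of 100 nulls for small-world calibration, and the full
126-node / 214-subject default cohort for the end-to-end run — sizes chosen
to make each stochastic check statistically decisive (binomial Monte-Carlo
error a few percent) while keeping a full run on one CPU comfortable.
Floyd-Warshall all-pairs path lengths and the double-edge-swap null model are
implemented in compiled code; `igraph` serves as an independent cross-check
in the tests rather than as the implementation. Determinism is end-to-end:
the pipeline writes a JSON manifest echoing the full configuration and seed,
and rerunning with the same pair reproduces every CSV byte for byte.

# Known limitations

* The Fisher z test at the group level inherits the edge-non-independence
  caveat discussed above.
* Tamhane's T2 is approximated by Sidak-adjusted Welch comparisons.
* Nodal tests are uncorrected across nodes by design (exploratory).
* The generator's ring surrogate has no hemispheric or network-community
  structure; nodal-level spatial patterns of real cohorts are out of reach.
* Only unsigned FC is supported.
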