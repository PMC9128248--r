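---
title: "Direct co-expression networks with part mutual information: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct co-expression networks with part mutual information: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pminet)
```

## The problem

Pearson-correlation (PCC) co-expression networks are dense: a regulatory
cascade X → Y → Z induces a strong X–Z correlation even though no direct
relationship exists, so edge-level interpretation drowns in redundancy.
Part mutual information (PMI) is a conditional dependence measure built to
score *direct* association: for a gene pair (X, Y) and conditioning
variables Z,

$$\mathrm{PMI}(X;Y\mid Z) \;=\; D\bigl(p(x,y,z)\,\|\,p^*(x|z)\,p^*(y|z)\,p(z)\bigr),$$

where $D(p,q)=\sum_x p \log (p/q)$ is the *extended* KL divergence ($q$
need not normalize to 1) and the partially conditioned marginals are

$$p^*(x|z)=\sum_y p(x|z,y)\,p(y), \qquad p^*(y|z)=\sum_x p(y|z,x)\,p(x).$$

Unlike conditional mutual information, PMI does not collapse to zero when
the conditioning variable is strongly dependent on X or Y, which is the
regime gene cascades live in. PMI is symmetric in X and Y and is reported
in nats throughout.

## Estimation: two schemes

`pmi()` estimates the functional from samples in one of two ways.

**Discretized (modular) scheme.** Variables are binned
(`equal_frequency` by default, `equal_width` available; `n_bins = 3`),
the joint table is the empirical relative frequency (`estimate_joint()`),
$p^*$ is computed by direct summation with the convention that terms with
$p(z,y)=0$ contribute 0 (`star_conditional()`), and the extended KL is
evaluated with $0\log(0/q)=0$ and a $+\infty$ sentinel when some observed
cell has zero reference mass (`extended_kl()`). No pseudocounts are added
by default (a Laplace `alpha` is available), so small-sample estimates
agree exactly with direct summation of the defining formula — the test
suite exploits this by checking the modular pipeline against an
independent brute-force oracle over a grid of 2×2×2 joints.

**Gaussian (covariance) scheme.** For continuous expression data the
binned plug-in estimator has a structural defect when used to *condition*:
after reducing a continuous mediator Y to 3 bins, X and Z remain
substantially correlated within bins. On the unit-coefficient chain
X → Y → Z with noise sd 0.5 at n = 2000 the leakage alone is roughly
0.07 nats — about a quarter of the unconditioned signal — and finer
conditioning bins trade leakage for rapidly growing plug-in bias, so no
bin count makes the indirect edge cleanly removable. We therefore also
provide a closed-form estimator under a jointly Gaussian working model:
with conditioning set W, $p(x|w,y)$ integrated against $p(y)$ is again
Gaussian, so $p^*(x|w)$ is Gaussian with variance
$s_x^2+\beta_y^2\sigma_y^2$, and every expectation in the PMI decomposition
is a quadratic form in the sample covariance matrix. This is the estimator
family used in practice for continuous expression data; it vanishes under
exact conditional independence, reduces to the Gaussian mutual information
$-\tfrac12\log(1-\rho^2)$ without conditioning, and conditions without
leakage. It is the default for network construction; `pmi()` itself
defaults to the discretized scheme so that discrete worked examples
(e.g. perfectly dependent binary variables giving $\log 2$) hold exactly.
The cost of the Gaussian scheme is its working model: strongly
non-monotonic dependence is invisible to it, exactly as for PCC. When
non-monotonic structure matters, the discretized scheme (or the
`nonlinear` option of the simulator, for experimentation) is the tool.

## Network construction

`pmi_network()` starts from the fully connected network over the input
genes and eliminates edges against a threshold:

* **order 0** removes pairs whose unconditioned PMI is below the
  threshold;
* **order k ≥ 1**: for each surviving edge (X, Y), the conditioning
  candidates are the k-subsets of the *common network neighbors* of X and
  Y; the edge's retained strength is the **maximum** PMI over candidates
  ("retain the top one"), and the edge is removed when that maximum falls
  below the threshold. Passes are synchronous (neighbor sets frozen at the
  start of each pass) and candidate enumeration is lexicographic, so the
  procedure is fully deterministic; the loop stops at `max_order`
  (default 1) or as soon as a pass removes nothing.

Restricting candidates to common neighbors bounds the combinatorial scan
that makes the full procedure infeasible at genome scale; a genuinely
unconditionally-dependent pair with no shared neighbors keeps its order-0
strength. The `+Inf` sentinel from degenerate estimates means "retain".

The max-over-candidates rule deserves a caveat: an edge is removed only
when *every* candidate conditioning set explains it away. A poor separator
(e.g. a noisy sibling of the true mediator) can therefore keep an
indirect edge alive. That is the intended semantics of "top one", not an
implementation accident, and it is what keeps strongly supported edges
from being eliminated by one unlucky conditioning set.

**Threshold selection.** `optimal_network_scan()` fits one network per
threshold on an ascending grid and scores consecutive edge sets by Jaccard
similarity; the chosen network sits at the first step whose similarity
reaches `stability_tol` (default 0.95 — no stability criterion is
inherited from the procedure's description, so this is the package's own
definition, exposed as configuration). Two empty edge sets count as
identical. If the scan never stabilizes the last (sparsest) network is
returned with a warning.

## Comparable PCC networks

Three constructions make a PCC network comparable to a fitted PMI network:
type 1 matches the **edge count** (top pairs by |PCC| within the PMI gene
set), type 2 the **node coverage** (shortest |PCC|-descending prefix whose
endpoints cover the PMI nodes), and type 3 asks, for each PMI edge
(G1, G2), whether a third gene G3 has higher |PCC| with *both* endpoints
than |PCC(G1, G2)|; each such G3 contributes both of its edges. Type-3
networks include the PMI edges themselves so the recall comparison runs on
one universe; `pcc_only_edges()` recovers exactly the contributed edges
absent from the PMI network, which is unaffected by that inclusion. Ties
in |PCC| are broken lexicographically by pair name so repeated runs are
identical; G3 candidates range over the PMI gene set (the natural reading
of "another gene from the PMI network"), excluding zero-variance genes.

## Correlation change networks

Four single-stage networks along a progression (normal plus three disease
stages, stage numbers 1–4) are unioned by `combine_stages()`; each edge
carries a 4-bit existence pattern rendered `"a-b-c-d"` (`"0-1-1-1"` =
present in all three disease stages but not in normal).
`filter_inconsecutive()` drops edges whose occupied stages do not form one
contiguous run — a correlation that flickers on and off along the
progression is treated as unstable. The per-node *mean stage value*
averages the stage numbers over every (edge, stage) incidence of the node,
so a node whose edges concentrate late in the progression scores near 4.
Filtering precedes the mean-stage computation in the writers, matching the
reading that ignored edges contribute nothing to node placement.

## Omics-defined gene-pair relationships

Every table stores unordered canonical (lexicographic) gene pairs with
nonnegative weights:

* **CoTR** — pairs sharing upstream regulators, weighted by the number of
  common regulators; TF- and miRNA-derived tables are never mixed.
* **PPI** — curated interaction pairs, unit weight.
* **SCGD** — same-chromosome pairs weighted by the distance between
  transcription start sites; coordinates are 0-based half-open (BED
  dialect) and the TSS is the interval start on `+` and the end on `-`.
* **CoCNV** — per sample, the joint GISTIC-style status of a pair: GG
  (both gained), LL, GL/LG (mixed, oriented by the canonical gene order),
  or NC when either gene is unmutated. Per pair and type the table
  records the sample count, the count normalized by cohort size, and the
  level-product weight $\sum |cnv_1 \cdot cnv_2|$.
* **CoDM** — per gene and sample, the counts of CpG islands with beta
  below 0.3 (L) or above 0.7 (H) (standard hypo/hyper conventions,
  configurable); a pair's profile is the four cross products
  (LL, HH, LH, HL), which satisfy HH·LL = LH·HL identically. Tables
  record the positive-sample count, the value sum, and the sum normalized
  by cohort size.

## Recall Z-scores

`recall_zscore()` matches a network's canonical edge pairs against a
relationship table and compares the recalled count (and weight sums, one
variant per numeric weight column, each labeled in the output) with a
permutation null: each of `n_perm` (default 100) draws takes the same
number of pairs uniformly *without replacement* from all pairs of the
universe — by default the network's own gene set, matching comparisons
within a fixed PMI gene universe. $Z=(\text{obs}-\mu_0)/\sigma_0$; a
zero-spread null yields an `NA` sentinel with a warning. The unweighted
null is exactly hypergeometric, which the tests exploit as an independent
oracle. Depletion ("may exclude") simply appears as a negative Z.
`compare_weights()` contrasts the weight distributions of two recalled
sets with a two-sided Mann–Whitney test (distribution-free; Welch t
behind a flag).

## Survival factors and the patient score

For a gene pair, CoCNV statuses partition patients into up to five groups;
every unordered pair of groups with **more than** `min_n = 20` samples is
compared by a two-group log-rank test (implemented from the standard
O−E / hypergeometric-variance formula; the suite cross-checks it against
`survival::survdiff` and a permutation oracle). Significant comparisons
(uncorrected p < 0.05, mirroring the original design; a BH flag is easy to
apply downstream) become factors oriented by the Kaplan–Meier restricted
mean: `"GG > NC"` means GG patients survive better. For CoDM, each of the
four values with normalized mean absolute deviation
$\mathrm{NMAD}=\mathrm{mean}|v-\bar v|/\bar v$ above 0.25 (the NMAD
formula is the package's reading of "normalized mean average deviation",
which has no printed formula) is median-split (`> median` = high) and
tested the same way, giving factors such as `"HH-high > HH-low"`.

Each factor-bearing pair contributes $I_{gp}\in\{-1,0,+1\}$ to a patient:
+1 if the patient's status (or median group) appears only on the better
side of the pair's factors, −1 if only on the worse side, 0 otherwise.
NC is always neutral — in a factor against NC only the mutated side
carries impact, so NC scores 0 even when it formally sits on a factor
side; any *mutated* status appearing on both sides across one pair's
factors is a contradiction and raises an error rather than summing
silently. The patient score is $\mathrm{Score}=\sum_{GP} I_{gp}$, bounded
by the number of factor-bearing pairs; patients are divided into three
groups by score tertiles with ties assigned to the lower group (the
3-group division has no printed cutpoints; fixed cutpoints can be supplied
by calling `divide_by_score()` on recoded scores). `cox_multivariate()`
fits the score(s) — CoCNV and CoDM scores may enter together — alongside
simplified integer clinical covariates with `survival::coxph()`, and
`subsample_stability()` summarizes per-covariate p-values over repeated
80% subsamples (mean and sd; a single repetition reports an `NA` sd).

Single-gene analyses can reuse the same machinery by encoding a gene's
status as a degenerate "pair"; the grouping thresholds are unchanged,
which is an interpretation rather than a printed rule.

## The synthetic-data module

All pipeline inputs are generated from known ground truth so every stage
is testable without external downloads:

* **Expression** (`simulate_expression()`): linear-Gaussian structural
  sampling over a DAG in topological order — roots are standard normal,
  children are coefficient-weighted parent sums plus N(0, `noise_sd`²)
  noise. Defaults are unit coefficients and `noise_sd = 0.5`, the chain
  conditions used throughout the tests; path correlations then have
  closed forms (e.g. r(X1,X3) = r(X1,X2)·r(X2,X3) on a chain), which the
  tests use as oracles. A quadratic-link option produces non-monotonic
  dependence for experimentation with the discretized scheme; it is not
  part of any acceptance condition.
* **Staged expression** (`simulate_staged()`): the base graph restricted
  to four per-stage edge masks, with per-stage seeds derived from one
  seed.
* **CNV** (`simulate_cnv()`): sparse background mutations
  (rate 0.05/cell, levels ±1/±2) plus designated pairs co-mutated at
  stated rates.
* **Methylation** (`simulate_dm()`): per-island betas from a
  low/mid/high Beta mixture — Beta(1.5, 15), Beta(10, 10), Beta(15, 1.5)
  — with per-gene weights, so L/H island counts are controllable.
* **Survival** (`simulate_survival()`): exponential event times with
  per-sample hazard `baseline × ∏ multipliers` over planted pair
  statuses (multiplier 0.5 doubles the median survival of carriers —
  closed form used as an oracle) and independent exponential censoring
  calibrated so each sample is censored with probability `censor_rate`.

What the generators deliberately omit: microarray noise models, batch
effects, copy-number segment structure, probe-level methylation artifacts,
and any dependence between censoring and covariates. Passing tests
therefore certify the *algorithms* under clean generative conditions, not
robustness to real-data artifacts.

## Problem sizes and numerical choices

The suite runs its end-to-end checks at deliberate desk scale: 2×2×2
joint grids for oracle equality (tolerance 1e-9), 3-gene chains at
n = 2000 over 50 seeds for indirect suppression, 20 genes / 10 planted
edges / n = 1000 over 10 seeds for network recovery (median precision and
recall ≥ 0.7), 200-replicate null calibration for recall Z-scores, and
100 simulations at n = 200 for survival-factor power. Genome-scale
optimal networks are explicitly out of scope — the elimination procedure's
cost is the known obstacle — and the common-neighbor candidate restriction
plus `max_order = 1` are the package's bounded stand-in for the full
combinatorial scan.

Degenerate inputs are handled explicitly: constant variables error as
"degenerate"; zero-variance genes are excluded from PCC candidate sets
with a warning; zero-spread permutation nulls, all-identical scores and
single-repetition subsampling return flagged sentinels rather than
numbers that look meaningful.

## Reproducibility

Every stochastic function takes an integer seed and restores the caller's
RNG state on exit; networks, tables and scores are deterministic given
data and parameters (lexicographic tie-breaks throughout). The CLI
(`inst/cli/pminet.R`) writes a JSON manifest of parameters, seeds and the
package version next to every output, so a run is reproducible from its
manifest alone.
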