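---
title: "Discriminative k-mer groups: model, design choices and validation"
author: "peakgl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative k-mer groups: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Peak calls from ChIP-seq, DNase-seq or ATAC-seq mark genomic windows
where a transcription factor binds or chromatin is open, but not *which*
sequence signals drive the signal. `peakgl` learns those signals de
novo by a discriminative route: it classifies 150 bp windows centered
on peak summits (positives) against same-width windows centered 300 bp
upstream of the summits (negatives), using wildcard k-mer counts as
features, and then reads the binding signals off the structure of the
fitted model.

Features are all 8-mers over A/C/G/T plus all 8-mers carrying one
interior run of one or two wildcard positions (`.`, matching any base).
A pattern and its reverse complement describe the same double-stranded
signal, so the pair is collapsed into a single feature whose count in a
sequence is the number of positions where either orientation matches;
palindromes are counted once per position, and any window containing N
matches nothing. Wildcards let a single feature absorb the degenerate
positions typical of binding sites, which keeps a motif's evidence from
being shredded across dozens of isolated exact k-mers.

The 5000 most discriminative features (30000 in open-chromatin mode)
are clustered into `G` groups (20 / 200) by hierarchical clustering
with one minus the Spearman correlation of their count profiles as the
distance, so that k-mers that co-occur across the same examples — a
consensus together with its wildcarded and shifted variants — share a
group. The classifier is a logistic regression with a sparse group
lasso penalty,

$$
\min_w \sum_i \log\!\big(1 + e^{-y_i\, w \cdot x_i}\big)
 + \lambda_1 \sum_g l_g \lVert w_g \rVert_2
 + \lambda_2 \sum_m \lvert w_m \rvert ,
$$

where $x_i$ is the k-mer count vector of example $i$, $y_i = \pm 1$ its
label, $w_g$ the weight block of group $g$ and $l_g$ the group size.
The group term switches whole groups off — each surviving group is a
candidate binding signal — while the elementwise term keeps the active
groups sparse inside.

After the fit, each group is associated with the class whose examples
it activates more strongly (the sign of the mean-activation
difference), examples significantly explained by the group are called
against an empirical null built from the opposite class's activations
(Benjamini–Hochberg at 5% FDR, with the +1/(N+1) correction so p-values
are never zero), the best-scoring position of the group's patterns in
each significant sequence is located, and a 50 bp window around it is
exported for motif summarization or external motif tools. Groups need
at least 25 significant examples to be considered for motif finding.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `width` | 150 bp | window around the peak summit assumed to contain the signal |
| `flank_gap` | 300 bp | distance from summit to the flank-window center; leaves a 150 bp gap between windows |
| `k`, `max_run` | 8, 2 | k-mer length and maximal wildcard run |
| `n_top` | 5000 (chip) / 30000 (dnase) | discriminative features kept |
| `G` | 20 / 200 | co-occurrence groups = group lasso blocks |
| `lambda1`, `lambda2` | 10-fold CV | group- and k-mer-level penalty weights |
| `fdr` | 0.05 | false discovery rate for group membership calls |
| `min_examples` | 25 | significant examples required for motif eligibility |
| `alpha`, `beta` | 1.5, 1 | multitask penalty multipliers (task-specific / common) |

The penalty grids default to eight log-spaced points spanning three
decades down from the data-derived maximum (the smallest value at
which the zero model is optimal, computed from the gradient at
$w = 0$), and folds are stratified by class from an explicit seed — the
fold assignment is the only randomness in training.

## Design choices where the design was open

**Flank geometry.** "Upstream" means the lower reference-strand
coordinate; the flank is a full-width window *centered* `flank_gap`
upstream of the summit, which is symmetric with the positive window
and guarantees the two windows never touch at the defaults. Odd widths
put the extra base on the right: `[summit - floor(w/2),
summit + ceil(w/2))`.

**Wildcard geometry.** "Up to two consecutive wildcards" is realized
as exactly one interior run of one or two `.` positions. Runs touching
the first or last position would duplicate shorter k-mers and are
excluded; the run-geometry enumeration is validated against an
exhaustive generate–canonicalize–dedupe oracle for all `k <= 5`.

**Feature selection score.** The selection criterion is
`|mean(pos) - mean(neg)| / (pooled sd + 1e-8)` — a scale-free
two-class separation measure, deterministic, with ties broken by
dictionary order.

**Clustering linkage.** Ward's criterion (`ward.D2`) is the default.
On planted-motif data, average linkage chains the large mass of weakly
correlated background features into one giant cluster that swallows
distinct motifs' k-mer families (observed on every seed tried: one
cluster holding over half of all features, with both planted motifs
inside), which defeats the purpose of the groups. Ward produces
compact, balanced clusters that isolate each family; average linkage
remains available through the `linkage` argument, and the toy-scale
correctness test compares `linkage = "average"` against a hand-written
agglomerative oracle.

**Group weights.** The group penalty uses $l_g$ itself, matching the
objective above; `group_weight_exponent = 0.5` gives the conventional
$\sqrt{l_g}$ weighting, and `0` plain unweighted norms.

**Class association.** The printed per-example score
$\log(1 + e^{-y_i\, w_g \cdot x_{i,g}})$ *decreases* as a group fits its
class better, so associating a group with the class of *maximal*
summed score points at the class the group does not explain. The
default rule therefore uses the sign of the mean-activation difference
(positive-class groups activate positives more); the literal
max-of-sums rule is retained behind `method = "score"`, and the test
suite pins down that the two disagree in exactly this way.

**Empirical null and calibration.** For a positive-class group the
activations of the negative examples form the null. Because features
are *selected* for separating the two classes, in-sample membership
calls are anti-conservative under a global null: with no signal at all,
selection plus fitting manufactures groups whose in-sample activations
separate the classes. Calibration is therefore a held-out property:
fitting on one half of a null data set and calling membership on the
other half yields essentially no significant examples and no
motif-eligible group, which is what the acceptance checks assert. On
real data the pipeline reports in-sample calls — there the signal is
real — but predictions on new sequences inherit the calibrated
behavior.

**Hit localization.** The per-position score of a group is the summed
weight of its patterns matching at that start (either orientation);
the hit is the maximum-scoring position, leftmost on ties. Summing the
per-position scores over all positions reproduces the group activation
exactly, which the tests assert. The 50 bp export window is centered
on the matched k-mer's center and clipped at sequence bounds (clipped
records carry a `len=` tag).

**Multitask geometry.** The multitask model scores an example of task
$t$ with $(w_c + w_t) \cdot x$ and penalizes the task blocks with
multiplier $\alpha = 1.5$ and the common block with $\beta = 1$.
Per-task feature selection precedes the union; the common assignment
is clustered on all examples pooled, each task's on its own examples.
Two consequences of this geometry are worth knowing. First, signals
present in both tasks reliably load on the common block, and sending
$\beta \to \infty$ provably decouples the fit into independent
per-task fits at $\alpha$-scaled penalties (asserted numerically to
1e-3 relative). Second, a signal present in only one task but
*statistically inert* in the other — a motif planted in task-1
positives that simply never occurs in task 2 — satisfies the
optimality conditions inside the *common* block whenever its
other-task gradient is below $(\alpha - \beta)\lambda_2$: since the
task block is penalized more, nothing pushes an inert feature out of
$w_c$. Task-specific blocks capture a signal cleanly only when carrying
it in $w_c$ measurably hurts the other task. The acceptance suite
asserts the folklore expectation (private signal in the task block)
faithfully and documents that at $\alpha > \beta$ it is not the
optimum of this objective.

## The synthetic generator

`simulate_peak_sequences()` emulates the structure the classifier
assumes: negatives are order-1 Markov background (by default with the
C→G transition down-weighted four-fold, mimicking genomic CpG
depletion; uniform and custom transition matrices are available), and
positives are the same background with motif instances planted at
uniform positions away from the outer 5 bp, sampled column-wise from a
position probability matrix and reverse complemented with probability
one half. A truth table records every planted instance (sequence,
motif, 0-based start, strand), and the whole set is byte-reproducible
from its seed. `simulate_two_motif_set()` partitions 500 positives
60/40 between two exact-consensus motifs (AP-1-like `TGACTCAT`,
E-box-like `CACGTGAC` by default) so that every positive carries
exactly one signal; `simulate_two_task_set()` builds the two-task
variant with one shared and one task-1-only motif at 0.9 planting
fraction. `dinucleotide_shuffle()` provides composition-matched
negatives via an Altschul–Erickson Eulerian-walk shuffle that
preserves the exact dinucleotide multiset.

What the generator does *not* emulate: soft (PWM-noisy) instances are
supported but the benchmark plants exact consensus sites, so passing
recovery tests bounds performance on crisp motifs only; there are no
repeats, no GC heterogeneity beyond order-1 structure, no cooperative
spacing constraints, and no read-level artifacts (coverage, cut bias,
footprints). Real peak sets mix all of these, so test performance on
the fixtures is an upper bound, not a forecast.

## Numerical choices

The solver is FISTA — accelerated proximal gradient from a cold start
at zero — with backtracking line search from a spectral step estimate
($L = \lVert X \rVert_2^2 / 4$ by power iteration) and adaptive
restart whenever the objective would increase, run to a relative
objective change below `tol` (1e-7 by default; validation uses down to
1e-12). The proximal operator is the closed form: elementwise soft
threshold at $t\lambda_2$, then groupwise shrinkage by
$\max(0,\, 1 - t\lambda_1 l_g / \lVert u_g \rVert)$ — groups below the
threshold are *exactly* zero, so downstream code never needs an
epsilon. Logistic terms use the `log1p(exp(·))` stable form. Spearman
correlations use midranks; constant count columns get correlation 0
with a warning. Cross-validation breaks criterion ties toward the more
regularized pair.

## Validation scale

The checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` run at desk scale, chosen to finish in minutes
on one CPU: solver agreement with an independent SLSQP minimizer on 20
instances of n = 60, p = 30, 5 groups; 100 proximal-operator cases;
the two-motif benchmark at 500 + 500 sequences of 150 bp with
`n_top = 2000`, `G = 10`, a fixed mid-path penalty pair (2% of the
data-derived maximum on both axes) and an even train/test split; null
calibration at the same size; and the two-task study at 200 sequences
per class per task. Larger runs change runtimes, not the logic.

## Known limitations

- Group structure is hard and non-overlapping; a k-mer shared by two
  motifs must choose one group.
- The empirical null is exchangeability-based; covariate shifts
  between peaks and flanks (GC, repeats) that are not sequence-signal
  will register as discriminative structure.
- In-sample membership calls after feature selection are
  anti-conservative (see above); interpret them on data with real
  signal, or call on held-out sequences.
- The multitask objective at $\alpha > \beta$ does not force
  other-task-inert signals into the task blocks.
- Wildcard runs are single and contiguous; spaced dyad motifs with a
  gap longer than two need the gap absorbed by two features.
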