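---
title: "Pair co-occurrence models for amyloid hot-spot recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair co-occurrence models for amyloid hot-spot recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylopair)
```

## The problem

Short segments of 4–10 residues — "hot spots" — can confer amyloidogenic
behavior on an entire protein: once such a segment is solvent-exposed, it can
nucleate the densely packed zipper contacts of a fibril. Experimentally
labeled hot-spot peptides number only in the hundreds, so sequence-based
classifiers are the practical route to scanning candidate segments.

`amylopair` implements a classifier built on a simple structural intuition:
an amyloidogenic segment is characterized not just by position-specific
residue preferences but by *pairs* of residues that co-occur at fixed
relative positions (valine at position 2 entailing isoleucine at position 4,
say). The unit of modeling is therefore a position-specific residue-pair
co-occurrence matrix over a sliding window of fixed length $n$.

## The model

For a set of length-$n$ windows, the co-occurrence matrix counts, for every
unordered position pair $p < q$ and every residue pair $(a, b)$, how many
windows carry $a$ at $p$ and $b$ at $q$. Residues are indexed alphabetically
(A = 1, …, Y = 20), giving $\binom{n}{2} \times 400$ cells; the mirror cell
$(q, p, b, a)$ is redundant and not stored. Normalization divides by
`window_count` $\times \binom{n}{2}$ so the whole matrix sums to 1.

Two matrices are learned:

* **Negative matrix** (`matrix_no`): *every* sliding window of every
  negative training sequence contributes equally. The shifting window
  averages away any positional structure a negative set might carry.
* **Positive matrix** (`matrix_yes`): each positive sequence contributes
  exactly **one** window — the segment believed to carry the amyloidogenic
  pattern, whose location is unknown and must be discovered during training.

The discriminative quantity is the element-wise ratio
$\mathrm{yes}(c)\,/\,(\mathrm{no}(c) + \varepsilon)$ and the distance
$w$, the sum of those ratios over the positive-support cells
(`distance_w()`). Large $w$ means the positive mass sits where the negative
pattern is thin.

## Training: discovering one window per positive sequence

`fit_pair_model()` proceeds in two stages:

1. Initialize the positive matrix from **all** windows of all positive
   sequences (the same averaging used for negatives). This is deterministic,
   seed-free, and unbiased toward any offset.
2. Sweep the positive sequences in input order, reselecting for each the
   single window that maximizes the training distance, committing each
   choice immediately (sequential greedy coordinate ascent). Stop at a
   selection fixpoint or after `max_iterations` (default 100) sweeps.

The selection objective couples the two requirements a relevant segment must
satisfy: it should be *distant from the negative pattern* and *consistent
with the segments selected from the other positive sequences*. Formally the
training distance of a selection state is the mean classification-style
score of the selected windows against the positive matrix $X$ they
themselves induce,

$$ w \;=\; \binom{n}{2} \sum_c \frac{X(c)^2}{\mathrm{NO}(c)+\varepsilon}, $$

and substituting a candidate window for sequence $k$'s current choice
changes $w$ by a term proportional to
$\sum_{c \in \text{cells}} (2 S_{-k}(c) + 1) \, / \, (\mathrm{NO}(c) +
\varepsilon)$, where $S_{-k}$ counts how often the other selected windows
hit cell $c$. A purely linear distance
($\sum_c X / (\mathrm{NO} + \varepsilon)$) would make each sequence's choice
independent of all others and reward nothing but rarity against the negative
sample; the quadratic self-consistency term is what lets agreement between
positives accumulate and pull selections onto a shared motif. Because each
step maximizes $w$ over one coordinate and the incumbent window is always
among the candidates, $w$ is non-decreasing across sweeps; `w_trace` records
it per sweep and $w_d$ is its maximum (equal to the final value). Ties
between candidate windows are broken toward the smallest start. With
hexapeptide training data and $n = 6$ every sequence offers exactly one
window and training converges in a single sweep.

Greedy coordinate ascent finds a local optimum; with weak or conflicting
signal the fixpoint can depend on the order in which positives are visited.
With a coherent motif the optimum is unique in practice and the fit is
order-invariant (this is exercised in the test suite on synthetic data).
Positive or negative sequences shorter than $n$ cannot contribute a window
and are skipped with a warning.

### The smoothing mass $\varepsilon$

Cells unsupported by the finite negative sample would otherwise divide by
zero, so the denominator carries a pseudo-mass $\varepsilon$. Its *scale*
matters more than its existence: normalized negative cells average
$1/(400\binom{n}{2})$ ($2.5\times10^{-4}$ at $n = 5$), and an $\varepsilon$
far below that scale turns every sampling zero of the negative matrix into a
spike worth hundreds of genuine pattern cells — window selection and the
ratio pattern then lock onto noise. The default
($\varepsilon = 1/(400\binom{n}{2})$, used when `epsilon = NULL`) is the
mass a cell carries under i.i.d. uniform negatives: an unseen cell is scored
as if seen at the uniform background rate, which keeps it attractive but not
dominant. The parameter remains configurable for users who want sharper or
flatter smoothing; `ratio_matrix()` and `distance_w()` take an explicit
`epsilon` argument for direct matrix work.

## Classification

A test window's own singleton co-occurrence matrix contracted against the
model's ratio matrix reduces to the sum of the $\binom{n}{2}$ ratio cells
addressed by the window's residue pairs (`score_window()`). The score is
expressed as the fraction $w_s = \text{raw}/w_d$ of the maximal training
distance; in the fully concentrated limit (all positives selecting the same
word) the best training window scores exactly $w_s = 1$, so test scores
land on an interpretable $[0, \sim 1]$ scale (values above 1 are possible
and accepted).

A sequence is scanned window by window (`classify_sequence()`): it is called
positive when its best window *strictly exceeds* the threshold $w_l \in
[0, 1]$ (ties at the threshold are negative), and every residue inside at
least one above-threshold window is annotated `1`. The default
$w_l = 0.14$ corresponds to the working point used for full-protein
scanning; the bundled sup35 fragment set is reproduced exactly by any
threshold in the open interval $(0.12, 0.13)$, and the package deliberately
leaves $w_l$ a free parameter rather than hard-coding either value.

`extract_pattern()` reports the learned pairs: ratio cells rescaled to
$[0, 1]$ by the matrix maximum, listed at a cut-off (default 0.4). The
rescaling makes the cut-off scale-free; on raw ratios the same number would
mean entirely different things depending on $\varepsilon$ and the training
set size.

## Evaluation

`roc_curve()` sweeps the decision threshold over every distinct score,
yielding the exact step curve with $Sn$ non-increasing and $Sp$
non-decreasing, and integrates trapezoidally; the result equals the
tie-corrected Mann–Whitney pairwise concordance (asserted against a
brute-force oracle in the tests, and against `pROC` as an independent
implementation). `cross_validate()` runs repeated stratified $k$-fold
cross-validation — default 4 folds $\times$ 10 repeats = 40 trials — with
fold assignments drawn from a seeded generator, so results are reproducible
bit for bit. Stratification preserves the class ratio per fold; with
unbalanced hot-spot data, unstratified folds risk test folds without
positives. Mean ROC curves average sensitivity at 101 fixed specificity
grid points (linear interpolation); the "diagonal" operating point is the
sweep point minimizing $|Sn - Sp|$, summarized as $(Sn + Sp)/2$, with
median/0.85/0.95 quantiles over trials. `cross_test()` trains on one
dataset and tests on another, and its `swap_labels` probe (inverting the
test labels) measures whether a *negative* set carries its own
discriminative pattern — values near 0.5 mean it does not.

## The synthetic generator

`generate_synthetic()` produces the controlled benchmark the package is
validated on: negatives are i.i.d. uniform over the 20-letter alphabet;
each positive carries one planted window at a uniformly random admissible
offset in which motif pairs — by default Q–N at positions (1,2), Y–F at
(3,4) and N–Q at (2,5) of a 5-residue window — are realized with a given
probability (default 1, i.e. always). Defaults are 100 positives and 200
negatives of length 10. Ground-truth offsets are returned alongside, so
window-selection accuracy is directly measurable.

The generator emulates exactly the structure the model assumes: a single
contiguous pattern of pairwise correlations in an otherwise exchangeable
background. Real amyloid data violate most of this — residue usage is far
from uniform, negatives are biased collections rather than random peptides,
positives may carry several or partial hot spots, and labels themselves are
noisy. Passing the synthetic recovery and cross-validation checks therefore
demonstrates correctness of the machinery, not field performance;
performance claims on experimental data require the experimental datasets,
which the package reads (`read_labeled_csv()`) but does not bundle beyond
the published sup35 fragment table (`sup35_fixture()`).

## Numerical and design choices

* Windows shift by one position; all reported positions are 1-based
  inclusive.
* Strict sequence validation by default; a permissive mode NA-codes
  non-standard residues (B, J, O, U, X, Z) and drops affected windows with
  a warning — needed for real-world FASTA.
* Only the upper position triangle $p < q$ is stored; exports can mirror.
* Call rule is strict inequality ($w_s > w_l$).
* Tie-breaks in window selection go to the leftmost start; `which.max`
  semantics make this deterministic.
* Training stops at an exact selection fixpoint by default
  (`min_improvement = 0`); a positive tolerance stops on small $w$ gains.
* Degenerate inputs fail loudly: empty matrices, all-short sequence sets,
  single-class label vectors, and folds that cannot be stratified are
  errors, not silent results.
* Test-suite problem sizes are kept small by design: synthetic datasets of
  24–300 peptides, cross-validations of 4–12 trials, and oracle sweeps of
  200–500 random instances; the full 40-trial design runs in the
  acceptance script.

## Limitations

The classifier sees only pairwise, within-window structure: triplet
dependencies, gapped correlations beyond the window, and physicochemical
similarity between residues (an I/V substitution is as distant as I/P) are
outside the model. The greedy selection can settle into order-dependent
local optima on weak data. And since experimental hot-spot collections are
small and biased, cross-dataset transfer is the realistic measure of
generalization — single-dataset cross-validation flatters any method,
including this one.
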