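---
title: "Motif discovery from hierarchical sparse representations: models and methods"
author: "sparsemotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif discovery from hierarchical sparse representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

sparsemotif looks for conserved elements — primary binding sites, gapped
two-box sites, long repeat-like elements, and overlapping combinations of
these — in a set of unaligned DNA strings, typically ChIP-seq peak
sequences. It does so through a two-level convolutional sparse
representation.

**Level 1 (sequence level).** Each string is one-hot encoded as a 4×L
matrix $s_n$ and approximated as a sum of convolutions

$$ s_n \approx \sum_{m=1}^{M} d_m * x_{mn} + \tilde d_m * y_{mn}, $$

where every filter $d_m$, reshaped as a 4×ℓ matrix, is constrained to the
probability simplex column-wise — i.e. it is a position frequency matrix
(PFM) — and $\tilde d_m$ is its reverse complement, so the forward code
$x_{mn}$ and the reverse code $y_{mn}$ place sites on the two strands. The
codes are non-negative and ℓ1-penalized (weight $\lambda$): each non-zero
code entry is an indicator saying "filter $m$ explains the substring
starting here". The PFM constraint removes the usual scale ambiguity of
sparse coding and makes every filter directly interpretable as a motif
model. "Convolution" here is placement: the code indexes the
$P = L-\ell+1$ valid offsets and the filter is stamped, not flipped.

**Level 2 (image level).** The per-sequence codes, concatenated
horizontally (columns $1..M$ forward, $M{+}1..2M$ reverse), form a P×2M
*code image*. A second bank of K non-negative filters $F_k$ (h×2M pixels,
unit Frobenius norm, ℓ1-penalized with weight $\mu$) sparsely reconstructs
a scaled version of this image,

$$ \sum_k F_k * z_{kn} = \beta\,(X_n, Y_n), \qquad \|Z_n\|_0 \le \alpha, $$

with the image code $Z_n$ restricted to at most $\alpha$ non-zeros. The
scaling $T(M) = \beta M$ (default $\beta = 100$) keeps the image-level
quantities numerically comfortable: code entries are O(1) while image
filters have unit norm, so their natural product scale is O($\beta$).
Each non-zero of $Z_n$ is an image-level *component*: a recurring local
arrangement of sequence-filter activations — precisely the kind of object
that a gapped or composite motif produces.

# Fitting

## Alternating classical solver

`fitClassical()` alternates a per-sequence ADMM solve of the codes
(filters fixed) with joint filter updates (codes fixed):

* **Codes.** Non-negative ISTA sweeps update X and Y alternately
  (Jacobi across filters within a sweep); a projected gradient step with a
  hard top-$\alpha$ projection updates Z; scaled duals of the coupling
  constraint are then updated. The coupling enters the code step as
  $\rho\,(x - (L + \Gamma)/\beta)$ — the image-side quantities mapped back
  to code scale — which is exactly the textbook term at $\beta = 1$ and
  keeps the two half-problems balanced at $\beta = 100$. (The fully
  "consistent" augmented-Lagrangian form carries a $\beta^2$ factor on the
  code side, which makes the iterates unusable at any single penalty
  value; mapping back to code scale is the stable reading.)
* **PFM filters.** Mirror descent under the negative-entropy mirror map:
  every column is updated multiplicatively,
  $d \leftarrow d\,e^{-\pi g}$, renormalized to the simplex — a softmax-
  weighted step that keeps columns strictly stochastic. The gradient $g$
  includes the chain through the reverse-complement filters and is the
  per-sequence *mean* of the reconstruction gradient, so the step size
  $\pi$ is meaningful independently of dataset size.
* **Image filters.** A gradient step on the quadratic coupling term,
  non-negative soft-thresholding with $\mu\omega$, then Frobenius
  renormalization. A filter zeroed entirely by the threshold is redrawn
  at random (normalizing a zero matrix is undefined).

Two departures from a naive implementation matter in practice and are
deliberate:

1. **Dual resets across outer rounds.** While the filters are still
   moving, the image constraint cannot be satisfied; scaled duals that
   integrate this infeasibility across rounds grow linearly and crush the
   codes through the coupling term. `fitClassical()` therefore resets the
   duals at the start of every outer round while keeping the codes warm.
   Within a single ADMM call (and inside the unfolded forward pass, whose
   depth is fixed and small) duals accumulate normally.
2. **Fixed iteration budgets.** Convergence is by iteration count, not
   tolerance, mirroring the unfolded architecture; all budgets are
   configurable.

Default step sizes ($\eta = 0.02$, $\gamma = 0.1$, $\pi = 0.5$,
$\omega = 10^{-5}$, $\rho = 1$, $\lambda = 0.1$, $\mu = 0.01$) were chosen
by fixed-point scale matching: each phase's step multiplied by the natural
magnitude of its gradient should move its variable by a few percent per
iteration. They are serviceable defaults for the classical path; the
unfolded network treats all of them as trainable parameters.

## Deep unfolding

`netTrain()` parameterizes a *fixed number* of the same iterations as a
network: $2K_1$ code layers (ISTA sweeps interleaved with the Z-step and
dual step; codes and duals enter layer 1 as exact zeros) followed by
$2K_2$ filter layers (mirror step interleaved with the image-filter step
and its dual step). The trainable parameters are the filters, the
sparsity weights $\lambda, \mu$, the coupling penalty $\rho$, and one
$(\eta_t,\gamma_t)$ per code layer plus one $(\pi_t,\omega_t)$ per filter
layer. The loss is the mean two-term reconstruction error

$$ \frac1N \sum_n \Big[\; \big\|\textstyle\sum_m d_m^{K_2} * x_{mn}^{K_1}
   + \tilde d_m^{K_2} * y_{mn}^{K_1} - s_n\big\|^2
   + \big\|\textstyle\sum_k F_k^{K_2} * z_{kn}^{K_1}
   - \beta(X_n, Y_n)\big\|_F^2 \;\Big]. $$

Because the iterates are shared code, a forward pass with shared step
sizes is *tensor-identical* to the classical iterations — unfolding is a
parameterization, not a new algorithm — and the test suite asserts exact
equality.

No automatic differentiation framework is used: the reverse pass is
derived by hand, layer by layer, with the convolution adjoints expressed
through the same four primitives as the forward pass. Three
non-smooth points need conventions:

* the hard top-$\alpha$ projection passes gradients only through the kept
  entries (straight-through on the support);
* the soft-threshold passes gradients where its output is positive;
* a fully-zeroed image filter stays zero inside the differentiable
  forward (no random redraw mid-graph).

Positivity of all scalars is maintained by log-reparameterization.
Optimization uses minibatch AdaBelief (the variance-of-gradient variant
of Adam) with bias correction and $\epsilon = 10^{-12}$; after every step
the filter parameters are re-projected (Euclidean simplex projection per
PFM column; clipping plus Frobenius normalization per image filter, with
a fully-zeroed filter redrawn under the run's RNG). Batches are drawn
without grouping by length — every operation in the forward pass is
per-sequence, so mixed lengths pose no shape problem. Every gradient is
verified against central finite differences in the test suite (relative
error below $10^{-3}$).

**Parameter count.** Problem formulation has a *single* coupling
constraint, $\sum_k F_k * z_{kn} = T(X_n, Y_n)$; the two penalty symbols
that appear in the code-phase and filter-phase derivations are penalties
on that same constraint in the two half-problems. The network therefore
ties them and trains one penalty scalar. The count is
$4 M \ell + 2 M h K + 3 + 2K_1 + 2K_2$; at the reference configuration
($M{=}50$, $\ell{=}8$, $K{=}24$, $h{=}12$, $K_1{=}6$, $K_2{=}3$) this is
30,400 filter weights + 3 scalars + 18 step sizes = **30,421** trainable
parameters. Counting the two penalties separately would give 30,422.

# Enumerating at the image level

After fitting, `inferCodes()` produces an image code per sequence and
`buildMotifTable()` enumerates all $\binom{\mathrm{nnz}}{q}$ subsets of
$q$ components per sequence (default $q = 3$; at $\alpha = 32$ that is at
most 4,960 per sequence). A component at image row $p$ covers nucleotides
$[p, p+h+\ell-2]$. Each subset, sorted by position, is keyed by its
filter indices and the $q-1$ *coverage gaps* between consecutive
components; overlapping components give negative gaps and are perfectly
valid keys (overlapping motifs are a real phenomenon). Because the key
fixes the gaps, every placement of a key covers the same number of
nucleotides, so the placements collected under one key form an MSA. Keys
are ranked by bucket occupancy; a bucket must hold at least two
placements to become a candidate (an MSA of one substring defines no
alignment), and up to J = 1000 candidates are taken.

The distance convention (coverage gaps rather than start-to-start
offsets) is internal: keys produced under one convention are not
comparable to keys produced under another.

# From MSAs to scored motifs

* **Merging.** Candidates are walked in rank order; each is aligned
  against every retained motif over all gapless offsets and both strands,
  scored by the mean column ALLR (average log-likelihood ratio, the
  standard column-similarity statistic) over an overlap of at least
  `max(6, ceiling(w/2))` columns. The best alignment above 0 bits merges
  the candidate's aligned counts into the retained motif; MSA rows are
  conserved. Merged motifs are then trimmed to their conserved core:
  edge columns with information content below 0.25 bits are removed,
  while internal low-information columns — the spacers of gapped motifs —
  are kept.
* **Site refinement.** Each merged-and-trimmed motif is re-estimated
  once from its own hit sites in the *training* records: the PWM is
  scanned, hit windows are extracted (reverse-complemented when the
  minus strand scores better) and the count matrix is rebuilt from them.
  This single pass de-noises PWMs assembled from heterogeneous buckets —
  the same site-re-estimation idea classic discovery tools iterate — and
  never touches the held-out test set, so the significance test below
  remains honest.
* **Score thresholds.** Each motif's log2-odds PWM (pseudocount 1,
  distributed by the background; uniform background by default) gets a
  score threshold calibrated by exact dynamic programming over scores
  discretized at $10^{-3}$: the smallest achievable score whose upper
  tail probability under the background is at most the target p-value.
  Because every position is scanned on both strands, the pipeline
  calibrates each strand's threshold at half the scan p-value, so the
  per-position two-strand background hit rate matches the nominal
  $10^{-3}$ (a Bonferroni correction over the two strand tests).
  Negligible lower-tail mass (below $10^{-12}$ of the target) is lumped
  during the DP; the upper tail is exact to that tolerance.
* **Hits and significance.** Scanning slides the PWM over every position
  of every record on both strands (reverse strand via the
  reverse-complemented PWM on the forward text); a position counts once,
  windows containing N never hit. On the held-out test set (15 % of
  records, never used in fitting), hits $\tau_h$ out of
  $N_T = \sum_t L_t$ positions are contrasted with hits $c_h$ in a
  control set built by an exact dinucleotide-preserving shuffle of the
  same records (Euler-tour construction: identical 2-mer multiset,
  identical first and last base). A two-sided Fisher exact test on the
  2×2 table yields the p-value; the sample odds ratio
  $(\tau_h/\tau_m)/(c_h/c_m)$ is reported, and a degenerate margin
  reports an NA odds ratio with p = 1. Motifs are reported most
  significant first, flagged at p < $10^{-6}$; instance counts are hits
  over the full dataset.

Note that $N_T$ counts *all* positions, not only valid window starts —
the convention is deliberate and consistent between test and control, so
the contrast is unaffected.

# Synthetic data

The generator in `sampleBackground()` / `plantMotifs()` emulates exactly
the statistical structure the method assumes: i.i.d.-uniform or
first-order-Markov background with sparse, localized conserved sites.
Three planting modes cover the motif classes of interest: `primary`
(sites of one PFM), `gapped` (two or more boxes joined by a
random-content spacer of specified length range), and `embedded` (a
primary site inside a fixed flanking element, emulating a binding site
embedded in a repeat). Inserts are optionally reverse-complemented with a
configurable probability, are written at uniform random offsets (at most
one per record, so ground truth is unambiguous), and every plant is
recorded in a 1-based closed-coordinate truth table.

What the generator does *not* emulate — and therefore what passing
recovery tests cannot show — includes ChIP-seq peak-shape positional
bias, genomic repeat families with their own internal structure,
composition heterogeneity across records, and sequencing artifacts. The
null-control tests use the same generator without plants.

# Problem sizes and validation choices

The packaged tests exercise the method at CPU-friendly sizes chosen as
this package's own validation design: parameter-recovery runs use 300
sequences of 120 nt with an 8-nt planted PFM at 80 % occurrence, run
under the desk profile; gapped recovery plants two 6-nt boxes with a
fixed 5-nt spacer; null controls run the identical pipeline on pure
background (50 sequences of 80 nt, candidate cap 400) over ten seeds —
roughly a hundred scored motifs per run, so the ten runs jointly give the
1e-6 significance gate on the order of a thousand chances to produce a
false positive. The desk profile is M = 8 sequence filters,
K = 6 image filters of height h = 6, with all statistical settings (
$\alpha$, $\beta$, q, scan p-value, significance gate, J) at their
reference values. M = 8/K = 6 rather than a larger bank is a deliberate
choice: at a few hundred training sequences, more filters split the code
mass of a single planted motif across near-duplicate filters and the
image-level keys stop recurring; a smaller bank concentrates them. At
the reference scale (tens of thousands of sequences) the full
M = 50/K = 24 configuration is the intended setting.

# Known limitations

* The classical fitter's fixed step sizes are scale-matched for one-hot
  data with the default $\beta$; radically different $\beta$ values need
  retuned $\gamma$/$\omega$.
* Recovery of *which* filter learns a motif is seed-dependent; the
  pipeline's output is robust to this because the hash table aligns
  recurring arrangements regardless of which filters carry them, but
  filter-level PFM recovery (as opposed to reported-motif recovery) can
  require a favorable seed at desk scale.
* The threshold DP assumes a zeroth-order background; higher-order
  backgrounds enter only through the shuffled controls.
* Training the unfolded network in pure R costs roughly a second per
  minibatch at desk scale — fine for hundreds of sequences, not for the
  reference-scale corpora, which the architecture supports but this
  implementation does not target.
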