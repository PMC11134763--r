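---
title: "Predicting structural similarity of MS/MS spectra from mass-difference matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting structural similarity of MS/MS spectra from mass-difference matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spectral library search assigns a structure (or a structural analogue) to
an unknown tandem mass spectrum by ranking reference spectra by
similarity. Classical scores such as the cosine and modified cosine count
identical fragment (or neutral-loss) matches, which works poorly for
analogues: a single functional-group change shifts many product ions by a
characteristic mass delta, so two structurally near-identical compounds
can share almost no identical peaks. `ms2sim` implements a supervised
similarity metric that instead looks at the *mass differences* between
every query and reference fragment pair, learns which difference patterns
indicate structural relatedness, and returns a score that estimates the
Tanimoto structural similarity of the underlying compounds. A post-hoc
relevance analysis maps a predicted score back to the fragment pairs that
drove it.

## Encoding a spectrum pair

Spectra are preprocessed on a 2-decimal m/z grid: m/z rounded to 2 dp
(equal-m/z peaks merged keeping the larger intensity), intensities
rescaled to percent of the base peak, peaks below 0.1% or outside
10-1000 Da removed, and a 3-Da sliding-window denoising that keeps only
the locally highest peak. The window rule is implemented as greedy
non-maximum suppression with radius 1.5 Da (descending intensity, ties to
the lower m/z): it is deterministic, order-independent, and removes
isotope/noise satellites around dominant peaks. Because the m/z filter
can remove the base peak, intensities are rescaled once more at the end
so the output base peak is exactly 100%; the pipeline is idempotent.

For a query spectrum with $s_q$ fragments and a reference with $s_r$
fragments, the *mass difference matrix* (MDM) is the $s_q \times s_r$
grid of absolute m/z differences (2 dp). The MDM is re-indexed into an
*aligned matrix*: each difference $d < 300$ Da is split into its nominal
mass $c = \lfloor d \rfloor$ and mass defect token
$\mathrm{round}(100(d - c)) \in \{0, \dots, 99\}$, and the token is
placed in column $c$ of the fragment's row. Columns with no difference
hold a PAD token; a CLS row is prepended as the aggregation entry. When
two reference fragments produce the same nominal mass for one query
fragment, the more intense reference fragment wins (ties to the smaller
m/z) - the most informative ion is kept, deterministically. All
arithmetic runs on integer hundredths of a Da, so the nominal/defect
split is exact.

The same construction is applied to the hypothetical neutral-loss
spectra (precursor m/z minus fragment m/z; non-positive losses dropped),
giving each pair two aligned matrices: one for the fragment tower and
one for the neutral-loss tower. Intensity enters the encoding only
through preprocessing and collision tie-breaking; the matrices
themselves are intensity-free by design.

## The model

Each tower maps its aligned matrix to a single embedding:

1. **Row encoder.** Tokens are embedded in 32 dimensions and each row's
   $300 \times 32$ block is flattened to 9600 features. Two
   head-splitting blocks follow (100 heads of 96 features, then 20 heads
   of 640), each applying dropout, a shared affine map to 128 dimensions
   and a ReLU per head; a final affine map projects the re-flattened row
   to a 128-dimensional row embedding. Head weights are shared within a
   block (a local filter over head positions); per-head output width 128
   follows the configured hidden dimension.
2. **Transformer encoder.** Two standard post-norm encoder layers
   (4 heads, feed-forward width 256, dropout 0.1) over the rows, with
   *no positional encoding*: fragments are an unordered set, which makes
   the score provably invariant to peak permutations. The CLS-row output
   is the tower embedding.

The two tower embeddings (fragment and neutral loss; independent
parameters) are concatenated and a two-layer fully connected head with a
sigmoid produces $y_{sim} \in [0, 1]$. The sigmoid was chosen because
the training label (Tanimoto similarity) lives in $[0, 1]$; the
reference description leaves the output activation open. ReLU is the
single nonlinearity used throughout.

Defaults (see `model_config()`): embedding 32, blocks 2 with 100/20
heads, hidden dimension 128, transformer 2 layers / 4 heads / FFN 256,
dropout 0.1, learning rate 1e-4, weight decay 0, batch size 64.

### Implementation notes

The network and its gradients are implemented on a small reverse-mode
matrix autodiff tape (`R/autodiff.R`); every operator is tested against
finite differences or a dense reference implementation. The first
row-encoder block is computed in a fused form: because its affine map
only ever sees embeddings of the 102 vocabulary tokens, the product
`embedding %*% W` is precomputed per position slot, and all-PAD /
all-CLS cells (the vast majority) reduce to batch constants. This is
bit-identical to the naive embed-flatten-split pipeline and an order of
magnitude faster in R. Dropout inside block 1 acts element-wise on the
embedded features of real mass-defect tokens; PAD/CLS filler embeddings
are never dropped (they carry no pair information). Later blocks drop
whole input units. Attention over variable-length row stacks is computed
densely with an additive block mask; batches never mix rows across
pairs.

## Training

Labels are Tanimoto similarities on path-based fingerprints. For real
structures the package uses Open Babel FP2 fingerprints (1024-bit,
linear fragments up to 7 atoms) via ChemmineOB as the Daylight-style
stand-in; `tanimoto()` itself is fingerprint-agnostic. Because all-pairs
training sets are enormous and skewed towards low similarity, each epoch
resamples a balanced pair list: similarity is binned into $B = 10$
equal-width bins over $[0, 1]$ and every spectrum is paired with one
uniformly drawn partner per occupied bin (`sample_epoch_pairs()`,
deterministic per epoch seed). Training minimises the mean squared error
between $y_{sim}$ and the label with Adam (lr 1e-4, weight decay 0,
batch 64); MSE matches the squared-error-based evaluation. Epoch count
and early stopping are not fixed by the reference description; the
package defaults to patience-based early stopping on the MSE of a fixed
validation pair set, returning the best-validation parameters. A sampled
pair is used once per epoch with the first spectrum in the query role;
`train_config(symmetrize = TRUE)` adds the swapped roles.

Test pairs mirror the evaluation protocol: each test spectrum is paired
with at most $k = 3$ reference partners per similarity bin
(`make_test_pairs()`), and test/reference sets must be structure-disjoint
(an information-leakage guard enforces this, as does the training-time
validation guard).

## Post-hoc explanation

The explanation estimates how much each (query fragment, reference
fragment) pair contributed to the score. The propagation rule is
gradient-weighted attention relevance in the Deep Taylor style: per
encoder layer, the head-averaged, positively clamped elementwise product
of the attention map with its gradient (plus identity for the residual
path, rows renormalised) is composed across layers; the CLS row of the
composition gives each data row's relevance. Row relevance is spread
over the row's non-PAD cells proportionally to the L2 norm of the
score's gradient at each cell's embedded input, and each cell maps to
the reference fragment recorded in its provenance. Fragment-tower cells
map directly to fragment pairs; loss-tower cells map through the
loss-to-fragment correspondence. The two tower contributions are
weighted by each tower's share of positive gradient-times-input mass at
the fusion head and summed; the result is nonnegative and normalised to
total 1. Within this scheme relevance is conserved layer-to-layer: the
composed propagation matrix is row-stochastic (asserted in the test
suite), so clamping redistributes rather than creates relevance.

`top_associations()` reports, for the $q = 20$ query ions with the
largest total relevance (ties to the higher m/z), the $k = 3$ most
relevant reference ions each (ties to the smaller absolute shift, then
the smaller m/z) with signed shifts `reference m/z - query m/z`;
`render_heatmap()` writes the heatmap and a TSV twin. Explanations are
meaningful for pairs predicted highly similar; the CLI warns below 0.6.
The exact propagation variant used by the original description is not
recoverable from it; every step here is documented so alternative rules
can be slotted in.

## The synthetic study system

Real training corpora (public spectral libraries with tens of
thousands of structure-annotated spectra) need downloads and days of
GPU time, so the package ships a generator whose ground truth is exact.
A molecule is an ordered chain of 5-9 moieties drawn from a
residue-mass alphabet (57-147 Da); an analog family shares a scaffold
chain and derives members by 1-3 substitutions - swapping a moiety or
applying a realistic modification delta (+15.99 O, +14.02 CH2, +18.01
H2O, +2.01) - or by an adjacent transposition (same moiety multiset,
reshuffled chain). A spectrum is the chain's prefix-sum fragment series
plus protonated precursor, with log-normal intensity noise
(`intensity_cv = 0.3`), 5% fragment dropout and on average 0.5 spurious
peaks. Ground-truth structural similarity is the multiset Jaccard of
moiety masses.

This construction makes the learning task well-posed in the same way the
real task is: a single internal edit leaves prefix fragments matching
exactly and shifts all later fragments by one constant delta, while the
neutral-loss tower sees the complementary pattern (suffix losses match),
so exact-match and shifted-match evidence across the two towers
identifies the edit count regardless of edit position - precisely the
structure the two-tower design exploits. What the generator does *not*
emulate: real fragmentation chemistry (rearrangements, multiple
cleavages), isotope envelopes, adduct diversity, instrument-dependent
intensity patterns, and fingerprint-based labels (moiety Jaccard stands
in for Tanimoto). Passing the recovery experiment therefore shows that
the architecture, encoding, training loop and explanation are correctly
wired and can extract mass-difference structure from data - not that the
desk-scale model matches published performance on real libraries.

### Problem sizes

The packaged recovery experiment trains the full default architecture on
a 200-molecule library (seed 0; 140/30/30 molecules in train/validation/
test), at most 24 epochs of ~950 balanced pairs with early stopping on a
fixed validation pair set evaluated every second epoch, and evaluates on
structure-disjoint test pairs (at most 3 per bin per test spectrum).
These sizes were chosen as the smallest library on which family
structure is rich enough for all ten similarity bins to be populated and
the experiment completes comfortably on one CPU.

## Evaluation battery

`evaluate_pairs()` reproduces the standard read-outs: precision-recall
curves at Tanimoto cut-offs 0.6-0.9 (score threshold swept over all
observed scores; precision defined as 1 when nothing is predicted
positive), squared-error distribution per similarity bin (empty bins are
reported absent, not zero) and the Pearson correlation between scores
and labels (0 with a warning under zero variance). `cosine_score()`
provides the classical plain/modified cosine baselines (0.02 Da
tolerance on the 2-dp grid, greedy intensity-product matching);
`network_edges()` exports molecular-network edges (symmetrised scores,
threshold 0.6, mutual top-k 10, families capped at 100 nodes by
weakest-edge removal - topology parameters follow common molecular
networking practice and are configuration-exposed).

## Numerical choices and degenerate inputs

* All m/z arithmetic in integer hundredths; no float drift in the
  nominal/defect split.
* An all-PAD data row (every difference >= 300 Da) is legal and yields a
  finite embedding and score.
* A constant predictor gets Pearson r = 0 (with a warning) rather than
  NA; a zero relevance matrix yields a deterministic report ordering.
* Ties are broken deterministically everywhere (documented per
  function), so rankings, edge lists and reports are reproducible.
* Seeds: the generator, pair samplers and training are deterministic
  given their seed arguments; model initialisation is fixed by
  `model_config(seed = )`.

## Known limitations

* The desk-scale recovery experiment does not speak to performance on
  real spectral libraries; results reported for models trained on
  library-scale corpora are not reproducible in this setting.
* The fused row encoder assumes the packaged vocabulary layout
  (0-99 defect, PAD 100, CLS 101).
* Greedy cosine matching is the classical algorithm but is not an
  optimal assignment in rare overlap patterns.
* FP2 fingerprints are a 1024-bit stand-in for proprietary Daylight
  fingerprints; absolute Tanimoto values differ between fingerprint
  families.
* Checkpoints are R serialisations; they are portable across platforms
  but not across incompatible configurations (a fingerprint check
  refuses those).
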