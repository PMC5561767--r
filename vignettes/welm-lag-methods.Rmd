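---
title: "Predicting self-interacting proteins with WELM on LAG features: models and methods"
author: "sipwelm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting self-interacting proteins with WELM on LAG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipwelm)
```

## The problem

A self-interacting protein (SIP) is one whose copies bind each other,
forming homodimers and higher homo-oligomers. Self-interaction matters for
enzyme activation, signalling and regulatory function, but experimental
detection is incomplete, and pairwise protein–protein-interaction predictors
do not transfer: their features are built around *pairs* of distinct
partners, and their training sets exclude same-protein pairs. `sipwelm`
implements a sequence-only SIP predictor with three stages:

1. **Evolutionary profile.** Each protein is represented by its
   position-specific scoring matrix (PSSM), the `L × 20` profile PSI-BLAST
   produces by iteratively searching a sequence database (the reference
   protocol: e-value 0.001, 3 iterations). Entry `P[i, j]` scores residue
   `j` at position `i`; conserved positions score high. The package
   consumes PSI-BLAST's `-out_ascii_pssm` files — it never runs BLAST
   itself, but documents the command:
   `psiblast -query protein.fasta -db swissprot -num_iterations 3
   -evalue 0.001 -out_ascii_pssm protein.pssm`.
2. **Fixed-length features.** PSSMs have variable length `L`, classifiers
   need fixed dimension. The Local Average Group (LAG) transform splits the
   `L` positions into 20 contiguous groups of roughly 5% of the sequence
   each and averages every PSSM column within every group: 20 groups × 20
   residue columns = a 400-dimensional vector regardless of `L`. The
   rationale is that residue-conservation structure and domain locations
   scale with sequence length within a family, so fractional position is
   the meaningful coordinate. PCA optionally reduces 400 to 300 dimensions
   to suppress noise.
3. **Weighted extreme learning machine (WELM).** A single-hidden-layer
   network whose hidden parameters are random and fixed; only the output
   weights are learned, in closed form, by weighted ridge regression. The
   per-sample weights counter the heavy class imbalance of SIP data (e.g.
   710 SIPs against 5511 non-SIPs in the curated yeast set, about 1:7.8).

## The LAG transform in detail

For a PSSM with length `L ≥ 20`, group boundaries are
`b_g = floor(g·L/20)`, `g = 0..20`, and group `g` covers positions
`b_{g-1}+1 .. b_g`. Feature `(g-1)·20 + j` is the mean of column `j` over
group `g`. When `20 | L` this is exactly the `(20/L)·Σ` normalisation of
the defining formula; for other lengths the per-group arithmetic mean is
its natural extension (groups differ by at most one position). Sequences
shorter than 20 cannot fill 20 groups and are rejected; shorter than 50
trigger a warning, since the curated datasets exclude them.

```{r lag}
p <- generate_synthetic_pssm(L = 137, noise_sd = 3, seed = 1)
v <- lag_transform(p, warn_short = FALSE)
length(v)
```

## The classifier

Targets are `+1` (SIP) and `-1`. With hidden output matrix
`H[i, l] = act(w_l·x_i + b_l)` (input weights uniform on `[-1, 1]`, biases
uniform on `[0, 1]`, seeded), weight matrix `W = diag(w)` and
regularisation `C`, the output weights solve the weighted ridge problem in
either of two algebraically identical closed forms:

* `β = H'(I/C + W H H')⁻¹ W y` — an `n × n` inversion, preferred when
  `n ≤ L_hidden`;
* `β = (I/C + H' W H)⁻¹ H' W y` — an `L × L` inversion otherwise.

`solver_form = "auto"` picks the smaller system. With unit weights both
reduce to the classical unweighted ELM solution. The kernel form replaces
`H H'` with any kernel matrix `Ω`; its coefficients are
`α = (I/C + W Ω)⁻¹ W y` and a new sample scores `k(x, X_train)·α`. With a
linear kernel (or the explicit random feature map used as a kernel) the
kernel and explicit routes coincide, which the test suite exploits as a
cross-check. Predictions are `sign(score)` with the tie at exactly 0
mapped to `+1` (a fixed, documented convention).

### Weighting schemes

The weighting literature behind WELM defines two standard schemes, and the
package implements both:

* `W1`: sample weight `1/n_class` — both classes contribute equally to the
  weighted least-squares loss;
* `W2`: `1/n_minority` for the minority, `0.618/n_majority` for the
  majority — the golden-ratio variant pushes the decision boundary further
  into the majority class.

`W1` is the default. On imbalanced data an unweighted ELM buys accuracy by
sacrificing minority sensitivity; weighting recentres the boundary, raising
sensitivity and the Sn·Sp geometric mean. The acceptance checks quantify
this on synthetic 1:7.8 Gaussian data over 20 seeds.

### Reference profile and tunable parameters

The reference configuration (`welm_default_config()`) is the grid-search
optimum of the original SIP experiments: `tribas` activation
(`max(0, 1-|z|)`), `L_hidden = 5000` hidden neurons, `C = 100`. Parameters
that matter in practice:

| parameter | default | meaning |
|---|---|---|
| `L_hidden` | 5000 | random-feature count; more features = lower variance, more compute (`O(n L²)` or `O(L n²)` solve) |
| `C` | 100 | inverse regularisation; `I/C` is added to the Gram diagonal. Large `C` interpolates, small `C` shrinks `β` to 0 |
| `scheme` | `W1` | class weighting (above) |
| `activation` | `tribas` | any of tribas, sigmoid, sin, hardlim, radbas |
| `pca_dim` | 300 | PCA output dimension; `NULL` skips PCA |

### Input normalisation

Bounded activations respond only in a narrow pre-activation window —
`tribas` is identically zero outside `|z| < 1`. With uniform `[-1, 1]`
input weights in `d ≈ 300` dimensions, raw PCA scores produce `z` with a
standard deviation in the tens, leaving almost every hidden unit dead and
the fit degenerate. `welm_train(normalize = "minmax")` (the default, and
the classical ELM-toolbox convention) therefore rescales each training
feature to `[-1, 1]`, maps near-constant features to 0, and applies one
global scale to unit mean row norm, placing `z` near the responsive range.
The transform is stored in the model and replayed at prediction;
`normalize = "none"` exposes the bare closed forms, which is what all
algebraic equivalence tests use.

The near-constant guard matters: PCA on `n < d` samples yields trailing
components with numerically zero training variance, and out-of-sample
projections onto those null directions are arbitrary — unguarded min–max
scaling would amplify them without bound. `pca_fit` additionally clamps
the number of components to the realized rank (`sdev > 1e-8 · sdev[1]`),
with a warning.

## Evaluation protocol

`confusion_counts`/`compute_metrics` implement accuracy, sensitivity
`TP/(TP+FN)`, specificity, precision and the Matthews correlation
coefficient; a zero denominator reports the metric as 0 with an explicit
flag rather than `NaN` or an error. ROC curves and AUC come from a
threshold sweep with trapezoidal integration, which equals the
Mann–Whitney pairwise statistic (ties count one half); the tests verify
that identity exactly. The data protocol mirrors the reference study:
a stratified 1/6 holdout (`holdout_split`) and stratified five-fold
cross-validation (`five_fold_cv`) reporting per-fold metrics with mean and
population standard deviation. Stratification is a package choice (the
original protocol does not say); `stratified = FALSE` restores plain
random splits. Likewise, whether PCA was originally fitted per fold or
once globally is unstated: the leakage-free per-fold fit is the default
(`pca_scope = "train"`), with `"all"` available to reproduce the other
reading.

## Synthetic benchmarks: what they emulate and what they do not

Because the curated SIP datasets require external databases plus a
PSI-BLAST run, the package ships a generator whose output exercises every
pipeline stage without downloads. A synthetic PSSM has i.i.d.
`Normal(base_mean, noise_sd)` entries rounded to integers (mimicking
log-odds files); positives receive a mean shift `delta` on a chosen set of
PSSM *columns*, so the signal must survive the LAG transform to be
learnable. The committed study conditions:

* imbalance 30:234 = 1:7.8, the yeast ratio at test scale;
* lengths uniform on 50–200 (the curated sets keep 50–5000; the upper end
  is truncated for speed);
* `base_mean = 0`, since log-odds scores are roughly zero-centred;
* separable condition: `delta = 8`, `noise_sd = 1`, columns 1–6 — a strong
  conservation signature that a correct pipeline must classify nearly
  perfectly (5-fold CV accuracy > 0.95);
* null condition: `delta = 0`, `noise_sd = 4` — no signal, so performance
  must be chance-level;
* moderate condition (`delta = 1.5`, `noise_sd = 4`) for overlap regimes.

Chance level needs care on imbalanced data. An unweighted classifier on
null data overfits noise into a few percent of false positives, so its
accuracy sits slightly *below* the majority rate — that is classifier
variance, not sampling error. The meaningful null checks are therefore
(i) out-of-fold AUC within its null sampling band (Hanley–McNeil standard
error at AUC 0.5 with 30/234 samples is ≈ 0.054) and (ii) accuracy not
*exceeding* the majority rate beyond binomial error — a no-signal pipeline
can only lose accuracy, never gain it. The `W1`-weighted model on null
data deliberately trades accuracy for balance and lands well below the
majority rate; the null check therefore uses `scheme = "none"`.

What the generator does not emulate: phylogenetic correlation between
positions, gap structure, composition bias, or any real evolutionary
model. Passing the synthetic benchmarks demonstrates that the pipeline's
machinery is correct and sensitive to column-space signal; it does not
certify accuracy on real proteomes, which depends on PSI-BLAST profiles
against a real database.

## Numerical choices

* Ridge systems are solved with dense `solve()`; `I/C` makes them
  well-conditioned for any finite `C > 0`.
* PCA component signs are fixed (largest-magnitude loading positive) so
  fits are deterministic.
* All randomness flows through explicit integer seeds via isolated RNG
  streams; the caller's RNG state is never touched. Cross-validation
  offsets the model seed by the fold index so folds draw distinct hidden
  layers reproducibly.
* Feature CSVs and archived training scores are written with 17
  significant digits, so a saved model's predictions reproduce training
  scores bit-for-bit after the text round-trip.
* Test-suite and benchmark problem sizes (`L_hidden ≤ 1000`, `n ≤ ~530`)
  were chosen to keep the whole suite under half a minute while leaving
  every property measurable; the reference profile's dimensions are
  verified structurally.

## Known limitations

* PSSM quality is inherited from PSI-BLAST; the single-sequence
  `compute_pseudo_pssm` fallback (each row is the Dayhoff/PAM250 row of
  the observed residue) carries no alignment information and should be
  treated as a smoke-test profile, not a substitute.
* Binary classification only; no multi-class WELM, no online updates.
* The `L × L` or `n × n` dense solves cap practical sizes around a few
  thousand hidden neurons or samples per fold on one CPU.
* The worked confusion-table example in the test suite uses the
  recomputed MCC (0.6641) from its own counts.
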