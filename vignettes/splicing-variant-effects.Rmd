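---
title: "Modular prediction of variant effects on splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular prediction of variant effects on splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceshift)
```

## The modelling idea

Splicing outcomes — whether an exon is included, which of two competing
splice sites is used, how efficiently an intron is removed — are driven by
sequence elements in a handful of well-defined regions: the donor and
acceptor sites themselves, the exon body, and the adjacent intron ends.
`spliceshift` follows a modular strategy: train one small network per
region on data that directly measures that region's contribution, freeze
them, and let a low-dimensional interpretable model combine their score
*changes* into variant-effect predictions. The division of labour matters:
the modules absorb the hard sequence-to-function mapping where large
training sets exist (annotated splice sites, reporter libraries of random
sequences), while each downstream task needs only a nine-parameter fit and
therefore very little task-specific data.

Every candidate exon is carried around as a `RegionSequence`: the exon plus
`L_a` intronic nucleotides on the acceptor side and `L_d` on the donor side
(defaults 100/100), always in transcript 5′→3′ orientation. Minus-strand
handling is confined to region extraction; no module or composition model
ever sees strand.

## The six scoring modules

| module | input | architecture |
|---|---|---|
| donor | 18 nt: last 5 exonic + first 13 intronic | MLP, 2 ReLU hidden layers (64, 32), batch-norm + dropout 0.2, sigmoid head |
| acceptor | 53 nt: last 50 intronic + first 3 exonic | conv 32×15 (valid) → conv 32×1 with batch-norm + dropout 0.2 → dense, sigmoid head |
| exon 5′ / exon 3′ | exon, any length | shared conv 128×15 (same padding) → ReLU → global average pooling → per-head dense |
| intron 5′ / intron 3′ | flank, any length | as exon modules but 256 filters |

A module's score is the **pre-activation** output of its network;
`sigmoid(score)` is the corresponding probability or Ψ estimate. The exon
(and intron) networks are trained with two heads on paired labels
emulating the two arms of a reporter experiment — alternative-5′ and
alternative-3′ usage of the same random insert — and split afterwards
(`split_heads()`); the two resulting modules share identical convolution
weights by construction. Global average pooling is what makes these modules
length-free, which the variant machinery relies on (indels change exon
length).

All modules train with the fractional-label binary cross-entropy
`-(ψ log ψ̂ + (1-ψ) log(1-ψ̂))` — valid both for 0/1 splice-site classes and
for continuous Ψ targets — using Adam (learning rate 1e-3, batch 64, at most
100 epochs, early stopping patience 5), an 80/20 train/validation split, and
selection of the epoch with the smallest validation loss. Training, like
every generator in the package, is a pure function of its seed. The layer
framework (dense, 1-D convolution, batch normalization, dropout, global
average pooling, Adam, analytic backpropagation) is implemented in the
package on base-R matrix operations; its gradients are verified against
finite differences in development and its behaviour pinned by the training
tests. Hyperparameter search is a seeded random search over a discrete
space with the same selection criterion (minimum validation loss).

Where the architecture was under-determined, the package commits to:
hidden sizes (64, 32) for the donor MLP (configurable; the parameter count
is recorded on the module); dense→batch-norm→ReLU→dropout ordering;
valid padding for the acceptor convolutions but same padding for the
exon/intron convolution so 15-wide filters work on short exons. Exons
shorter than the 5-nt/3-nt exonic sub-windows are N-padded rather than
rejected, so very short reporter-style exons remain scorable; `N` encodes
as an all-zero one-hot row (a zero row contributes nothing through
convolution, which is the least-informative choice; an alternative would be
¼ in every column).

## Variant processing

A variant is paired with an exon when its REF interval intersects the exon
extended by `L_a`/`L_d` (an insertion occupies its single anchor base —
this makes the rule unambiguous for indels). One variant can pair with
several exons; each pair is scored independently against the pristine
reference, and overlapping variants are never combined. For alternative
sequences:

* SNVs substitute in place.
* Insertions and deletions away from splice sites stretch or shrink the
  segment they fall in; flanks are then re-extracted so the alternative
  region again has exactly `L_a` and `L_d` intronic nucleotides.
* A deletion overlapping a splice site removes the deleted span and
  relocates the splice site to the deletion boundary: the exon then ends at
  the deletion's 5′ edge, and the donor-side flank starts at its 3′ edge.
* A deletion that removes the entire exon is an explicit error — there is
  nothing left to score.
* Insertions exactly at a boundary are assigned by their anchor base, in
  transcript orientation: at or upstream of the acceptor they are intronic,
  strictly inside the exon (including its last base) exonic. Complex
  substitutions spanning a splice site (multi-nucleotide replacements that
  both delete across the boundary and insert new sequence) are rejected
  rather than guessed at.

REF alleles are always verified against the genome. Internally all
coordinates are 0-based half-open; GTF is read as 1-based inclusive and VCF
as 1-based anchored, each in exactly one place.

The acceptor window is taken as 53 nt (50 intronic + 3 exonic). Boundary
counting could also justify 54; the window sizes are a `window_spec()`
argument, so the choice is explicit and overridable.

## Composition models

With `ΔS = S_alt − S_ref` per module, the exon-skipping model is

$$\Delta \mathrm{logit}(\Psi) = \beta_0 + \sum_{m} \beta_m \Delta S_m
 + \beta_6\,\mathbb{1}_{\text{exon} \cap \text{ss}}\,\Delta S_{\text{exon}}
 + \beta_7\,\mathbb{1}_{5'\text{i} \cap \text{donor}}\,\Delta S_{5'\text{intron}}
 + \beta_8\,\mathbb{1}_{3'\text{i} \cap \text{acceptor}}\,\Delta S_{3'\text{intron}}$$

— nine parameters. The indicators mark variants falling in doubly-scored
windows (the 5+3 exonic splice-site nucleotides, the 13 intronic donor
nucleotides, the 50 intronic acceptor nucleotides); their interactions with
the corresponding ΔS let the fit discount double-counted effects. The model
is fitted by minimising Huber loss (transition point `huber_delta = 1.0`,
configurable) with BFGS and an analytic gradient, started from the
least-squares solution; reporter measurements carry gross outliers, and the
tests show the Huber fit holding coefficients within ±0.05 where ordinary
least squares drifts visibly. Module weights are never updated by this fit.

Downstream transforms: `Ψ_alt = sigmoid(Δlogit(Ψ) + logit(Ψ_ref))`,
`ΔΨ = Ψ_alt − Ψ_ref`. Ψ values are clipped to `[1e-5, 1 − 1e-5]` in exactly
one place (`logit_clipped()`), so boundary references stay finite and the
clipping constant cannot drift between call sites. `Ψ_ref` must be supplied
by the caller — no default reference inclusion is assumed, and asking for
ΔΨ without one is an error. For competing splice sites,
`Δlogit(Ψ5) = ΔS_1 − ΔS_2` over the two candidate exons' predictions;
assuming equal allelic expression, heterozygous effects are exactly half
the homozygous ones. Splicing efficiency uses the same linear design with
the allelic log-ratio `log2((m_o/m_i)/(w_o/w_i))` as response and the
exon 5′ head, which is the default exon head throughout (switchable to
exon 3′). Pathogenicity is a logistic regression on the five ΔS plus three
indicators (nine weights; an extended set adding the five reference-allele
scores sits behind `feature_set = "delta_ref"`), evaluated by 10-fold
cross-validation; filtering to splice-region windows and removal of
stop-gain variants are the caller's responsibility. For variant-level
summaries across multiple paired exons, the signed effect of largest
magnitude is reported while all per-pair rows are kept.

Splice-disruption calls rank variants by |ΔΨ|: disruption can act in either
direction, so the magnitude, not the sign, is ranked for precision-recall
evaluation.

## Benchmark statistics

Model comparisons use the basic bootstrap: items (rows pairing an observed
value with both models' predictions) are resampled with replacement
`B = 999` times, the metric difference `d* = t1* − t2*` recomputed each
time, and `P = (1 + \#\{d^* \le 0\})/(B+1)` — floored at 0.001. Confidence
intervals are percentile-bootstrap (B = 1000, 2.5th/97.5th percentiles,
linear interpolation between closest ranks — `quantile()` type 7, chosen
for bit-reproducibility and documented because the endpoints are then
interpolants rather than exact order statistics). Resamples on which a
metric is undefined (a single-class draw for an area metric) are redrawn
and counted. The area under the precision-recall curve is trapezoidal with
tied scores collapsed and the curve anchored at recall 0 with the
top-threshold precision; auROC is likewise trapezoidal and cross-checked
against an independent implementation in the tests.

## What the synthetic generators emulate — and what they do not

`generate_mini_genome()` emulates the annotation-derived training corpus:
multi-exon genes on both strands with planted GT/AG dinucleotides at a
configurable `canonical_rate` (default 0.9, leaving room for non-canonical
sites, which are kept as positives just like canonical ones). Negative
splice-site windows are sampled inside the genes contributing positives,
never centred on an annotated junction, with a configurable fraction
(default 0.5) carrying the canonical dinucleotide to make the classifiers
robust; the default 1.5 negatives per positive mirrors the roughly 3:2
negative:positive ratio typical of such corpora. Only genuine exon–intron
junctions yield positives: a gene's transcript-last exon has no donor and
its first no acceptor.

`generate_mpra_like()` emulates reporter libraries of random 25-mers with
measured Ψ. Its ground truth is a planted-motif model: a PWM built from a
consensus (default `CATCGT`, consensus-base probability 0.85) with
column-centered log-odds, a latent score equal to the scale-weighted
sliding-window sum of those log-odds (expectation 0 under the uniform
background, so background sequences average Ψ ≈ 0.5), motif instances
planted into half the sequences, and labels
`Ψ = sigmoid(score + N(0, 0.3))`. Two properties are deliberate. First,
labels are generated on the logit scale and squashed, mirroring the model
family being fitted, so recovery tests have a well-specified optimum.
Second, the latent score is *graded* (linear in the one-hot encoding)
rather than a binary present/absent signal: with a binary ground truth no
predictor, however good, can exceed a Spearman rank correlation of about
0.75 against the labels (between-group rank variance `n²/16` over total
`n²/12`), which would make rank-recovery criteria unattainable for reasons
unrelated to the model. The default scale 0.35 puts the latent-score spread
near one logit unit for background sequences.

`generate_variant_truth_set()` places SNVs and ≤10-nt indels across exons
and their 100-nt flanks (5% of them deletions straddling a splice site, to
keep the boundary-relocation path exercised), writes a valid VCF, and
simulates each variant's response from known composition coefficients
applied to the *actual* module delta scores — so a zero-noise refit must
recover those coefficients exactly, and does so in the tests to about
1e-6 and better.

What passing these tests shows is that the machinery is correct and the
estimators behave as designed: coordinates and strand handling are exact,
the networks can extract planted signals, the robust fit recovers known
coefficients under noise and outliers, the bootstrap is calibrated under
the null. What it does not show is biological accuracy: the generators
have no branch points, no splicing grammar beyond one motif, no
position-dependent effects, no tissue specificity, and uniform base
composition. Performance on these fixtures is a correctness statement, not
a benchmark claim about real genomes.

## Problem sizes and numerical choices

The test suite trains the donor module on about 1,250 windows from a
600-exon genome (30 epochs) and the exon module on a 20,000-sequence
library (8 epochs); both are chosen as the smallest sizes at which the
planted signals are comfortably recovered (validation AUROC 1.0 for the
GT-determined classes, held-out Spearman ≈ 0.95 against true Ψ). Null
calibration of the bootstrap comparison runs 200 repetitions at B = 999.
Other constants: Adam (0.9, 0.999, 1e-8); batch-norm momentum 0.99,
epsilon 1e-3; Glorot-uniform initialization; Huber transition 1.0; Ψ
clipping 1e-5; BFGS relative tolerance 1e-14. Empty intronic flanks
(when `L_a` or `L_d` is 0) score 0 by convention so that their ΔS is 0.

## Known limitations

Deep intronic variants (beyond the flanks) are out of reach by
construction, as are phased compound effects — each variant is applied to
the pristine reference. Structural variants, branch-point-specific models,
and tissue-specific predictions are out of scope. The networks here are
deliberately small; scaling them up (and training on real corpora) changes
compute, not interfaces.
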