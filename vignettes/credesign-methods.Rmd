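---
title: "Designing cell-type-specific regulatory elements with credesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cell-type-specific regulatory elements with credesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A cis-regulatory element (CRE) is a short stretch of DNA — here always a
200-nt "insert" as assayed by massively parallel reporter assays (MPRAs) —
that modulates transcription of a linked gene. For gene- and cell-therapy
payloads one often wants a CRE that drives expression in one cell type and
stays quiet in others. Natural genomes offer a limited menu of such
elements; the space of possible 200-mers (4^200, over 2.58e120 sequences)
is astronomically larger. `credesign` implements a model-guided design
loop over that space: a convolutional sequence-to-activity model trained
on MPRA tables, specificity objectives that score how cell-type-restricted
a predicted activity profile is, three optimization algorithms that
propose sequences maximizing those objectives, and an interpretation stack
that explains designs in terms of transcription-factor (TF) motif
vocabulary.

## The activity model

The predictor maps a one-hot encoded sequence (columns A, C, G, T; `N`
rows are all-zero) to one predicted log2 fold-change (log2FC) per cell
type. Its three segments follow the Basset lineage of chromatin CNNs:

1. three convolutional blocks, each `convolution -> batch normalization ->
   ReLU -> max pooling`;
2. flatten and one fully connected layer that mixes positional and filter
   information;
3. one branch per cell type, a stack of four linear transforms ending in a
   scalar, so each output is an independent read-out of the shared trunk.

Two conventions matter downstream. First, 200-nt inserts are padded on
both sides with *constant flanks* to the model input length (600 nt by
default). The true reporter-vector backbone sequence is lab-specific and
not bundled; `default_flanks()` ships a fixed, documented pair so results
are deterministic, and every entry point accepts a replacement pair when
you have the real vector. Second, predictions are always computed for the
padded forward and reverse-complement sequence and averaged
(`predict_activity()`), which makes the prediction API strand-symmetric by
construction — a property the tests assert exactly.

The forward and backward passes are implemented in the package (im2col
convolutions, fused batch-norm kernels, Adam with cosine-annealed learning
rate, linear warmup and global gradient-norm clipping). Input gradients —
the hook needed by the gradient-based designer and by attribution — are
verified against finite differences in the test suite. The per-output
branches use a mildly leaky ReLU (slope 0.1, `branch_alpha`): with fully
hard rectifiers an unlucky initialization can switch an entire branch off,
and because each cell type's gradient reaches the trunk only through its
own branch, that branch never recovers. The leak keeps every output
trainable; warmup and clipping remove the rare early-training collapse we
otherwise observed for one output in roughly one run out of four.

Defaults: channels 300/200/200, kernels 19/11/7, pools 3/4/4 at 600-nt
input (any configuration passing the integer-pooling arithmetic is
accepted); MSE loss; batch 128; the parameters achieving the lowest
validation loss during training are returned.

## Objectives and specificity geometry

For an activity vector with a designated target cell, `min_gap()` is the
target prediction minus the maximum off-target prediction. Because MinGap
is translation invariant, it cannot distinguish "high on-target, low
off-target" from "very high everywhere"; the bending function
`g(x) = x - exp(-x) + 1` (`bend()`) breaks that invariance.
`bent_min_gap()` clamps predictions into [-2, 6] — deep models produce
pathologically extreme values on sequences far from the training
distribution, so all design-time predictions are constrained — and returns
`g(y+) - g(y-)`.

The propeller coordinate system (`propeller()`) summarizes a three-cell
activity triple: the winning cell type gives the axis, MaxGap
(max - min) the radius, and the deviation angle
`60 * (median - min) / (max - min)` degrees measures how close the leading
off-target sits to the target. `classify_specific()` calls a sequence
cell-type-specific when MaxGap strictly exceeds 1 (stringent: 4) and
MinGap/MaxGap strictly exceeds 0.5, with the effective target taken as the
argmax cell (sequences whose argmax differs from the designed target are
counted as reassigned). `specificity_report()` applies the replicate-SE
filter (drop oligos with SE > 1 in any cell type) and tabulates group
percentages to one decimal.

## Designers

All three algorithms optimize sequences against the model; each run
returns at most one sequence so a batch of runs maximizes diversity.

**Fast SeqProp** (`design_fast_seqprop()`) maintains a learnable 200x4
logit matrix, initialized from a standard normal. Each step:
instance-normalize the logits (per-base mean/variance over the length
axis, epsilon 1e-5, *no* learnable affine), softmax into a position
probability matrix, draw 20 one-hot samples, and take the loss as the
negative mean bent-MinGap of the samples (plus the motif penalty when a
pool is given). Gradients pass through the sampling with the
straight-through estimator — the sample's gradient is applied unchanged to
the softmax probabilities — and Adam (0.9/0.999) runs at learning rate 0.5
cosine-annealed to 1e-6 over 300 steps. Afterwards 20 sequences are drawn
from the learned distribution and the best by bent-MinGap is kept unless
it scores below 3.6. The learned distributions are returned (`ppms`); on a
linear scorer the distribution provably concentrates on the scorer's
per-position argmax, which the suite checks.

**AdaLead** (`design_adalead()`) evolves 20 random sequences for 30
generations with mu = 1 expected mutations per child, per-site
recombination at rate 0.1, parent selection within `threshold = 0.25` of
the generation best, and a greedy rollout bounded by `rho = 2` extra
mutation rounds (we read rho as the rollout depth bound, matching the
reference implementation's behaviour). Fitness is bent-MinGap; the final
best is collected unless its MinGap is below 2.

**Simulated annealing** (`design_simulated_annealing()`) runs a
Metropolis-Hastings chain whose proposals mutate three random positions;
the energy is the negative MinGap *without* bending, and the temperature
follows `tau(s) = 1/(1 + s^0.501)` — decreasing, with a divergent sum, so
the chain keeps a sliver of exploration at any finite step. The chain
length is not prescribed anywhere we could find; the default is 3,000
steps and the best-visited sequence is returned (both configurable).

**Motif penalization.** The penalty of a motif pool
`{PWM(1)..PWM(m)}` over a batch of n sequences is
`1/(mn) * sum_i (m - i + 1)^(1/3) * sum_{j: s_j >= t_i} s_j`, the windows
j running over both strands of every sequence; the cube-root factor keeps
early pool members penalized hardest. Thresholds are a fraction of each
motif's consensus score (0 retains even weak instances in the penalty, as
is useful for grammars with strong suboptimal binding sites; 0.25
otherwise). `penalization_track()` iterates: design an unpenalized batch,
find the top enriched motif, append it to the pool, design the next batch
penalized, and so on. PWMs here are log2-odds against the uniform
background, so consensus scores are positive and fraction-of-consensus
thresholds are well defined; the Patser-style threshold is computed from
the exact discretized null score distribution with cutoff
`P(S >= t) <= 2^-IC`.

Enrichment uses a built-in seed-and-extend surrogate
(`enrich_motifs()`): over-represented words versus a shuffled background
seed PPMs that a few EM rounds polish; candidates are ranked by
fold-enrichment and near-duplicates dropped. An external discovery tool
can be substituted by supplying its motifs in MEME minimal format.

## Interpretation

**Sampled integrated gradients** (`sampled_integrated_gradients()`)
adapts integrated gradients to the simplex geometry of sequence space:
the straight path runs in logit space from the zero matrix (the uniform
background) to `logit_scale` times the one-hot (default 10, about 0.999
probability on the observed base). At each midpoint-rule path point the
softmax distribution is sampled and only genuine one-hot sequences reach
the model; gradients return through the straight-through estimator and
the softmax. Averaging over samples and path points and scaling by the
path length yields *hypothetical* scores for all four bases at every
position; masking by the one-hot gives the observed-sequence scores. For
a linear model the construction has a closed form, and the suite checks
agreement within three Monte-Carlo standard errors (the function can
return its own per-entry standard error).

**Contribution blocks** (`call_blocks()`): the 200 per-position masked
scores are smoothed with a Gaussian filter (sigma 1.15, reflect edges,
kernel radius `int(4*sigma + 0.5)`); positive blocks are runs of at least
4 positions above 0.015, negative blocks runs below -0.015. The source
text we follow says "below a threshold of 0.015" for negative blocks; we
read that as below minus 0.015, since a one-sided +0.015 cut would
re-capture weak positive signal. `ablate_blocks()` randomizes block
positions (or outside positions, coverage-matched to the upper half of the
block-coverage distribution, minimum five positions) and reports the
prediction change.

**Pattern conversion and scanning.** `pattern_to_pwm()` turns an
attribution-space pattern into PWM/PPM form (divide by the maximum
position score sum, times 10; row softmax for the PPM; negative patterns
have their repressive portions sign-flipped and compensated by 1.2).
`contribution_motif_scan()` matches motifs in contribution-weight-matrix
form against hypothetical maps: maps are zero-padded by 5 on both sides,
every window and orientation is scored by Pearson correlation, and per
(cell, motif) the hit threshold is `min(0.75, mu + 4*sd)` of a sampled
coefficient distribution. Zero-variance windows have an undefined
correlation and are excluded rather than scored 0. Downstream,
`motif_contribution_summary()` averages the masked score sums inside hit
spans weighted by match correlation (masked scores by default; the
hypothetical alternative is a switch), `motif_ablation()` and
`motif_embed_background()` measure predicted effects of removing or
inserting motifs, `motif_cooccurrence()` tabulates pairwise presence, and
`nmf_programs()` factorizes the sequences-by-motifs count matrix with
multiplicative updates from a deterministic NNDSVD start (k = 12 by
default; coefficient rows normalized to 1 for reporting; program activity
signatures average motif contributions clipped at 3).

## The synthetic-MPRA generator

Nothing above is testable offline without data, so `synth_grammar()` and
`simulate_mpra()` define a fully specified study-in-a-box. The default
grammar has 3 simulated cell types, each with 2 private activators
(effects uniform in [1.5, 3.5] log2FC) and 1 private repressor
([-2.5, -1]), baseline 0, Gaussian replicate noise of 0.25 log2FC, and a
saturation cap of 6 on summed effects. Motifs are 12-nt with 0.97 of the
probability mass on the consensus base per position — the
consensus-dominant end of real TF motifs — a deliberate calibration so
that a compact model recovers the grammar within minutes on a single CPU,
which is what makes the parameter-recovery and interpretation checks
meaningful at desk scale. Each simulated oligo is a uniform random
200-mer with 0-4 planted, non-overlapping instances at random positions
and strands, annotated exactly; per-cell activity is baseline plus capped
effect sum plus noise. Chromosome labels, plasmid/RNA counts and
replicate SEs are simulated so the full preprocessing path (count filter,
precedence averaging, 6-s.d. outlier cut, SE filter, chromosome split,
rc/duplicate augmentation) runs end to end.

What the simulator does *not* emulate: positional and orientation effects,
motif-motif synergy beyond additive-with-cap, soft homotypic clusters,
GC-content covariates, batch effects between libraries. Passing the
recovery tests therefore demonstrates that the machinery is correct and
that the model class can learn an additive motif grammar — not that it
matches any particular laboratory's MPRA.

## Desk-scale problem sizes and reproducibility

The package's own experiments (test suite and examples) use a compact
`surrogate_config()`: bare 200-nt inserts, channels 32/24/24, kernels
11/7/5, pools 5/2/2, hidden width 96, branch width 32, 7 epochs at batch
256 — sized so that the full simulate-train-evaluate loop
(`surrogate_experiment()`, n = 20,000 oligos) completes in a few minutes
on one CPU while reaching held-out per-cell Pearson r around 0.94.
Randomness is controlled by a single root seed from which component seeds
derive by fixed offsets; all seeded entry points restore the caller's RNG
state. Training is deterministic given seed and thread count at the
statistical level asserted by the tests (bit-exact replay additionally
requires a fixed BLAS).

## Known limitations

- The exact production hyperparameters of the published three-cell model
  (channel counts, dropout placement, segment-3 activations) are not in
  the public text; the defaults are documented members of the same family,
  not a weight-level reproduction.
- The reporter-backbone flanks are placeholders unless you supply your
  vector's sequence; absolute predicted log2FC values shift with flanks
  even though design objectives are robust to a constant context.
- `nmf_programs()` fixes k; bi-cross-validation for choosing k is out of
  scope.
- The enrichment surrogate targets ungapped motifs of width 8-15; gapped
  or variable-spacing patterns need an external discovery tool.
- Propeller geometry and the specificity rules are defined for exactly
  three cell types.
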