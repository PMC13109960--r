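---
title: "Gain-modulated recurrent networks as digital twins of arithmetic learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gain-modulated recurrent networks as digital twins of arithmetic learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and what it is for

`numtwin` simulates a mechanistic account of math learning disability (MLD):
that an excitation/inhibition imbalance — operationalized as a multiplicative
neural gain `G` on every rectified-linear neuron, `y = G * max(0, x)` — is
sufficient to produce the behavioral and representational profile seen in
affected children. The package trains a family of gain-modulated recurrent
convolutional networks on visually presented addition and subtraction,
matches each member of a synthetic cohort of children to the network whose
normalized accuracy best mirrors the child's normalized achievement score
("digital twins"), and then asks what the matched networks look like inside:
representational similarity between problems, and the geometry (capacity,
dimensionality, center alignment) of the 19 "result manifolds" formed by
problems sharing an answer.

## The task

Stimuli are equations rendered as `3 x 28 x 140` images of five 28-pixel
slots: tens and units of the first operand, the operator, tens and units of
the second operand (blank tens for single-digit operands, an all-black slot).
All ordered-operand problems with results in 0..18 and operands bounded by 18
are used: 190 additions plus 190 subtractions, exactly 20 problems per result
value, so both splits are balanced over the 19 answer classes by
construction.

No external handwritten-digit corpus ships with the package;
glyphs are synthesized procedurally from stroke skeletons: the handwritten
style jitters control points, pen thickness (2 +/- 1 px) and pose per
variant; the printed style renders one fixed shape per character and
translates it by whole pixels. The operator glyphs are assembled from the
same vertical-bar primitive as the digit "1" (the minus sign is its
rotation), and each character has at least 100 bank variants by default.
Each problem gets 100 rendered variants, half assigned at random (seeded) to
the training split and half to testing, with variant tuples kept disjoint.
What this generator does *not* emulate: the long-tailed shape variability of
real children's handwriting, writer-specific style correlations across a
problem, and ink/contrast variation. Passing tests therefore demonstrate the
*mechanism* (gain-dependent learning and geometry) on a controlled stimulus
family, not OCR-grade robustness.

## The network

The architecture is a four-block recurrent convolutional network in the
lineage of CORnet-S, with blocks named for the dorsal-stream areas V1, V2,
V3 and IPS. Each block applies one input convolution (V1: 5x5 window with
effective stride 4, fusing the conv + pool front end; later blocks: 3x3),
and on every recurrent timestep adds a lateral 3x3 convolution of the
previous hidden state before batch normalization and the gain-ReLU
(recurrence V1:1, V2:2, V3:4, IPS:2; the last timestep of each block is what
all representational analyses read). Batch normalization is
normalization-only: scale and shift are frozen at 1 and 0 forever, batch
statistics standardize each channel during training, and running averages
are used at evaluation. The readout is linear (no gain) over IPS activations
pooled across the *height* of the map only — the stimulus is a 1:5 equation
strip, so pooling width away would collapse the slot structure that narrow
desk-scale models have too few channels to re-encode; preserving the nine
coarse horizontal positions keeps the readout problem well-posed at small
widths. Networks are never pretrained.

A consequence of frozen, active batch norm worth stating explicitly: in
training mode the hidden stack is exactly positively homogeneous in the
gain, `h_l(G) = G * h_l(1)` (up to the batch-norm epsilon), so the gain
reaches behavior chiefly by scaling the readout logits — a temperature
effect that sharpens early, mostly wrong, softmax outputs and thereby
degrades the *learning dynamics* rather than the static function. This is
the mechanism by which higher excitability slows learning here.

## Training protocol

Cross-entropy loss, Adam with learning rate 0.001, batches of 100 stimuli
sampled uniformly with replacement from the training split (structural
balance makes batches label-balanced in expectation). One iteration is one
optimizer step; models are evaluated every 100 iterations, including
iteration 0 (before any update, where accuracy sits at chance, about 1/19).
All gain levels consume the identical batch stream (shared sampling seed)
from identical initial weights (the gain does not enter initialization).

Two profiles exist. The `full` profile is the full-scale protocol: 17 gains
`G = 1 + 0.25k`, 3800 iterations, CORnet-S-scale channel widths
(64/128/256/512). The `desk` profile — used by all tests and the analysis
scripts — keeps the protocol but shrinks scale to laptop size: gains
{1, 2, 3, 4, 5}, 600 iterations, widths 8/16/16/16. Checkpoint evaluations
use a fixed result-balanced subset of the test split (5 variants per
problem, 1900 images) so evaluation cost stays flat; captured activations
(IPS at every checkpoint, all four layers at the final one) are means over
the same subset. At desk scale the networks are still far from ceiling after
600 iterations (accuracies roughly 0.15-0.25, versus 5.3% chance); the
desk-scale analogue of "mastery" for iterations-to-threshold analyses is
therefore an accuracy of 0.15, a level the low-gain models cross in
mid-training.

## Behavioral metrics

From each checkpoint's 19 x 19 response matrix (counts of response r given
true result s, both 0..18):

* **systematic error** — mean over result levels of |mean response − result|
  (trueness);
* **imprecision** — mean over levels of the *population* (1/n) standard
  deviation of responses; the population convention is used because the
  quantity describes the response distribution itself, not an estimate of a
  larger one;
* **effective number of responses** — `exp` of the natural-log Shannon
  entropy of the response distribution pooled over all test trials; the
  natural log makes a uniform k-outcome distribution score exactly k (19 at
  most here, 1 for a constant responder). Pooling is over trials, not over
  problem types.

## Representational similarity

For one layer, a problem's representation is the unit-wise mean activation
over its evaluated test variants; the NRS matrix is the 380 x 380 Pearson
correlation (across units) between these patterns, sorted canonically
(addition before subtraction, then by result, then by first operand). Block
averages summarize similarity between operations (`add_sub`) and within
operations (`add_add`, `sub_sub`); within-operation averages exclude the
diagonal, whose self-similarity of 1 would bias the mean. Zero-variance
patterns yield undefined correlations; these are flagged `NA` and excluded
from averages rather than zero-filled. Cross-operation pairs are also broken
down by operand overlap (both operands shared, left only, right only,
none); the overlap analysis is restricted to cross-operation pairs, the
within-operation variant being a config-level alternative rather than the
default. Layers wider than 8192 units would be randomly subsampled (seeded)
before correlation; no desk-scale layer reaches that size. For comparison
with externally supplied similarity values recorded on the Fisher-z scale,
`fisher_unz()` (tanh) maps them back to the correlation scale.

## Manifold geometry

The 20 problems sharing a result form one of 19 "result manifolds" in each
layer's unit space. Geometry follows the replica mean-field theory of
perceptual manifolds: each manifold is described in a center-plus-axes frame
(axis coordinates divided by the center norm, a unit center coordinate
appended), and for Gaussian fields `t` the convex program
`F(t) = min ||v - t||^2 s.t. <v, s> >= kappa` over the manifold's points is
solved through its non-negative dual by cyclic coordinate descent (the
per-manifold Gram matrix is 20 x 20, so no external QP solver is needed).
Inverse capacity is the field-average of `F`; anchor points
`s* = (t - v)/sum(alpha)` give the radius (root-mean-square anchor norm) and
dimensionality (mean squared field-anchor alignment). Defaults: margin
`kappa = 0`, 200 field draws per manifold, seeded; unit spaces above 500
dimensions are first randomly projected to 500. For zero-radius (point)
manifolds the computation reduces to Cover's classical limit, capacity 2.

Center correlation is the mean absolute pairwise Pearson correlation between
manifold center vectors (self-pairs excluded); the absolute value is used
because "alignment" is sign-agnostic.

As an independent oracle, `empirical_capacity()` estimates capacity by
random balanced dichotomies: all member points, signed by their dichotomy
label, are tested for homogeneous linear separability, and bisection over
random-projection dimension locates the 50% separability transition
(capacity = manifolds / transition dimension). Separability is decided by
Gordan's theorem — a separating direction exists iff the origin lies outside
the convex hull of the signed points — using Gilbert's minimum-norm-point
iteration, which either emits a separating certificate or drives the hull
point to the origin. This characterization is exactly equivalent to the
linear-program feasibility formulation; it was chosen because it needs no LP
solver dependency and produces a verifiable certificate.

## Digital-twin matching

Model accuracies are min-max normalized over *all* checkpoints of the sweep
(every iteration and gain, bounds computed once before any matching);
cohort scores are min-max normalized across children. At each candidate
iteration every child receives the gain minimizing the L1 distance between
the two normalized values, ties breaking toward the lower gain
(conservative about attributing hyperexcitability). The best matching
iteration minimizes the cohort-mean distance; a permutation control
reassigns scores to fitted models at random. Exact ties in the distance are
possible in principle because desk-scale accuracies are multiples of 1/1900;
closed-loop recovery (pseudo-children built from the sweep's own normalized
accuracies) therefore recovers the generating gain exactly whenever that
accuracy value is unique at the iteration, and recovers a distance of zero
unconditionally. Group comparisons use Welch's t-test and pooled-SD
Cohen's d (the common default variants).

## The synthetic cohort

The cohort stands in for 45 children aged 7-9: 24 typically developing and
21 with MLD, defined by a standard achievement score below 90. Raw scores
are drawn on the standard-score scale inside an attainable range of 55-145:
TD scores from a moment-matched truncated normal on [90, 145], MLD scores
from a mixture of a dominant just-below-cutoff truncated normal on [70, 90)
and a 3% uniform low tail on [55, 70). The mixture is what makes the
reference normalized summaries (MLD mean 0.35 with SD 0.06 after cohort-wide
min-max normalization — i.e. a group mean nearly six group-SDs above the
cohort minimum) attainable at all: they imply a cohort containing at least
one far-below-range scorer. Component moments are solved analytically from
the normalized targets, so a large generated cohort converges to MLD
0.35 +/- 0.06 and TD 0.70 +/- 0.13; a 45-child draw, like any real 45-child
sample under min-max normalization, scatters around those values (the
low-tail child is present in roughly half of the draws). Classification is
consistent with the cutoff by construction, so the default cohort always
contains exactly 21 children below 90. Age/IQ/reading covariates play no
computational role and are not simulated.

For the prediction stage, synthetic "observed" child similarities are
generated from the twins' predicted IPS add-sub NRS through the Fisher-z
domain, `observed = tanh(coupling * atanh(predicted) + noise)`, so the
ground-truth coupling is known and recoverable. The analysis default
(coupling 0.8, z-noise SD 0.1) yields a moderately strong
predicted-vs-observed correlation; this is a calibration demonstration, not
an empirical claim about children.

## Extended-training remediation

Each MLD twin resumes training from its matching checkpoint with gain held
fixed until it reaches the median accuracy of the TD twins, up to a
censoring cap of five times the starting iteration (reported as censored,
not an error). The cost is reported absolutely and as a percentage of the
starting iteration.

## Numerical choices and degenerate inputs

* Convolution is im2col + GEMM with a precomputed gather; backprop uses a
  `rowsum` scatter-add. Gradients match central finite differences to ~1e-8.
* Batch-norm epsilon 1e-5; running-statistics momentum 0.1.
* Weight init: fan-in-scaled Gaussians (He) with a recorded seed.
* Coordinate descent for the manifold QP stops at a 1e-9 step tolerance or
  500 sweeps; Gilbert's iteration at 500 steps or a 1e-7 hull-norm
  tolerance (points are pre-normalized, making the tolerance scale-free).
* Degenerate inputs raise typed errors rather than returning silently:
  empty operation sets, odd variant counts, operands over 99, non-positive
  gains, missing checkpoints, response levels with no responses, constant
  activation patterns (flagged `NA`), identical manifold points, degenerate
  normalization bounds, infeasible cohort calibrations.

## Scale of the shipped analyses

The analysis scripts and the test suite run the desk profile: 5 gains x 600
iterations x ~14k parameters, 100 variants per problem rendered lazily,
checkpoint evaluation on 1900 balanced test images — about ten minutes of
CPU for the sweep, a few seconds for each downstream stage. The full
profile is provided as configuration (17 gains, 3800 iterations, full-width
blocks) and reproduces the study design, but is documented as long-running
and is not exercised by the tests. Desk-scale runs preserve the *signs* of
the full-scale phenomena (accuracy, error metrics, NRS, manifold geometry
versus gain), which is what the test suite asserts; they do not reproduce
full-scale numeric values such as correlation magnitudes near 0.95, and the
package does not claim them.

## Known limitations

* The gain acts through softmax temperature under frozen batch norm; other
  biologically plausible E/I implementations (unnormalized activation
  growth, per-layer heterogeneous gain, spiking saturation) are out of
  scope.
* The procedural glyphs are a stand-in; nothing is claimed about real
  handwriting statistics.
* Small-cohort normalized score summaries are sampling-variable by design
  (min-max normalization over 45 children); only large-sample calibration
  targets are guaranteed.
* The desk sweep stops far below ceiling accuracy; analyses of near-mastery
  regimes (e.g. 95% thresholds) are only meaningful under the full profile.
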