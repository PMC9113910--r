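---
title: "Methods: resting-state ALFF mapping, cluster statistics, autoencoder features and efficacy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state ALFF mapping, cluster statistics, autoencoder features and efficacy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phnalff` implements the computational core of a clinical resting-state
fMRI study design: evaluating an analgesic (pregabalin-style) treatment of
postherpetic neuralgia through (i) voxel-wise amplitude of low-frequency
fluctuation (ALFF) and fractional ALFF (f-ALFF) mapping with group
statistics and cluster-extent thresholding, (ii) a stacked-autoencoder
feature-extraction experiment comparing classifiers on raw versus learned
("fine") features, and (iii) visual-analog-scale (VAS) based efficacy
scoring. Because no imaging data are distributed with such studies, the
package includes a seeded synthetic-data generator that emulates the
acquisition geometry and the clinical table structure, so every stage of
the pipeline is exercised end to end by the test suite.

## The spectral model: ALFF and f-ALFF

A voxel's preprocessed BOLD series $x_t$ ($t = 0, \dots, n-1$, sampling
interval TR) is decomposed by the unpadded DFT. We use the one-sided
amplitude convention
$$a_k = \frac{2}{n}\,|X_k| \quad (0 < k < n/2), \qquad
  a_k = \frac{|X_k|}{n} \quad (k \in \{0, n/2\}),$$
so a sinusoid of amplitude $a$ on an exact interior bin has spectral
amplitude $a$ there, and the per-bin powers $a_k^2/2$ (interior) and
$a_k^2$ (DC/Nyquist) satisfy Parseval's identity against the series mean
square. ALFF is the *mean amplitude* over the bins whose frequency lies in
the closed low-frequency band $[0.02, 0.07]$ Hz; f-ALFF is the *summed*
in-band amplitude divided by the amplitude summed over the total band
$(0, 0.25]$ Hz (DC excluded, Nyquist included; 0.25 Hz is the Nyquist
frequency at TR = 2 s). Amplitude — the square root of power — is the
field's standard ALFF convention; `power = TRUE` switches both measures to
squared amplitude.

Two numerical consequences are worth stating. First, with $n = 240$
retained volumes at TR = 2 s the frequency grid is $k/480$ Hz and the
closed-interval rule puts exactly 24 bins (k = 10..33) in the band and 120
bins in $(0, 0.25]$, so the expected f-ALFF of white noise is close to the
bin fraction $24/120 = 0.2$ (the Nyquist bin's amplitude has a slightly
different expectation, shifting the exact value by under half a percent —
well inside the ±0.01 tolerance we test at). Second, the band-pass filter
is realized as an ideal spectral mask using the *same* closed-interval bin
rule, so "filter then measure" and "measure in band" are exactly
consistent; this is tested as an oracle-equivalence property.

**Ordering ambiguity.** Descriptions of this pipeline often say the series
is band-pass filtered *before* ALFF; taken literally for f-ALFF that would
make numerator and denominator identical. We therefore compute both
measures from the full spectrum of the detrended, smoothed (unfiltered)
series; the band restriction lives inside the ALFF/f-ALFF definitions.

## Preprocessing

Fixed order per subject: discard the first 20 of 260 volumes (keep 240),
voxel-wise linear detrending (intercept *and* slope removed — the mean
must not leak into the f-ALFF denominator), then separable Gaussian
spatial smoothing. The protocol this emulates never states a kernel
width; we default to 6 mm FWHM, the field convention, with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis in voxel units.
Boundary handling is nearest-edge replication: kernel mass falling outside
the grid accrues to the nearest edge voxel, so constant volumes pass
through unchanged and total intensity is conserved for interior-supported
inputs. Motion correction, slice timing and nuisance regression are out of
scope.

## Group statistics and cluster-extent thresholding

Voxel-wise tests are the classical pooled-variance two-sample Student t
(df $= n_A + n_B - 2$; group sizes are equal by design) and the paired t
on within-subject differences. Zero-variance voxels are handled by policy:
$t = 0, p = 1$ for degenerate pooled variance, $p = 0$ at the float floor
for a constant nonzero paired shift; both are counted and reported.

Before testing, each subject's map is standardized by dividing by its
in-mask global mean (mALFF convention), making maps comparable across
subjects. Suprathreshold voxels ($p <$ 0.001, strict) are split by the
sign of t — increases and decreases are analyzed separately — and labelled
into connected components at 26-connectivity by default (6 and 18 are
available; the underlying studies rarely state the choice). Components
with more than 36 voxels (strict inequality, matching the printed
"voxel size > 36" convention) are retained, sorted by size, then peak
|t|, then lexicographic peak index. Peak coordinates are reported both as
0-based voxel indices and in world mm through the affine. The "cluster
level P < 0.05" phrasing that usually accompanies the fixed 36-voxel rule
is *not* implemented as a random-field or permutation cluster p — no such
computation is described for this design; the extent rule itself is the
cluster-level control. This is a documented limitation.

## The synthetic BOLD generator

Each voxel's series is a constant baseline plus `n_sinusoids` (default 3)
sinusoids with frequencies drawn uniformly in 0.02–0.07 Hz and uniform
phases, plus white Gaussian noise (default SD 1, sinusoid amplitude 1,
baseline 100). A sinusoid-plus-noise model was chosen over filtered 1/f
noise because the ALFF ground truth is then analytic (a sinusoid of
amplitude $a$ has variance $a^2/2$ and in-band amplitude $a$); a config
flag adds a 1/f background for realism experiments. Inside *planted
regions* (rectangular blocks recorded in the label atlas) the sinusoid
amplitudes of the treatment group are multiplied by a configured factor —
the planted effect the pipeline must recover. Random draws do not depend
on the group label, so treatment/control volumes from the same seed differ
only inside the planted region. The default test grid is 24×24×12 voxels
(voxel size 3.4375×3.4375×5.2 mm, the acquisition geometry's in-plane
spacing and slice pitch); `grid = "full"` selects the 64×64×30 acquisition
matrix. The emulated design uses 20 subjects per group, 260 volumes at
TR = 2 s.

What the generator does *not* emulate: hemodynamic autocorrelation, head
motion, physiological noise structure, spatial intensity inhomogeneity,
and anatomy (the "atlas" is a synthetic label block, not a brain
parcellation). Passing tests therefore demonstrate the correctness and
calibration of the *computational pipeline* under a controlled signal
model, not performance on real scans.

The clinical generator draws each cell of the follow-up table
independently from Normal(mean, SD) at the study's printed group
summaries (treatment VAS 8.3±1.1 at baseline, then 6.5±0.8, 6.5±0.8,
3.1±0.3, 2.3±0.4 at weeks 1–4; control 8.3±1.2 baseline, 5.5±0.5 and
4.6±0.5 at weeks 3–4; sleep hours 3.6±0.3 / 4.8±0.5 / 5.1±0.4 / 5.8±0.6
versus 2.5±0.4 / 3.3±0.3 / 3.9±0.3 / 4.1±0.4). The control group's VAS at
weeks 1–2 is not reported anywhere; we interpolate linearly between the
printed baseline and week 3 (7.4±0.9, 6.4±0.7) and flag these as
synthetic, non-reported values. VAS draws are clipped to [0, 10] — a
deliberate truncation; at the configured SDs clipping is rare.

## Study-condition choices for the end-to-end checks

The planted-region recovery run uses the defaults above: one 60-voxel
(5×4×3) region at amplitude multiplier 2.0, 20 subjects per group on the
24×24×12 grid, default thresholds. A run counts as a recovery when the
cluster table contains exactly one increase cluster and its peak lies in
the planted region; we require at least 18 of 20 seeds.

The type-I calibration run removes the planted effect (multiplier 1) and
checks two things over 20 seeds: the pooled fraction of in-mask voxels
with $p < 0.05$ against the binomial 99% interval around 0.05, and the
number of retained clusters (zero expected in at least 19 of 20 seeds).
Two deliberate choices here: the run uses a 16×16×8 grid — calibration is
a per-voxel property, so the grid size only sets the Monte-Carlo voxel
count — and spatial smoothing is disabled, because the binomial reference
distribution for the suprathreshold *fraction* is exact only when voxels
are independent. Smoothing leaves marginal calibration intact but
correlates neighbouring voxels, which inflates the variance of the
fraction and makes binomial bounds invalid rather than conservative.
Cluster behaviour *with* smoothing is exercised by the recovery run, whose
background must contain no second cluster.

## The stacked autoencoder and the classifier comparison

The autoencoder is built from sigmoid coding layers
$H = \sigma(Wx + d)$ and a mirrored sigmoid decoder, trained to minimize
the summed binary cross-entropy reconstruction loss
$G(x, y) = -\sum_i [x_i \log y_i + (1-x_i)\log(1-y_i)]$ over inputs scaled
to $[0,1]$ (the loss's domain; the final layer is sigmoid so $y \in
(0,1)$ and the loss is well-defined). The decoder maps the hidden feature
$H$, not the input — the standard reconstruction architecture. Hidden
widths default to the geometric schedule $\lceil M/2 \rceil, \lceil M/4
\rceil, \lceil M/8 \rceil$ (three hidden layers); weights initialize
Uniform$(-1/\sqrt{d_{in}}, 1/\sqrt{d_{in}})$ from the seeded generator.

Training is greedy layer-wise pretraining (each hidden layer fitted as a
one-hidden-layer autoencoder on the previous layer's codes) followed by
end-to-end full-batch gradient descent. Full batch — not stochastic — so
runs are bit-reproducible from the seed and the descent property is exact.
The step size backtracks: a step that would increase the loss is halved
until it does not (so the recorded per-epoch loss is nonincreasing), and
grows by 10% after each accepted step. The growth matters: stacked
sigmoids initialized with small weights start in a small-gain regime where
activations contract toward 0.5 layer by layer; at a fixed small step the
optimizer crawls and the code layer collapses to a near-constant. The
adaptive step escapes this regime while never accepting an uphill move.
Gradient correctness is verified against central finite differences.

For the classifier comparison, the autoencoder is pretrained on the
training split only, then the encoder and a softmax head are tuned
*jointly* on the training labels (full-batch gradient descent on the
multinomial cross-entropy, backpropagated through the encoder; the head
is randomly initialized because a zero head is a symmetric saddle with
exactly zero encoder gradient). This supervised tuning step is the
"adjust the hidden-unit weights according to the softmax classifier"
element of the depth-autoencoder design. Code-layer activations of the
tuned encoder are the *fine features*. Softmax, linear SVM and RBF SVM
(e1071 baselines, default settings) are then trained on raw and on fine
features and scored on the held-out split.

The nonlinear synthetic feature structure is an exclusive-or arrangement
of four Gaussian blobs in two informative dimensions (diagonal blobs share
a class) plus independent uniform noise dimensions, all in $[0,1]$. No
linear boundary beats chance on XOR, the defining property we need, and a
small stacked-sigmoid network learns it reliably — unlike concentric
shells, which we found pathologically slow for this architecture under
full-batch descent. The expected pattern, reproduced as a directional
property over 20 seeds rather than as specific accuracy values (none are
printed for the original experiment): fine features ≥ raw features for
every classifier, with raw linear classifiers near chance and fine
features near-perfect.

## Efficacy scoring

The VAS weighted value is the fractional reduction from baseline,
$(\mathrm{VAS}_{pre} - \mathrm{VAS}_{post}) / \mathrm{VAS}_{pre}$ —
undefined at a zero baseline, scale-invariant, reported internally as a
fraction and as a percentage in outputs. Outcome categories partition the
weighted value: cured $\ge 0.75$, markedly effective $[0.50, 0.75)$,
effective $[0.25, 0.50)$, ineffective $< 0.25$ (closed at each lower
bound). The total effective rate is the fraction of subjects in any
category other than ineffective. The report runs paired t tests of each
week against baseline within groups, pooled two-sample t tests between
groups per week (both VAS and sleep hours), and tabulates outcome
categories at week 4. `two_sample_t_from_summary()` reconstructs the
pooled t test from printed mean ± SD and n, which is how the study's
significance claims are checked without subject-level data.

## Problem sizes and runtime

The suite and the acceptance script run on one CPU in well under their
half-hour scale: the recovery run (20 seeds × 40 subjects × 240 retained
volumes on 24×24×12) is the dominant cost at roughly 20–25 s per seed;
the calibration run uses the smaller grid at ~4 s per seed; the
white-noise f-ALFF check vectorizes 10^4 spectra in seconds; the
classifier comparison runs 20 seeds in about 80 s. The full 64×64×30
acquisition geometry is available as a config preset and runs the same
code path.

## Known limitations

- No cluster-level p value is computed; the fixed extent rule stands in
  for it, as in the emulated design.
- The generator's noise is temporally white; empirical BOLD noise is
  autocorrelated, so real-data type-I behaviour of the *extent rule* (not
  of the voxel test) will differ.
- f-ALFF's white-noise expectation 0.2 is specific to TR = 2 s and
  n = 240; other geometries shift the bin counts.
- The autoencoder is a from-the-equations reference implementation tuned
  for reproducibility (full batch, monotone loss), not a performance
  implementation.
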