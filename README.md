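# phnalff

Computational pipeline for evaluating analgesic treatment of postherpetic
neuralgia (PHN) from resting-state functional MRI and clinical follow-up.

Chronic pain studies of this design compare a treatment group against an
active control on two fronts: spontaneous brain activity, measured by the
amplitude of low-frequency fluctuation (ALFF) and its fractional variant
(f-ALFF) in resting-state BOLD, and clinical response, measured by the
visual analog scale (VAS) and continuous sleep time over four weeks of
follow-up. A deep-learning arm compares classifiers trained on raw
region-level features against "fine" features extracted by a stacked
autoencoder. `phnalff` implements all of these stages as a tested R
package plus numbered analysis drivers, together with a seeded
synthetic-data generator so the whole pipeline runs and is verifiable
without patient data. It is aimed at readers who want to audit, reuse or
stress-test the computational methods of such a study.

## What it computes

**Spectral maps.** For each voxel's preprocessed series (discard the first
20 of 260 volumes, linear detrend, 6 mm FWHM Gaussian smoothing; TR = 2 s)
the one-sided amplitude spectrum a_k = (2/n)|X_k| is computed and

- ALFF = mean amplitude over the closed band 0.02–0.07 Hz,
- f-ALFF = (Σ in-band amplitude) / (Σ amplitude over (0, 0.25] Hz),

with maps standardized by their in-mask global mean (mALFF) for group
comparison.

**Group statistics.** Voxel-wise pooled-variance two-sample t (df =
n_A + n_B − 2) or paired t maps; suprathreshold voxels (p < 0.001) split
by sign, connected components at 26-connectivity, clusters retained only
above 36 voxels (strict), labelled by the atlas region at the peak.

**Autoencoder features.** A stacked sigmoid autoencoder (three hidden
layers, geometric width schedule) trained by greedy layer-wise
pretraining plus full-batch gradient descent on the binary cross-entropy
reconstruction loss G(x,y) = −Σ[x log y + (1−x) log(1−y)], then tuned
jointly with a softmax head on training labels; code-layer activations
("fine features") are compared against raw features under softmax,
linear SVM and RBF SVM.

**Efficacy scoring.** VAS weighted value (pre − post)/pre; outcome
categories cured ≥ 75 %, markedly effective [50, 75), effective
[25, 50), ineffective < 25 %; total effective rate = fraction not
ineffective; weekly within-group paired and between-group pooled t tests,
including reconstruction of the pooled t from printed mean ± SD summaries.

## Worked example

The numbered drivers under `analysis/` run the full study flow on
synthetic data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # cohort + clinical table (NIfTI, CSV)
Rscript analysis/02_alff_maps.R    # per-subject ALFF / f-ALFF maps
Rscript analysis/03_group_stats.R  # cluster table + null calibration
Rscript analysis/04_autoencoder.R  # raw vs fine classifier comparison
Rscript analysis/05_efficacy.R     # clinical efficacy report
```

`03_group_stats.R` plants a 60-voxel region with doubled low-frequency
amplitude in the treatment group (n = 20 per group, 24×24×12 grid) and
recovers it:

```
 cluster_id size_voxels peak_i peak_j peak_k peak_x_mm peak_y_mm peak_z_mm
          1         101     15     11      4   51.5625   37.8125      20.8
   peak_t     sign     region_label
 28.43989 increase planted_region_1
recovered planted region: TRUE (1 increase / 0 decrease clusters)
voxel p<0.05 fraction 0.0564 over 816 voxels (nominal 0.05); 0 clusters
```

One suprathreshold cluster survives the extent rule, its peak lies inside
the planted region, and with no planted effect the voxel-level type-I rate
sits at its nominal 5 % with zero surviving clusters.

`05_efficacy.R` reproduces the study-style clinical comparisons from a
table drawn at the printed group summaries:

```
total effective rate: treatment 1.00, control 0.95

summary-statistic t tests from the printed group values:
  VAS week 4, treatment vs control     |t| =  16.06, df = 38, p = 1.6e-18
  sleep week 4, treatment vs control   |t| =  10.54, df = 38, p = 7.7e-13
  VAS treatment, baseline vs week 4    |t| =  22.92, df = 38, p = 7.4e-24
  sleep week 1, treatment vs control   |t| =   9.84, df = 38, p = 5.4e-12
```

A week-4 VAS of 2.3 against a baseline of 8.3 gives a weighted value of
72.3 % — "markedly effective" — and every week-4 contrast is significant
at the printed group sizes.

`04_autoencoder.R` shows the deep-feature effect on nonlinearly structured
features (XOR blobs + noise dimensions), mean held-out accuracy over 10
seeds:

```
 featureset classifier  accuracy
       fine linear_svm 0.9600000
        raw linear_svm 0.5341667
       fine    rbf_svm 0.9600000
        raw    rbf_svm 0.5400000
       fine    softmax 0.9550000
        raw    softmax 0.5491667
```

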