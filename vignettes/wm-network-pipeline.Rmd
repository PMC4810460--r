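---
title: "Working-memory network connectivity from block-design task fMRI"
author: "wmfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working-memory network connectivity from block-design task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Working-memory load engages a set of distributed cortical networks. Given
multi-subject BOLD acquisitions under an alternating 0-back/1-back digit
task, the question is whether a patient group differs from controls in (a)
the task-evoked activation of those networks, (b) the coupling of voxels
within each network (intra-network functional connectivity), and (c) the
coupling between networks (inter-network functional connectivity), after
adjusting for age, gender and education.

`wmfc` implements the complete chain: group spatial ICA with stabilized
Infomax, dual-regression back-reconstruction, tissue- and task-based
component selection, condition-specific connectivity, and covariate-adjusted
group inference with Monte-Carlo cluster-extent correction. A synthetic-data
generator with full ground truth accompanies every stage, so the chain is
testable end to end without any scanner data.

## The decomposition model

Each subject's masked run is a time-by-voxel matrix $X$. Group spatial ICA
models the temporally concatenated, PCA-reduced cohort as a mixture of $C$
spatially independent component maps $Y$ (components $\times$ voxels):

1. **Order selection.** $C$ is estimated by the minimum-description-length
   criterion on the eigenspectrum of the time-by-time covariance (voxels as
   samples), averaged across runs. The sample count entering the criterion
   is the number of in-mask voxels of a single run: averaging run spectra
   stabilizes the estimate but does not multiply the number of independent
   samples. At desk scale (hundreds to ~1000 voxels rather than the
   $\sim 5\times 10^4$ of whole-brain data) the noise eigenvalue bulk is
   wide, which makes MDL conservative for weak sources; `gica()` therefore
   also accepts an explicit `order`, and the reference analyses fix
   `order = k` of the generator, mirroring the usual practice of fixing the
   order reported by the original decomposition.
2. **Two-step PCA.** Each subject's time dimension is reduced to
   $C_1 = \lceil 1.5\,C \rceil$ principal components (a GIFT-like retention;
   only the final order is prescribed by convention), the reduced data are
   stacked across subjects, and a second PCA whitens the stack to $C$ rows.
3. **Infomax.** Natural-gradient Infomax with the logistic nonlinearity
   maximizes the entropy of the transformed sources; it recovers
   supergaussian (sparse, blob-like) spatial sources. The learning rate
   starts at 0.05 and is multiplied by 0.8 whenever the update direction
   reverses (overshoot); iteration stops when the relative weight change
   drops below 1e-7 or at 1000 iterations (then flagged unconverged).
   Gaussian sources are not identifiable by ICA; the ICASSO stability index
   exposes this.
4. **ICASSO.** The decomposition is re-run with independent seeds
   (optionally with bootstrap resampling of voxels), all estimates are
   clustered by average-linkage agglomerative clustering on
   $1-|\mathrm{cor}|$, and each cluster is represented by its centrotype
   (the member with maximal total within-cluster similarity). The stability
   index is mean within-cluster minus mean between-cluster similarity.
   Reference analyses use 10 restarts; the index is insensitive to more
   restarts once sources are well separated, and 100 restarts remain
   available where the original convention is wanted.
5. **Sign convention.** ICA signs are arbitrary; each group map is flipped
   so its skewness is positive, making maps "activation-positive" for the
   downstream positive-FC masks.

**Dual regression** back-reconstructs each subject: regressing each time
point of $X$ on the maps gives the subject's temporal components $TC$;
regressing each voxel's timecourse on $TC$ gives the subject's spatial
components $SC$. Both steps include an intercept — the common dual-regression
contract — although the textbook equations omit it; on centered data the two
agree, and a sensitivity check in the test suite exercises the zero-mean
case explicitly. Subject maps and timecourses are z-scored before any
statistic is formed, which also makes the results invariant to positive
rescaling of the group maps.

## Task design and component selection

The block design is six 0-back blocks of 11 trials alternating with five
1-back blocks of 12 trials, 2 s per trial, TR = 2 s. The instruction screen
(2 s) occupies its block's first trial slot: only with that convention does
the total duration come to $6 \times 22 + 5 \times 24 = 252$ s, i.e. exactly
126 volumes — the published acquisition length.

The canonical HRF is the standard double-gamma (peak ~5-6 s, undershoot
~16 s, undershoot ratio 1/6, 32 s support), sampled at the TR; all
parameters are configurable since only "canonical HRF" is prescribed.

Components are screened in three gates:

- **Tissue.** A maximum-probability map labels each voxel gray/white/CSF
  (ties break gray > white > CSF, logged). Each component map is correlated
  with each tissue's indicator vector; the highest *signed* correlation
  assigns the class. Only gray-matter components survive. The third tissue
  prior is treated as the CSF template (the standard third class).
- **Cerebellum.** No operational rule is prescribed for cerebellar
  exclusion, so the atlas carries an explicit cerebellum label mask and a
  component is flagged cerebellar when its correlation with that mask
  exceeds its best tissue correlation — a relative rule with no free
  threshold.
- **Task.** Each subject's component timecourse is regressed on the
  HRF-convolved 1-back-vs-0-back contrast; the across-subject mean slope is
  tested by a one-sample t-test, Bonferroni-adjusted over the candidates
  that passed the tissue gates, at adjusted p < 0.05.

## Condition-specific connectivity

Because the 0-back condition reflects attention rather than memory load,
connectivity is computed on the 1-back volumes only: the 1-back block
volumes are shifted forward by 3 volumes (6 s, the hemodynamic delay),
indices running past the end of the acquisition are truncated (never
wrapped, which would mix run boundaries), and the retained volumes are
concatenated contiguously before dual regression is re-run. The 2 s
instruction screen sits inside the shifted window; whether it should be
excluded is not specified anywhere, so it is retained and flagged here.

- **Intra-network FC** of a network is the subject's z-scored spatial map
  from this condition-specific decomposition: each voxel's value measures
  its coherence with the network timecourse.
- **Inter-network FC** is the Fisher-z-transformed Pearson correlation
  between two networks' temporal components. The matrix diagonal is stored
  as missing (atanh(1) is undefined). By default the condition-specific
  timecourses are used — they are produced in the same step — but a flag
  permits full-run timecourses, since the original description is ambiguous
  on this point.

## Group inference

- Group comparisons use `value ~ group + age + gender + education` ordinary
  least squares; the group coefficient's t is reported with Cohen's d of the
  covariate-adjusted residuals. Gender enters as a 0/1 indicator. All tests
  are two-sided at alpha = 0.05.
- The **positive-FC mask** per network is the set of voxels whose one-sample
  t across all subjects is positive and survives Bonferroni FWE at 0.05 over
  in-mask voxels (the FWE method is unspecified; Bonferroni is exact to
  implement and conservative, and random-field theory is out of scope at
  desk scale).
- **Cluster-extent correction** follows the Monte-Carlo recipe: voxel
  p = 0.01 two-sided, 1000 simulated noise fields, 6 mm FWHM smoothing,
  5 mm cluster connection radius on 3 mm voxels, cluster alpha = 0.05. With
  3 mm voxels a 5 mm radius admits face (3 mm) and edge (4.24 mm) neighbors
  and excludes corners (5.196 mm): 18-connectivity, by the literal distance
  rule. Fields are re-standardized within the mask after smoothing so the
  voxel threshold applies to unit-scale values. Because the statistic being
  thresholded is a t map with modest degrees of freedom, simulating Gaussian
  fields understates cluster sizes and inflates the realized family-wise
  error — the well-known anticonservativeness of the classic recipe. When
  the spec carries a `df`, each simulated field is instead a matched t field
  (a one-sample t across df + 1 independent smoothed Gaussian fields), which
  restores calibration; the pipeline sets `df` to the adjusted model's
  residual degrees of freedom automatically. The extent threshold k* is
  recomputed per network mask, since it depends on mask size and shape.
- **Inter-network comparisons** are covariate-adjusted t-tests per network
  pair, reported uncorrected with Cohen's d, as in the original protocol.
- **Partial correlations** between connectivity and clinical or cognitive
  scores control the same covariates; p-values use the t transform with
  df = n − #covariates − 2.

## Behavioral metrics and summary-level tests

The inverse efficiency score is mean reaction time divided by the accuracy
ratio (undefined at zero accuracy); mean RT is computed over correct trials
only, the common convention, since the protocol does not say. Demographic
and clinical variables are gated per group by Shapiro-Wilk at 0.05: normal
variables go to the pooled two-sample t-test, others to the Mann-Whitney U
with tie-corrected normal approximation and continuity correction. The 2x2
sex table uses Pearson's chi-squared without continuity correction. Both the
pooled and the Welch t are exported because published summary rows are
reproducible row-by-row with the pooled formula except for the one
heteroscedastic clinical marker (an order-of-magnitude SD ratio), which
matches Welch — the table-reproduction report therefore prints both. The
published table's patient count (20) differs from the scanned patient count
(19); behavioral n is configurable and the inconsistency is left unresolved.

## What the generator emulates — and what it does not

`simulate_cohort()` draws, per subject, mixing timecourses times shared
spatial maps plus white Gaussian noise:

- **Maps** are thresholded Gaussian blobs at well-separated, jittered
  centers (pairwise |cosine| < 0.2 by construction) rather than atlas
  shapes: orthogonality is controllable and no atlas download is needed.
  With the default k = 6, components 1-3 are task-modulated gray-matter
  networks, one component is white matter, one CSF-like, and one cerebellar,
  so every selection branch is exercised.
- **Timecourses** are AR(1) backgrounds (phi = 0.3, mimicking BOLD
  autocorrelation; the noise model is otherwise unconstrained) plus, for
  task components, the HRF-convolved 1-back regressor scaled by a per-group
  activation gain (default 0.8 control, 1.04 patient — patients activate
  more strongly, the direction reported for this population).
- **Connectivity effects.** The designated pair (2, 3) has its background
  innovations correlated so the pair's *total* timecourses hit the target
  correlation: 0.5 in controls and tanh(atanh(0.5) − 0.4) in patients, a
  0.4 drop on the Fisher-z scale. Patients additionally lose intra-network
  coupling at the strongest 30 voxels of component 1: the component's
  contribution there is scaled by 0.55 and replaced by variance-matched
  noise.
- **Behavior.** Per-trial Bernoulli accuracy (0.95 control vs 0.90 patient)
  and Gaussian RTs (600 vs 650 ms, SD 150 ms, truncated at 150 ms);
  covariates are drawn from group-typical demographic and glycemic
  distributions.

Default problem sizes are k = 6 networks on a 12 x 12 x 10 grid with an
ellipsoidal mask (~780 voxels), 10 subjects per group, 126 volumes, and
noise SD 0.8 (blob-voxel SNR around 2). Calibration studies use 400 null
cohorts and power studies 200 cohorts at the study's 20-vs-19 group sizes.

The generator does **not** emulate motion, spikes, physiological noise,
scanner drift, spatial nonstationarity, or anatomical geometry. Passing
tests therefore demonstrate the correctness and calibration of the
algorithms under the stated generative model — not robustness to real
acquisition artifacts, which preprocessing is assumed to have handled.

## Numerical choices and degenerate inputs

- Noiseless configurations are allowed (`noise_sd = 0`) and produce exactly
  rank-k runs; dual regression then inverts the generative model to machine
  precision, which the tests assert at 1e-8 relative residual.
- Zero-variance maps or timecourses are rejected with the offending
  component named, rather than silently producing NaN.
- A delay that leaves no retained volumes warns and errors downstream;
  indices are truncated at the run end.
- Perfect correlations (|r| = 1) abort the Fisher transform with the pair
  named.
- If no cluster extent attains the corrected alpha (e.g. voxel_p near 1),
  the threshold is reported as mask size + 1 and flagged unreachable.
- All randomness flows from explicit integer seeds; repeated runs are
  bit-identical, which the pipeline test asserts on the written tables.

## Known limitations

- MDL order selection is honest but conservative at desk-scale voxel
  counts (see above); supply the order where it is known.
- Bonferroni FWE for the positive-FC mask is conservative relative to
  random-field or permutation alternatives.
- The Monte-Carlo extent threshold assumes stationary smoothness inside the
  mask; anisotropic or nonstationary smoothness is not modeled.
- Inter-network power studies back-reconstruct with the generator's true
  maps, isolating the connectivity inference from ICA estimation error;
  end-to-end recovery including ICA is validated separately.
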