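---
title: "Scatter-window attenuation compensation and its task-based evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scatter-window attenuation compensation and its task-based evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctless)
```

This vignette documents the models, the numerical choices and the design
decisions behind the package, and states precisely what the synthetic
experiments do and do not demonstrate.

## 1. The imaging model

A SPECT system observes a tracer distribution $f(r)$ through projection
data in two energy windows, the photopeak $g_{pp}$ (126–154 keV) and a
scatter window $g_{sc}$ (114–126 keV); the windows are carried as
metadata only — no energy-resolved transport is simulated. The
reconstruction with attenuation compensation (AC) is
$\hat f = R_\mu\, g_{pp}$, where $R_\mu$ is OSEM with the attenuation
map $\mu$ in its system model; without AC, $R$ omits attenuation.

**Projector.** Parallel-beam, rotation-based: for each view the activity
volume enters the rotated frame by bilinear *splatting* (the adjoint of
an interpolating gather). Splatting is exactly count-conserving, which
is the property an emission projector must have — a source of $a$ counts
contributes $a$ counts to each view before attenuation. The attenuation
field, a value field rather than a density, is placed in the same frame
by bilinear interpolation; survival factors use a half-voxel self term
plus the cumulative sum towards the detector, i.e. a trapezoid rule
along the ray. The collimator-detector response (CDR) is a
distance-linear Gaussian, FWHM$(d) = 0.3\,\mathrm{cm} + 0.044\,d$,
anchored at 7.4 mm at 100 mm; it is applied per constant-depth plane.
The back-projector is the exact algebraic adjoint (gather ↔ scatter,
symmetric blur, broadcast ↔ sum), verified to $10^{-6}$ relative in an
inner-product test — OSEM requires a matched pair. Discretization error
of the attenuated line integral is about 0.4 voxel of path length, so
closed-form comparisons in the tests use a $\mu h$ product small enough
to keep that inside a 2 % band.

**Scatter window.** A surrogate, not Compton transport: the scatter
source is $q(r) = c\,\mu(r) \cdot \text{smooth}(f)(r)$ (fluence
smoothing 2.5 cm), projected without attenuation and blurred by a wide
(1 cm) sinogram kernel. The surrogate is linear in $c$ and in $\mu$,
vanishes when $\mu \equiv 0$, and reproduces the one property the method
rests on: scatter-window reconstructions show contrast between regions
of different attenuation. The default amplitude $c = 7$ was set so that
scatter-window counts are roughly 40 % of photopeak counts on the
default phantom, the order observed clinically for Tc-99m windows; the
smoothing lengths are stated relative to the desk-scale subject (which
is half scale when the grid is 32), chosen so the lung-versus-soft-tissue
contrast in the scatter-window reconstruction survives the collimator
blur and the clinical post-filter.

**Noise.** Element-wise Poisson with mean `countScale × projection`,
applied after defect insertion so defect-present and defect-absent data
are independent realizations. The default activity scale yields on the
order of $1.5\times10^5$ photopeak counts per desk-scale study (mean
≈ 5 counts per body-traversing bin), a deliberately modest count level.

**OSEM.** Classical multiplicative updates with interleaved subset view
ordering (subset $s$ holds views $s, s+S, \dots$), uniform positive
initialization, denominators floored at $10^{-12}$; 8 iterations × 6
subsets by default. With one subset the code path *is* MLEM.
Initialization and view ordering are conventions with no single standard;
the choices here are the package's own, documented in this section. Post-processing follows clinical practice: zero-phase 3-D
Butterworth filter ($|H| = (1+(f/f_c)^{2n})^{-1/2}$, order 5, cutoff
0.44 cycles/cm), then a 32 × 32 short-axis region of interest centred on
the defect centroid, clipped to $[0, x_{LV}]$ ($x_{LV}$ = maximum value
in the LV wall) and mapped affinely to $[0, 255]$. Phantoms are built
axis-aligned, so short-axis reorientation is the identity and the ROI
slice is the transaxial plane through the centroid (ties to the lower
index).

## 2. The attenuation-map estimator

Ground-truth segmentation of an attenuation volume into the six regions
uses iterated conditional modes with a Potts prior on the
6-neighbourhood: data term $(\mu_i - m_k)^2 / 2\sigma^2$ with class
means fixed at the predefined coefficients, $\beta = 1$, $\sigma =
0.005$ cm⁻¹, 10 sweeps, nearest-mean initialization. On noiseless
table-built volumes the result is exact; under Gaussian noise of sd
0.005 cm⁻¹ per-region Dice stays above 0.95.

The CT-number conversion is a bilinear model with a slope break at
0 HU, anchored at air ($-1000$ HU $\to 0$) and water
(0 HU $\to 0.15$ cm⁻¹ at 140 keV), with a reduced slope above water
(default $5\times10^{-5}$ cm⁻¹/HU); all anchors are configurable. The
map is monotone and clamps input to $[-1024, 3000]$ HU.

Map assembly is the exact piecewise-constant sum
$\hat\mu = \sum_k \mu_k \hat\Phi^k$, evaluated as a table lookup; the
predefined coefficients are the population values
$(0.13, 0.16, 0.03, 0.22, 0.09, 0)$ cm⁻¹ and ship as
`defaultCoefficientTable()`, which also carries the population mean and
sd per region used for cohort jitter.

## 3. The segmentation network

McEUN is implemented from first principles in this package (im2col +
BLAS GEMM convolution kernels in C++, backpropagation and Adam in R);
there is no deep-learning runtime underneath. Architecture, exactly as
specified: two input channels (scatter- and photopeak-window
reconstructions, each normalized to $[0,1]$ by its maximum); a
five-layer $3^3$-kernel encoder of which two layers have stride 2
(spatial /4, e.g. $64^3 \to 16^3$), filters doubling at each
downsampling; one decoder per region, each with three
{transposed conv + conv} blocks (strides 2, 2, 1; filters halving as
resolution doubles) and additive attention gates (sigmoid gating on a
leaky-ReLU hidden layer) on the skip connections from the encoder; the
six single-channel decoder outputs are concatenated and passed through a
voxel-wise SoftMax. Leaky ReLU (slope 0.1) follows every convolution
except the final logit layer. Glorot-normal weights, biases 0.03,
dropout 0.1 at the bottleneck.

The loss is the weighted per-region *binary* cross-entropy summed over
voxels and regions,
$L(\Theta) = \sum_i \sum_k w_k\,[-\Phi_i^k \log\hat\Phi_i^k
- (1-\Phi_i^k)\log(1-\hat\Phi_i^k)]$, with probabilities clipped at
$10^{-7}$; default weights are inversely proportional to region voxel
frequency, normalized to sum to $K$. Backpropagation is verified against
central finite differences on every layer type to $10^{-4}$ relative.

Training hyper-parameters are not dictated by the architecture and were
chosen for the desk scale: Adam at learning rate $10^{-2}$ on the
per-voxel mean loss, batches of 2 volumes, and a two-phase curriculum
(`trainSegmentationNetwork()`): the bulk of the optimizer steps run on 2×
mean-pooled reconstructions with majority-pooled labels, where each step
costs an eighth of full resolution, followed by a short full-resolution
fine-tune at a third of the learning rate. The network is fully
convolutional, so the same weights apply at both scales; the curriculum
roughly doubles the segmentation quality obtainable per CPU-minute in our
measurements. Because batch-normalization-free rectifier stacks land in
optimization basins of very different quality depending on the random
initialization (we measured a two-fold spread in training loss across
inits), several restarts are probed for a few coarse epochs and the
lowest-training-loss candidate continues — a best-of-restarts selection
on the training objective only.
Two desk-scale adaptations of the protocol deserve explicit mention.
First, the study configurations use *square-root* inverse-frequency loss
weights (`weightPower = 0.5`): plain inverse frequency concentrates about
two thirds of the loss on the bones region (a few hundred voxels of thin
rods), starving the large organs that the attenuation map actually needs;
the square root tempers this while still up-weighting small regions.
Second, the weight initialization uses a gain of 1.6 on the Glorot-normal
scale (`initGain`): without batch normalization, an exactly-Glorot
ten-layer leaky-ReLU stack attenuates the input signal to near-constant
activations (measured logit s.d. across voxels ≈ 0.03 at initialization),
which on a CPU step budget leaves the network stuck at the
majority-class solution; the enlarged gain restores signal propagation,
in the spirit of He-style initialization for rectifier networks. The
default `initGain = 1` keeps the exact Glorot scheme. Optional five-fold
cross-validation selects the epoch count by minimum mean validation
loss. Training is bit-reproducible for a fixed seed (single-threaded
deterministic kernels); the log records the mode.

## 4. The synthetic cohort — what it emulates, and what it does not

Each subject is built from analytic solids parameterized in fractions of
the field of view: an elliptical torso with a skin/adipose shell, two
lungs (the left one truncated by the heart), a spine and sternum, a
liver, a thin patient table, and a left-ventricular wall modelled as a
hollow truncated ellipsoid in the left-anterior chest — its mid short-axis
slice is an annulus, so angular defect sectors behave like wall
segments. Axis convention: $+x$ patient right, $+y$ anterior; hence the
LV lateral wall faces 180°, anterior 90°, inferior 270° in the
short-axis plane. Uptake defaults: soft tissue 1, lungs 0.3, bones 0.5,
liver 1.8, myocardium 12, blood pool 1 — a typical rest-study contrast.
Cohort variability draws region attenuation coefficients from the
population statistics in the coefficient table, scales torso/lung/LV
size by ±4 % (s.d.), jitters the LV position, and varies myocardial
uptake by 10 %.

Defects are angular sectors of the LV wall (full thickness, full
height): extent ∈ {30°, 60°, 90°}, severity ∈ {10 %, 25 %, 50 %},
location ∈ {anterior, inferior, lateral}; the perturbation
$d = \text{severity} \times f \times \mathbb 1_{\text{sector}}$ is
forward-projected with the subject's attenuation and subtracted from the
photopeak sinogram only — scatter-window data are returned bit-identical.
Insertion precedes Poisson noise.

What passing tests on this cohort show: that the full chain — scatter
reconstruction, learned segmentation, coefficient assembly, AC
reconstruction — recovers detection performance degraded by attenuation,
under a forward model whose physics (parallel-beam, Gaussian CDR,
surrogate scatter) is internally consistent. What they do not show:
performance on real anatomies (no XCAT-grade organs, no motion, no
obesity stratification), real Compton scatter, septal penetration, or
camera-specific effects. The synthetic study is a verification harness
for the method's logic, not clinical evidence.

## 5. The observer and the statistics

The channelized Hotelling observer uses four rotationally symmetric
frequency channels: annular indicators of radial frequency on the 32×32
DFT grid with octave spacing from 0.046 cycles/cm
(0.046/0.092/0.184/0.368/0.736), realized as real spatial templates via
the inverse DFT (radial masks are conjugate-symmetric). At 0.68 cm
pixels the top edge marginally exceeds the axial Nyquist frequency
(0.735 cycles/cm); passbands are therefore truncated to the
representable grid frequencies, and only a channel whose *start*
frequency reaches Nyquist is rejected. Features $v = U^T \hat f_{SA}$;
template $w = K_v^{-1}\Delta\bar v$ with $K_v$ the equal-weight average
of the two class covariances (ridge $10^{-8}\,\mathrm{tr}/4$ on
near-singularity); test statistics $t = w^T v$ under leave-one-out
training, computed by rank-one downdates of the class sums and scatter
matrices so the exhaustive refit is only used as a test oracle. The
default LOO excludes the sample; excluding the whole subject cluster is
available as an option (the choice is not determined by the protocol;
sample-level exclusion is the default because defect-absent replicates
are bit-identical and cluster exclusion would discard the entire class
stratum for small studies). ROC analysis is empirical
(Mann–Whitney with half tie credit); a binormal maximum-likelihood fit
was deliberately not implemented.

AUC variances account for clustering: placement values are averaged
within subject clusters and the empirical variance taken across cluster
means — with singleton clusters this is exactly DeLong. Confidence
intervals are normal-approximation, truncated to $[0,1]$; coverage is
verified by simulation. Non-inferiority uses a margin of 5 % of the
reference AUC: non-inferior iff the lower 95 % bound of the paired AUC
difference exceeds $-\Delta$ (strict). Two superiority comparisons
against the no-AC arm are Bonferroni-adjusted ($m = 2$). RMSE is the
plain root mean square; SSIM uses uniform 7³ windows on the valid
region, unbiased local covariances, $K_1 = 0.01$, $K_2 = 0.03$ on the
joint dynamic range (cross-checked against an independent reference
implementation). The bootstrap resamples clusters with replacement
(percentile CI, p by CI inversion).

## 6. Problem sizes and reproducibility

The package defaults describe the clinical protocol (64³ volumes at
0.68 cm, 30 views over 180°, OSEM 8 × 6). The test-suite and
acceptance-script studies run at the desk scale the package chose for
single-CPU execution: 32³ grids (anatomy in field-of-view fractions, so
the subject is half scale), 60 training subjects for the held-out
segmentation assessment, 20 + 20 test subjects (10 + 10 in the
acceptance script with 30 training subjects), and a defect subset
(90° extent, 50 % severity, all three locations), where the desk-scale
counts give a usable operating range. The defect-present arm of the
study crosses every test subject with every configured defect type;
defect-absent subjects contribute matching replicate entries sharing one
cluster id, mirrored from the bookkeeping of the full protocol.

Every stochastic step — cohort anatomy, Poisson realizations, weight
initialization, shuffling, dropout, bootstrap — derives from one master
seed through a deterministic child-seed scheme, and the RNG state is
isolated (`withSeed`) so library calls do not perturb user code.

## 7. Known limitations

* The scatter surrogate has no energy dependence and no down-scatter
  tail; methods whose performance hinges on scatter *spectra* cannot be
  studied with it.
* The projector's bilinear discretization leaves ~±0.4 voxel of path
  jitter in attenuated line integrals; at 0.68 cm voxels and soft-tissue
  μ this is a ~4 % per-ray effect (matched in reconstruction by the
  adjoint pairing, so it does not bias the study arms).
* Training the segmentation network on one CPU limits the schedule to on
  the order of a thousand optimizer steps; this architecture family
  (no batch normalization, one single-channel decoder per region)
  typically needs several thousand steps to segment the low-contrast
  regions (lungs, skin shell), so desk-scale segmentation quality is
  substantially below what the architecture reaches on a GPU at clinical
  scale: the large regions (muscles/organs, background, patient table)
  are recovered first, the lungs and the thin skin/bone structures last.
  The held-out Dice the desk-scale study reaches is reported by the
  acceptance script rather than asserted here.
* The LV wall is a geometric shell; no papillary muscles, no apex
  thinning, no wall-motion blur.
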