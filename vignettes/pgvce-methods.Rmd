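---
title: "Virtual contrast enhancement with a pixelwise gradient GAN: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual contrast enhancement with a pixelwise gradient GAN: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Gadolinium-based contrast agents make tumours and inflamed tissue conspicuous
on T1-weighted MRI (the "T1C" sequence), but they carry clinical risks and
add scan time and cost. Virtual contrast enhancement (VCE) aims to synthesize
a T1C-like slice from the pre-contrast T1-weighted and T2-weighted slices
alone. The two input sequences carry complementary information — fluid is
dark on T1-w and bright on T2-w, enhancing tissue sits in between — so a
faithful synthesis has to fuse both.

`pgvce` implements a paired image-to-image model for this task: a
dual-encoder U-Net generator trained with a *pixelwise normalized-gradient*
shape loss combined with a least-squares GAN (LSGAN) contrast loss, plus the
evaluation machinery (similarity and texture metrics, modality-ablation
ratios), per-patient intensity normalization with exact inverses, and a
synthetic head-phantom generator so the whole pipeline is trainable and
testable without patient data.

## The losses

For an image $x$, the forward-difference gradient at pixel $(i,j)$ is
$\nabla x_{i,j} = (x_{i+1,j} - x_{i,j},\; x_{i,j+1} - x_{i,j})$, defined as
zero where the neighbour would fall outside the image. Normalizing by the
magnitude plus a stabilizer, $n = \nabla x / (\lVert\nabla x\rVert +
\epsilon)$, discards contrast amplitude and keeps only edge geometry. The
shape loss between output $y$ and ground truth $z$ is

$$\mathcal{L}_{\mathrm{grad}} = -\frac{1}{N}\sum_{\mathrm{pixels}}
\left(n_{y} \cdot n_{z}\right)^2 \in [-1, 0],$$

minimized when every output gradient is parallel (or anti-parallel — the
square makes the loss polarity-blind) to the ground-truth gradient. Two
numerical choices matter here and are deliberate:

* **Mean, not sum.** The printed form of the loss sums over pixels; we divide
  by the pixel count so that the gradient:GAN weight ratios (10:1, 1:1,
  1:10) mean the same thing at any resolution.
* **$\epsilon$ default `1e-8`** (config-exposed). Flat regions map to a zero
  normalized gradient rather than dividing by zero, and contribute zero
  loss.

The adversarial part is a least-squares GAN with labels 1 (real) / 0 (fake):
$\mathcal{L}_D = \tfrac12\,\overline{(D(z)-1)^2} + \tfrac12\,\overline{D(y)^2}$
and $\mathcal{L}_G^{\mathrm{GAN}} = \tfrac12\,\overline{(D(y)-1)^2}$, where
$D$ returns a *grid* of patch scores and the bar is the mean over patches
and batch. The generator objective is
$\lambda_{\mathrm{grad}}\mathcal{L}_{\mathrm{grad}} +
\lambda_{\mathrm{GAN}}\mathcal{L}_G^{\mathrm{GAN}}$.

### Gradient penalty

Discriminator training is stabilized with an R1 penalty,
$\tfrac{\gamma}{2}\,\mathbb{E}_{x \sim \mathrm{real}}
\lVert \nabla_x \bar D(x) \rVert^2$ with $\gamma = 10$, applied lazily every
`gp_interval` (default 4) iterations. The penalty *value* is computed
exactly by backpropagation to the input. Its *parameter gradient* uses the
exact-direction central-difference identity: with $v = \nabla_x \bar D(x)$
held fixed, $\nabla_\theta \tfrac12\lVert v\rVert^2 = \nabla_\theta (v
\cdot \nabla_x \bar D)$, and the directional derivative is evaluated as
$[\bar D(x + \varepsilon \hat v) - \bar D(x - \varepsilon \hat
v)]\,\lVert v\rVert / (2\varepsilon)$ with $\varepsilon$ = `gp_fd_step`
(default `1e-3` on the normalized intensity scale). This needs only two
extra ordinary backward passes instead of second-order backpropagation; the
truncation error is $O(\varepsilon^2)$ along an exactly computed direction.

## Architecture

The generator is a U-Net with one convolutional encoder per modality
(3×3 convolutions, leaky ReLU, stride-2 downsampling, `depth` stages,
widths `base_width`·2^s capped at 8×), *gated additive fusion* at every
scale — each modality's feature map is scaled by a per-channel trainable
gate squashed through a logistic, then summed — and a decoder with
nearest-neighbour upsampling and skip connections from the fused encoder
features. In single-modality mode there is one encoder and fusion is the
identity. The output head is a sigmoid when training in the (0,1) sigmoid/
tanh normalization spaces and linear for z-score space.

The discriminator is a conditional PatchGAN: the candidate T1C slice is
concatenated with the conditioning input modalities and passed through
`depth` (default 3) stride-2 4×4 convolutions plus two stride-1 4×4 layers,
producing a grid of local realism scores with a 70×70-pixel receptive field
at the default depth. The fusion order and exact connectivity of the
published architecture are not fully specified in text form; the U-Net
arrangement here is one consistent reading, and all widths/depths are
config-exposed.

Both networks, their backpropagation, and Adam live inside the package (a
small define-by-run tape over `[H, W, C, N]` arrays with Rcpp/Armadillo
im2col convolutions); no external deep-learning runtime is involved, which
keeps a training run bit-reproducible for a fixed seed on a single thread.

## Training recipe

Adam with learning rate 0.0002, $\beta_1 = 0.5$, $\beta_2 = 0.999$
($\beta_2$ is the conventional default; only $\beta_1$ is prescribed), one
discriminator step then one generator step per iteration, minibatches of 4,
14,000 iterations by default. Every training sample is a *paired* (T1-w,
T2-w) input consumed simultaneously by the two encoder pathways, so each
batch automatically contains both modalities. Training aborts with a
diagnostic naming the term and iteration if any loss goes non-finite.

`shape_loss = "l1"` swaps the gradient term for a plain L1 term, giving the
L1+GAN baseline used in texture comparisons (a stand-in for the published
comparison model, which is out of scope); everything else is held fixed.

## Normalization

Per patient volume and per modality, with $\mu_x$, $\delta_x$ the volume
mean and (population) standard deviation:

* z-score: $z = (x - \mu_x)/\delta_x$;
* sigmoid: $1/(1 + e^{-z}) \in (0,1)$;
* tanh: $\tfrac12(\tanh(0.01\,z) + 1) \in (0,1)$, centered at $\tfrac12$.

The printed tanh formula has a garbled parenthesis; the form above is the
only placement consistent with its stated range (0,1) and centering at 1/2.
The slope constant 0.01 is taken literally. Fitting is per modality: the
source only says "each patient volume", and per-modality fitting avoids
cross-modality scale leakage. Inversion is algebraically exact; bounded
values are clamped to $[10^{-6}, 1-10^{-6}]$ first (with a warning) so
saturated pixels cannot produce infinite logits. Synthesized slices are
denormalized with the patient's T1C parameters — available whenever ground
truth exists; in a deployment they would have to be estimated, which the
package does not attempt.

## Evaluation metrics

MAE and MSE are plain pixel means. SSIM is computed *globally* per slice
from whole-slice means, variances and covariance (no sliding window is
involved in the printed formula), with $c_1 = (0.01 L)^2$, $c_2 = (0.03
L)^2$, $L = 4095$ — the raw dynamic range, which is why metrics are always
computed in raw space after denormalization.

The four texture metrics divide by the mean intensity $\mu$ so that
multiplying an image by a constant leaves them unchanged — texture is
intrinsic, brightness is not:

* TMSVPMI: mean per-pixel Euclidean gradient magnitude / $\mu$;
* TAVPMI: mean per-pixel L1 gradient magnitude / $\mu$ (≥ TMSVPMI always);
* TFPMI: mean Sobel gradient magnitude (Tenengrad) over the valid interior
  (one-pixel border excluded) / $\mu$;
* VFPMI: root-mean-square deviation from the mean / $\mu$ — the
  coefficient of variation.

The printed equations lose their root placements to typesetting; the
placements above are the only ones that make all four metrics
scale-invariant after dividing by $\mu$ (which the definitions explicitly
claim) and reproduce the printed orders of magnitude (e.g. VFPMI ≈ 0.08, a
coefficient of variation). Smaller values mean smoother images; a 3×3 mean
filter strictly decreases the three gradient-based metrics. No background
masking is applied anywhere — the source states none — so metric values
include air, and absolute values are not comparable to masked pipelines.

Modality ablation uses MAER/MSER/SSIMR = (single − dual)/dual: the relative
degradation when training with one input modality instead of both.

## The phantom generator

Because the patient dataset behind the published results is private, the
package ships a synthetic phantom with the statistical structure the method
assumes, not anatomical realism:

* a head-like ellipse whose size varies smoothly across slices, partitioned
  into five tissue classes by thresholding a smooth random field; each class
  has a (T1, T2) intensity signature loosely modelled on head tissue
  (white-matter-, gray-matter-, CSF-, muscle-like). Two classes share the
  same T1 signature with different T2, so the ground-truth T1C is provably
  not a function of T1 alone;
* ground truth T1C $= (0.5\,T1 + 0.5\,(4095 - T2))\cdot\mathrm{head} +
  \mathrm{gain}\cdot\mathrm{lesion}$, clamped to $[0, 4095]$: monotone in
  T1, anti-monotone in T2 (fluid bright on T2 is dark on T1C), forcing
  genuine dual-modality fusion. The mix is restricted to the head mask so
  air stays dark; an unmasked affine mix would make background bright,
  which no MRI exhibits;
* one elliptical "enhancing" lesion per patient (1–5% of the head area) in
  a random subset of slices, always at least one; it adds
  `enhancement_gain` (default 800) to T1C and a mild 20%-of-gain
  hyperintensity to T2, mimicking a tumour that is conspicuous
  post-contrast and faintly visible on T2;
* a fine-scale multiplicative texture field (amplitude
  `texture_amplitude`, default 0.05) shared by all three channels, plus
  independent additive Gaussian noise (`noise_sigma`, default 30 raw
  units). Noise is Gaussian rather than Rician for simplicity; the method
  makes no noise-model assumption.

Defaults were chosen once to resemble a plausible 3T head protocol at the
4095 dynamic range. What passing phantom tests shows: the losses, networks,
optimization, normalization and metrics interact correctly, dual-modality
fusion is genuinely required, and texture/sharpness behaves directionally
as reported. What it does not show: performance on real anatomy,
registration error, scanner artefacts, or Rician noise.

## Scaled study sizes and the reference configuration

The published experiments train 14,000 iterations on 3,051 slices of
192×192. The package's self-contained studies (tests and the acceptance
script) run the same pipeline at phantom scale: 8 phantom patients
(6 train / 2 test, a patient-wise split mirroring the 70/10 design),
64×64 slices with 2,000 iterations and batch 4 at the 1:1 loss ratio for
the learning study, and 32×32 slices with 400–1,200 iterations for the
texture-direction and modality-ablation studies. All of them are plain
arguments; the full-size configuration is just the default
`training_config()`.

The free hyperparameters of the reference configuration were selected by
pilot runs on the phantom (and then frozen): generator widths 16 (64×64
study) or 12 (32×32 studies) at depth 2; the depth-3 patch discriminator,
whose capacity proved decisive for anchoring absolute intensities (with a
depth-2 discriminator the trained model does not improve on the copy-T1
baseline); z-score normalization with the linear output head; and R1
coefficient `gp_gamma = 1`. Two further findings drove these choices. First, on
phantoms whose field of view is mostly air, the per-volume statistics are
background-dominated, so sigmoid normalization compresses all head tissue
into a narrow band near the top of the (0,1) range and starves the
adversarial intensity signal — z-score keeps tissue contrasts linear. (On
patient data, where the anatomy fills more of the frame, the published
comparison found sigmoid best; both are one config switch.) Second, the
penalty coefficient trades stability against intensity fidelity: γ = 0
collapses adversarial training outright, while γ = 10 over-regularizes the
small discriminator at this scale; γ = 1 trains stably and accurately.
The package default stays at the conservative γ = 10.

## What the phantom can and cannot show about texture

The motivation for the gradient loss is that pure regression objectives
oversmooth: a conditional-mean predictor averages away whatever part of the
target's fine-scale texture it cannot predict, so its outputs score lower
on the texture metrics than real T1C does. On the phantom this effect is
largely absent *by construction*: the multiplicative texture field is
shared by all three channels, so it is visible in the inputs and a
converged conditional L1+GAN baseline simply regresses it — its TMSVPMI
lands within about 0.01–0.02 of the ground truth, with no oversmoothing
left to detect. Only the small independent per-channel noise
(`noise_sigma = 30`) is unpredictable. The gradient+GAN model, which never
penalizes intensity error directly, tends instead to slightly
*over*-texturize (TMSVPMI above truth by 0.05–0.18 at desk scale). The
texture-fidelity comparison between the two objectives is therefore not
expected to reproduce its real-data direction on phantom data, and the
corresponding check in the test suite documents this by failing; on real
MRI, where fine texture is substantially stochastic, the comparison is the
interesting one. This is a property of the phantom's texture model, not of
the metrics or losses, which are all verified against independent oracles.

## Known limitations

* Global SSIM (per the printed formula) saturates more easily than windowed
  SSIM; values are not comparable across the two conventions.
* The R1-penalty parameter gradient is a directional finite-difference
  approximation (exact direction, $O(\varepsilon^2)$ magnitude error).
* Checkpoints are R serializations tied to the package's parameter layout.
* The phantom's tissue geometry is not anatomical; conclusions about real
  NPC data require real data.
* Registration of input volumes is assumed done upstream; the package
  neither checks nor corrects misalignment.
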