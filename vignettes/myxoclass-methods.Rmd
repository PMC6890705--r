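---
title: "Classifying myxobacterial fruiting bodies: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying myxobacterial fruiting bodies: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Myxobacteria (order *Myxococcales*: 3 suborders, 11 families, 30 genera)
aggregate into macroscopic spore-bearing fruiting bodies whose shape,
size and texture are the phenotypic key used for genus-level
identification under a stereomicroscope.  Reading that key reliably
takes years of experience.  `myxoclass` implements an automated
alternative: a small convolutional network classifies grayscale images
of fruiting bodies at the genus or suborder level, and — because the
final fully-connected softmax classifier of a small CNN is often its
weakest part — the network's feature representation can be handed to a
swappable classifier head (SVM, MLP, RBF network, boosted trees, or one
of four extreme-learning-machine variants).  The package calls this
hybrid an E-CNN.

## Preprocessing

Colour is deliberately discarded: culture conditions shift fruiting-body
colour, so it is not a reliable taxonomic feature.  Images are converted
with the ITU-R 601 luma weights

$$I_g = 0.2989\,I_R + 0.5870\,I_G + 0.1140\,I_B,$$

kept as real values, archived at 100x100 pixels (a normalisation that
absorbs differences in camera, magnification and maturity stage) and
resized to the 28x28 network input at dataset-assembly time.  Both
resizes are bilinear — the conventional default, and one that preserves
intensity bounds and monotone structure.  Intensities stay on the
`[0, 255]` scale through preprocessing; the network input layer divides
by 255, keeping optimisation inputs bounded in `[0, 1]`.  Small
collections can be expanded by random square crops (side uniform between
50% and 100% of the archive side, uniform positions, labels inherited)
taken at the archive stage.

## The network

The default architecture (configuration 3 of the three the package can
build) is four blocks of 3x3 convolution (16, 32, 64, 128 filters,
padding 1, stride 1), each followed by batch normalisation, ReLU and
2x2/stride-2 max-pooling, then one fully-connected layer and softmax.
Spatial sizes follow

$$\mathrm{out} = \left\lfloor \frac{I - F + 2P}{S} \right\rfloor + 1,$$

so the four pooling layers emit sides 14, 7, 3 and 1 on a 28x28 input;
the flooring at 7 to 3 and 3 to 1 is forced by that stated sequence.  A
convolution layer holds $(hwc + 1)n$ parameters ($+1$ for the bias).
These identities are asserted at construction and re-derived by
`cnn_architecture()`.

Training is stochastic gradient descent with momentum on the softmax
cross-entropy.  Published settings: 30 epochs, learning rate 0.01.
Where the source is silent the package fixes: momentum 0.9 (the
method's canonical default), mini-batch 32, weight initialisation
truncated-normal scaled by fan-in and drawn deterministically from the
configured seed, batch-norm stabiliser $\epsilon = 10^{-5}$.  Batch
normalisation uses mini-batch statistics during training; after the
last epoch each layer's mean and variance are recomputed over the full
training set and stored for inference, so prediction is deterministic.
The forward/backward passes are implemented as flat-matrix operations
(im2col gathers feeding BLAS products), which keeps the whole 10-fold
cross-validation of the test suite on a single CPU practical.

Features for hybrid heads are the pre-softmax fully-connected
activations — one value per class, so a 25-class model yields 1x25
features.  Pre-softmax preserves magnitude information that the softmax
normalisation would discard.

## The ELM family

An extreme learning machine is a single-hidden-layer network whose input
weights $W$ and biases $b$ are drawn randomly (here uniform on
$[-1, 1]$, the ELM convention) and never trained; with hidden output
$H_{ij} = g(w_j^\top x_i + b_j)$ (sigmoid by default) the output weights
are the ridge solution

$$\hat\beta = H^\top\!\left(\tfrac{I}{C} + H H^\top\right)^{-1} T,$$

with $T$ the $\pm 1$ one-vs-rest target coding (the coding is a package
choice; the formulation only requires $t_i \in \mathbb{R}^M$).  When
there are more samples than hidden nodes the algebraically identical
form $(\tfrac{I}{C} + H^\top H)^{-1} H^\top T$ is solved instead; the
test suite checks the two paths agree to $10^{-8}$.  Solves use a
symmetric positive-definite factorisation with a single
$10^{-10} I$-jitter fallback before raising a numerical error.

* **Kernel ELM** replaces the random-feature Gram matrix with a kernel
  matrix: dual coefficients $(\tfrac{I}{C} + K)^{-1} T$, prediction
  scores $K(X_\mathrm{new}, X)$ times the coefficients.  With an
  explicit-feature kernel this is exactly the ELM in that feature space,
  which the tests verify for linear and quadratic kernels.  The RBF
  width defaults to $1/D$.
* **Constrained ELM** draws each hidden weight from the difference
  vectors of between-class sample pairs,
  $w_j = 2(x_a - x_b)/\lVert x_a - x_b\rVert^2$ with bias
  $b_j = (\lVert x_b\rVert^2 - \lVert x_a\rVert^2)/\lVert x_a - x_b\rVert^2$,
  so each node's decision surface passes through the pair midpoint —
  the signs are fixed by that midpoint condition, and the fitted model
  records the pair behind every node so the constraint is auditable.
* **Online-sequential ELM** first fits an unregularised ELM on a
  boosting batch of at least as many samples as hidden nodes, keeping
  only $P = (H_0^\top H_0)^{-1}$ and $\beta$, then absorbs further data
  chunk-by-chunk with the recursive least-squares update
  $P \leftarrow P - P H_k^\top (I + H_k P H_k^\top)^{-1} H_k P$,
  $\beta \leftarrow \beta + P H_k^\top (T_k - H_k \beta)$.  The source
  protocol specifies only the two phases; the RLS recursion is the
  unique update consistent with its defining property — equality with
  the batch solution for any chunking — which the tests assert to
  $10^{-6}$.  It is unregularised because the boosting phase is
  described as the primitive (unregularised) ELM.

## Hybrid heads

Head hyperparameter defaults follow the published settings: MLP with one
hidden layer of three nodes (the recorded learning rate 0.3 is kept in
the specification for fidelity, but the underlying `nnet` optimiser is
BFGS and does not consume it); linear-kernel SVM with one-vs-one
multiclass (the library convention); boosted trees with library
defaults; ELM 100 nodes; CELM 20; OSELM 180 nodes with a 300-sample
boosting batch and 10 blocks; kernel ELM with an RBF kernel (its
"number of nodes" is recorded but meaningless for a kernel method, and
ignored).  The RBF-network head is a small kmeans-centres + Gaussian
design + ridge-solve classifier written here, as no installed package
provides one.  Features are fed to heads exactly as extracted;
standardisation exists as an opt-in flag.  The `softmax_baseline` head
performs no refit — it reuses the backbone's own classifier, and its
predictions are bit-identical to the plain CNN, which anchors the
hybrid machinery.

## Evaluation

All evaluation is k-fold cross-validation (k = 10 by default) with
accuracy defined as the diagonal fraction of the pooled confusion
matrix, plus per-class true/false-positive rates, precision and recall.
Folds are stratified by default: with the reference collection's class
sizes (1 to 38) an unstratified 10-fold split routinely strands whole
classes in one fold.  Classes smaller than k simply miss some test
folds; single-sample classes trigger a warning since they can never be
both trained and tested.  The headline number is pooled-confusion
accuracy; the per-fold mean is also reported since "averaged over
rounds" is ambiguous between the two.  Crucially, the backbone is
refitted inside each training fold — extracting features once from a
globally trained CNN would leak test information into the features.

## The synthetic generator

The reference image collection (322 images over the 30 genera, with
published per-genus counts from 1 to 38) is not publicly deposited, so
the package ships a renderer that emulates its structure: one
morphotype per genus distilled from the published macro-morphology key
into six shape families (sphere, sphere cluster, branched coral,
stalked tree, bean/oval, and swarm-only for genera without compact
fruiting bodies), with texture classes (hard/soft/glassy/tough) mapped
to contrast and edge sharpness, stalk and sporangiole flags, and
per-genus size ranges mapped linearly from the published micrometre
ranges onto 0.1–0.9 of the image side ("not distinguishable" sizes
default to the global median range; absolute scale is unidentifiable
from images alone).  Structured shapes are drawn no smaller than 30% of
the image side so their sub-structures (branches, stalks, cluster
members) remain expressible at raster resolution.  Illumination is a
random low-amplitude linear gradient; noise is additive Gaussian on
intensity; colour is an incidental per-channel tint carrying no spatial
information.  Generation is bit-reproducible from the profile seed.

What passing tests on these images do and do not show: the renderer
guarantees learnable shape/texture structure (a linear classifier on
mean intensity, foreground area and eccentricity separates three shape
families at 80%+), so end-to-end tests demonstrate that the pipeline
learns genuine morphology, at the study's sample sizes, under the
published training settings.  They do not calibrate absolute accuracy
on real stereomicrographs — real collections carry background clutter,
focus variation and within-genus diversity the renderer does not model —
so the published real-data accuracies are not reproduction targets
here.

The test suite exercises the full protocol at the study's scale: the
10-fold cross-validations run on a balanced three-shape-family set of
60 images per class (the class size the published subsets average), and
dimensional checks use the full 322-image class-size profile.

## Known limitations

* The CNN is CPU-bound base R; it is sized for 28x28 inputs and
  hundreds of images, not for large-scale training.
* Configurations 1 and 2 are buildable for completeness but only
  configuration 3 is the supported default.
* The crop-augmentation scheme is parameterised by crops per image; the
  reference collection's augmented subset (629 images from 313 sources)
  used an unstated scheme, so its exact counts are not reproducible.
* A sentence in the source describing "three features per image"
  contradicts its own reported 1x25 / 1x22 / 1x3 feature sizes; the
  feature length here always equals the class count, which matches the
  reported sizes (three applies only to the suborder task).
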