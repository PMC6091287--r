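# probmapreg

Two-stage 2D multimodal image registration with region-enhanced
probability maps, built for the hardest common case in image-guided
cardiac surgery: aligning an intraoperative transesophageal
echocardiography (TEE) frame to a preoperative CT slice. The two
modalities share anatomy but almost no gray-level relationship —
contrast-bright blood pools are near-anechoic on ultrasound, and speckle
scrambles the rest — so similarity metrics computed on raw intensities
routinely fail. The package is aimed at researchers in multimodal medical
image registration and at anyone who needs a testable, scriptable 2D
registration pipeline with a quantified accuracy story.

## Method

**Stage 1 — coarse.** Three corresponding valve landmarks per image
(`x,y` CSV) determine the planar affine transform exactly: stacking the
correspondences $x_r^{(k)} = T_{basic}\, x_f^{(k)}$, $k = 1..3$, in
homogeneous coordinates gives a linear system with a unique solution for
any non-collinear triplet.

**Stage 2 — fine.** Each image is replaced by its *region-enhanced
probability map*. With foreground segmentation $G$ and enhancement level
$L$ ($N = 80$ for the CT side, $M = 100$ for the TEE side), the enhanced
image is $I_h = I + L\cdot\mathbf{1}_G$ (unclipped), and the
per-intensity density

$$f(i) = \frac{\#\{\text{ROI pixels of intensity } i\}}{\#\{\text{pixels of intensity } i\}}$$

is applied as a lookup table, $P(x) = f(I_h(x))$, turning both modalities
into maps of ROI-membership probability. Normalized mutual information
$\mathrm{NMI} = (H(A)+H(B))/H(A,B) \in [1,2]$ between the fixed map and
the warped moving map is then maximized over affine (or rigid-plus-scale)
parameters by Powell's direction-set method with Brent line searches,
warm-started at $T_{basic}$. Dice overlap and RMS target registration
error (TRE, in mm of fixed-image space) quantify the result against a
reference transform.

A seeded synthetic phantom (`makePhantomPair()`) emulates the CT/TEE
modality gap — many-to-one gray-level collapse, Rayleigh speckle, fan
footprint — under a known ground-truth affine, so the whole pipeline is
testable without clinical data.

## Worked example

```r
library(probmapreg)

pair <- makePhantomPair(seed = 1)                      # pseudo-CT vs pseudo-TEE
mlm  <- perturbLandmarks(pair@movingLm, sd = 2, seed = 7,
                         shape = dim(pair@moving))     # 2 px clicking error

res <- registerMultimodal(pair@fixed, pair@moving,
                          pair@fixedMask, pair@movingMask,
                          pair@fixedLm, mlm)           # mode = "probmap"
res
#> RegistrationResult (probmap): NMI 1.5214 -> 1.8769 in 7 Powell iterations (801 evaluations)
#> Affine2D (moving -> fixed):
#>          [,1]      [,2]    [,3]
#> [1,] 0.929604 -0.193896 25.0645
#> [2,] 0.141307  1.011130 11.5392
#> [3,] 0.000000  0.000000  1.0000

evaluateRun(res, pair@movingMask, pair@tTrue)
#> EvaluationReport vs ground_truth: Dice 0.9980, TRE (RMS) 0.1339 mm over 16683 points
```

NMI rises from 1.52 at the landmark-only warm start to 1.88 at the
optimum; the recovered transform overlaps the ground-truth-warped
foreground with Dice 0.998 and mislocates ROI pixels by 0.13 mm RMS. The
same run with `mode = "intensity"` (NMI on raw gray levels — the ablation
baseline) reaches Dice 0.993 and TRE 0.63 mm, and the gap widens with
speckle strength; `runBenchmark(10)` reproduces the comparison across ten
seeded phantoms.

A command-line front end covers the same pipeline
(`inst/scripts/probmapreg-cli.R` with subcommands `simulate`, `basic`,
`probmap`, `register`, `evaluate`, `benchmark`), writing transforms as
diffable text matrices, results as JSON, and a run manifest with input
digests per output directory.

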