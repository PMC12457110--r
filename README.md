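# nlkcca

Nonlinear kernel canonical correlation analysis (KCCA) for task-fMRI
activation detection.

## What it does, and for whom

Standard task-fMRI analysis smooths each volume with a Gaussian filter and
correlates every voxel with an effective design regressor (the univariate
GLM). `nlkcca` implements the *global* alternative: the whole
time-by-voxel matrix `Y` (T x Q) is smoothed with a steerable filter bank
`A`, mapped to a T x T kernel matrix `K_Y`, and a single regularized
canonical correlation against the design kernel
`K_X = X_eff X_eff'` detects the task-related structure of the entire
image in one step:

```
r = vX' K_X K_Y vY / sqrt( vX'(K_X^2 + g K_X) vX  *  vY'(K_Y^2 + g K_Y) vY )
```

Six kernel families are supported (linear, parabolic, Gaussian, inverse
multiquadric, hyperbolic tangent, mixed hyperbolic tangent), each built
from normalized linear and quadratic Gram structures of the smoothed data.
The package's core contribution is the *back-reconstruction*: a signed
voxel-space activation map obtained from the analytic sensitivity of the
kernel matrix to the data,

```
alpha = s * sum_{t1,t2}  d(K_Y)_{t1,t2} / dY_{t1}  (vY)_{t2},
s = sign( corr(X_eff, K_Y vY) )
```

which reduces to the classical `alpha prop. A A' Y' vY` for the linear
kernel and extends it to arbitrary differentiable kernels. Around this
core the package provides hyperparameter selection by voxel-shuffling
robustness, permutation null thresholds, a matched-smoothing GLM baseline,
partial-AUC (FPR < 0.1) evaluation against ground truth or a gray-matter
mask, and a fully seeded simulation framework (2D word-mask toy model, 3D
tissue phantom, AR(1) noise, contrast-perturbation ablations).

It is intended for methods researchers in fMRI activation analysis and for
anyone who wants a self-contained, reproducible benchmark of global
kernel-based detection against the univariate GLM.

## Worked example

Simulate a 2D dataset whose active voxels spell a word (~10% of a
50 x 200 grid), with an HRF-convolved three-condition block design,
contrast `[1, -1, 0]`, and signal strength `rho = 0.035`; then compare the
GLM baseline with linear and mixed-tanh KCCA:

```r
library(nlkcca)

sim  <- simulateToy2D(dims = c(50, 200), rho = 0.035, seed = 7)
bank <- steerableBank(2)              # four 7x7 filters, FWHM 2 px overall

glm  <- glmMap(sim@dataset, sim@xEff)              # |corr| map, FWHM 2 px
lin  <- kccaActivation(sim@dataset, bank, kernelSpec("linear"),
                       sim@xEff, gamma = 70)
mix  <- kccaActivation(sim@dataset, bank,
                       kernelSpec("mixed_tanh", b1 = 0.3, b2 = 1, c = 0),
                       sim@xEff, gamma = 70)

lin$fit
#> KccaFit: r = 0.7148 (gamma = 70, T = 390)

truth <- truthMask(sim)
c(glm    = partialAUC(rocCurve(alphaValues(glm), truth)),
  linear = partialAUC(rocCurve(alphaValues(lin$map), truth)),
  mixed  = partialAUC(rocCurve(alphaValues(mix$map), truth)))
#>        glm     linear      mixed
#> 0.04070653 0.04317551 0.03998440
```

The numbers are partial AUCs at FPR < 0.1 against the ground-truth mask
(0.1 is perfect, 0.005 is chance): on this replicate the linear-kernel map
detects the activation slightly better than the matched-smoothing GLM,
and the hand-set mixed kernel sits just below it (at `delta = 0` there is
no nonlinear structure to exploit). Hyperparameters are normally not set
by hand but chosen by the voxel-shuffling robustness search
(`optimizeHyperparams()`, grids from `defaultGrid()`), which also sets
`gamma` on the scale of the mean kernel diagonal as used here;
`evaluateMap()` bundles the comparison, and
`nullThreshold()` / `glmNullThreshold()` give permutation activation
thresholds. A thin command-line interface over the same functions is
installed at `inst/scripts/nlkcca` (subcommands `simulate2d`, `fit`,
`glm`, `optimize`, `threshold`, `evaluate`, `ablation`).

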