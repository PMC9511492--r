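---
title: "Tilt-angle recovery from polarization-resolved VSFG: model, solver, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tilt-angle recovery from polarization-resolved VSFG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(vsfgorient)
```

## The physical model

Vibrational sum-frequency generation (VSFG) is a second-order process:
the detected intensity in a homodyne microscope is proportional to
$|\chi^{(2)}_{IJK}|^2$, where the lab-frame susceptibility
$\chi^{(2)}_{IJK}$ is addressed by the polarizations of the signal,
upconversion and IR beams. With the axial field component neglected
(high-NA condenser, but only in-plane fields retained), the indices run
over lab $X$, $Y$, giving eight measurable polarization combinations
(`SSS` ... `PPP`, with $S \leftrightarrow X$, $P \leftrightarrow Y$).

The molecular building block here is a supramolecule with a seven-fold
symmetry axis. For any rotational symmetry of order greater than three, a
rank-3 tensor is forced into the axially isotropic form: 13 nonzero
molecular-frame hyperpolarizability entries $\beta_{ijk}$ of which 7 are
nondegenerate,

$$\beta_{zzz},\;
\beta_{xxz}=\beta_{yyz},\;
\beta_{xzx}=\beta_{yzy},\;
\beta_{zxx}=\beta_{zyy},\;
\beta_{xzy}=-\beta_{yzx},\;
\beta_{zxy}=-\beta_{zyx},\;
\beta_{xyz}=-\beta_{yxz}.$$

Kleinman symmetry is *not* assumed. The lab frame is reached by a
$z$–$y'$–$z''$ Euler rotation with in-plane rotation $\varphi$, tilt
$\theta$ (from the surface normal) and twist $\psi$,

$$\chi^{(2)}_{IJK}(\varphi,\theta)
  = \bigl\langle \textstyle\sum_{ijk}
    R_{Ii} R_{Jj} R_{Kk}\, \beta_{ijk} \bigr\rangle_{\psi},
  \qquad I,J,K \in \{X, Y\},$$

with the twist averaged uniformly over $[0, 2\pi)$ because the subunits
have no preferred twist registry. A useful structural fact falls out of
the symbolic derivation (run once; the closed forms are frozen in
`chi_from_grouped()`): a C7 tensor carries only the $m = 0$ azimuthal
harmonic at rank 3, so it is invariant under any $z$-rotation and the
twist average equals the unaveraged tensor. The package nevertheless keeps
an independent brute-force $\psi$-quadrature oracle
(`chi_quadrature_oracle()`), and the two paths are required to agree to
better than $10^{-8}$ relative error in the test suite.

Two consequences shape everything downstream:

* **Zero-tilt annihilation.** Every nonzero $\beta$ entry carries at least
  one molecular $z$ index, which at $\theta = 0$ has no projection on the
  lab plane: all eight susceptibilities vanish identically. An upright
  film is invisible in this geometry, and orientation is unidentifiable
  there.
* **Grouping to six terms.** The twist-averaged equations depend on the 7
  components only through 6 combinations: the four achiral components and
  the chiral pairs $\beta_{xzy} + \beta_{zxy}$ and
  $\beta_{xyz} - \beta_{zxy}$. The package determines this null direction
  numerically (SVD of the stacked forward map) rather than trusting any
  printed grouping; `grouped_beta()` and `beta_from_grouped()` convert in
  both directions.

## The two-sheet inverse problem

A single sheet gives 8 magnitudes. Following the measurement design, the
solver consumes two sheets of the same material rotated by a known
in-plane offset ($\Delta\varphi = 60^\circ$ for the rhombic lattice), with
a relative coverage ratio $N$ absorbing ROI size and thickness: 16 inputs,
9 unknowns (6 grouped terms, $\varphi_1$, $\theta$, $N$).

Homodyne detection loses all signs, so the solver enumerates all
$2^{16} = 65536$ sign assignments, passes each normalized candidate
through a trained network, pushes the decoded parameters back through the
forward model, and keeps the assignment with the smallest mean squared
error between the normalized reconstruction and the candidate
(`solve_orientation()`). A global flip of all 16 signs is physically
unobservable — it is the hyperpolarizability sign convention — so
complementary patterns are scored as one equivalence class and both are
reported.

### What is actually identifiable

Implementation forced a sharper statement than "16 equations, 9
unknowns". Writing the stacked two-sheet map as a linear function of the
grouped terms, its 16-dimensional column space turns out to be **exactly
independent of the tilt**: the $\theta$-dependence factors into the
per-column scalars $\sin^3\theta$, $\sin\theta$ and
$\sin\theta\cos\theta$ that are shared by both sheets (both sheets have
the same tilt). Concretely, for any trial tilt $\theta'$ there is a
hyperpolarizability $g(\theta')$ that reproduces a given observation
*exactly*; the package's test suite verifies the subspace coincidence by
principal angles. In-plane rotation and coverage, by contrast, appear in
the column directions themselves and are exactly identifiable.

The tilt is therefore recovered *through the amplitude prior*: the
network is trained on hyperpolarizabilities drawn from a bounded box, and
it learns the posterior mean of $\theta$ given the data under that prior.
The compensating $g(\theta')$ needed to fake a wrong tilt grows like
$1/\sin^3\theta'$ in one direction and leaves the sampled box rapidly, so
the posterior is well concentrated at small and moderate tilts and
broadens as $\theta \to 90^\circ$ — which is why tilt accuracy is
quoted for the below-30° region throughout, and why the tilt figure
should always be read jointly with the independent geometric checks of
the `geometry` module.

### Sampling domains (and why they are what they are)

The generator defaults (`training_ranges()`) are frozen as the package's
study conditions:

| parameter | default | reason |
|---|---|---|
| $\beta_i$ (all 7) | $U[0, 1]$ | positive box; fixes the sign convention (see below) and concentrates the tilt posterior |
| $\varphi_1$ | $U[0^\circ, 180^\circ)$ | a global sign flip maps $\varphi \to \varphi + 180^\circ$; homodyne data determine $\varphi$ modulo $180^\circ$ only |
| $\theta$ | $U(2^\circ, 90^\circ)$ | $\theta$ and $180^\circ - \theta$ are equivalent up to the chiral sign convention; below $2^\circ$ the signal vanishes and scale-normalized targets diverge |
| $N$ | $U[0.2, 5]$ | ROI size/thickness ratios of a few, log-symmetric endpoints around 1 |
| $\Delta\varphi$ | $60^\circ$ | rhombic lattice of the sheets |

The forward map is odd under a global $\beta$ sign flip
($\chi(\varphi,-\beta) = \chi(\varphi + \pi, \beta)$) and odd in the
chiral components under $\theta \to \pi - \theta$. With a sign-symmetric
prior (e.g. $U[-1,1]$) every observation would sit at the intersection of
two equally likely branches and the regression target would not be a
function of the input — interval indicators become coin flips and the
mean-squared-error optimum is the useless branch average. The positive
box removes the branch intersection entirely (the flipped branch is
component-wise negative, bounded away from the sampled family), makes the
input-to-output map single-valued *and continuous* on the closed domain,
and is the natural reading of "randomly generated" amplitudes. The
11-value output encoding keeps two binary interval-indicator slots
($\varphi$ in the upper half-turn, $\theta$ in the upper quadrant); under
the default domains they are constant, and they become informative if a
user widens the angle domains together with a sign-breaking prior.

### Output encoding

Each training row is `16 inputs + 11 outputs = 27` values. Inputs: the
two signed susceptibility 8-vectors (sheet 2 scaled by $N$), jointly
normalized to unit Euclidean norm — only ratios are measurable, and $N$
is the only carrier of relative scale. Outputs: the 6 grouped terms
normalized to a unit 6-vector (the overall amplitude is not identifiable
from normalized inputs, so the unit representative is the unique
deterministic target), $\varphi_1$ and $\theta$ in radians folded into
their base intervals, $N$, and the two indicator bits. Every stored row
satisfies a strict round trip: decoding the outputs and re-running the
forward model reproduces the input row to $< 10^{-10}$ (tested).

## The network and its training recipe

The regressor is a fixed 200–100–50 feed-forward network with hyperbolic
tangent activations between layers and a linear 11-wide output, trained
by minibatch Adam on mean squared error with batch size 100 and a 90/10
train/validation split (the validation fraction is the trailing part of a
seeded shuffle). The reference recipe draws 100,000 forward-model
samples. Where the original description is silent the package fixes:
Glorot-uniform initialization, Adam with step size $2\times 10^{-3}$
decayed geometrically per epoch, and seed-pinned shuffling — all recorded
in the saved model manifest. Training aborts on non-finite loss.

Problem sizes are chosen so the standard runs complete in minutes on one
core: the bundled acceptance script trains the 100,000-sample set for a
600-epoch schedule (losses plateau well before the end of the schedule;
doubling the epochs changes the test-set angle errors only marginally),
and the test suite uses 20,000-60,000-sample runs for smoke-level checks.
The training loop itself is compiled (RcppArmadillo).

## Spectra, images, and the synthetic scene

The lineshape model is a constant baseline plus Voigt components added in
intensity; interference cross-terms between resonances and any
non-resonant phase are deliberately out of scope. The Voigt profile is
evaluated through a 64-term rational approximation of the Faddeeva
function (accurate to ~$10^{-13}$, tested against direct numerical
convolution), and fits use Levenberg–Marquardt with box constraints. The
analysis band is the CH$_2$ asymmetric stretch at 2910 cm$^{-1}$ with
companions at 2860/2930/2960 cm$^{-1}$; $|\chi|$ is taken as the square
root of the fitted 2910 peak *height* (amplitude is stable under
width-parameter correlations, and only cross-polarization ratios matter
after normalization).

The synthetic scene generator renders rhombic sheets on a pixel grid;
each sheet's per-pixel spectrum is the multipeak lineshape scaled by
$|\chi|^2$ for its orientation, overlaps add in intensity, and additive
Gaussian noise is calibrated so the mean per-pixel 2910-peak signal over
the sheet mask meets a target SNR (CCD shot noise at high counts is
approximately Gaussian). What the generator does *not* emulate — optical
point-spread functions, scanner geometry, detector nonlinearity, Fresnel
and local-field factors, dispersion of $\beta$ — bounds what passing
tests show about real data: they validate the analysis chain, not the
microscope. Segmentation is seeded k-means on L2-normalized pixel
spectra; any deterministic clustering meeting the same ground-truth-IoU
property would do.

## Numerical choices and degenerate inputs

* Angles are radians internally; degrees appear only at file/CLI
  boundaries. Reported tilt is folded into $[0^\circ, 90^\circ]$;
  reported $\varphi_1$ is modulo $180^\circ$.
* Decoded candidates are clamped to the physical domains
  ($\theta \in (0, 90^\circ)$, $N > 0$) before re-running the forward
  model during sign scoring.
* Ties among sign patterns are broken by lowest pattern index and all
  tied indices are reported; the global-flip partner of the winner is
  always reported as equivalent.
* All-zero observations are rejected (the $\theta = 0$ family is
  unidentifiable); flat spectra are rejected by the fitter; empty ROI
  masks are errors.
* The tilt-from-heights check refuses $h_{\mathrm{obs}} > h_{\mathrm{up}}$
  (no real solution). The steric classifier is a rigid-cylinder gap model
  `lattice * cos(tilt) - diameter` with thresholds calibrated once
  (effective diameter 1.25 nm on the 1.52 nm lattice) to reproduce the
  qualitative picture: feasible near 20°, tight at 30°, colliding at
  45-60°; it is a plausibility check, not an energy model.

## Known limitations

* Tilt is prior-identified (see above); its honest uncertainty at large
  tilt is much wider than at small tilt, and runner-up sign patterns
  should be inspected (`solve_orientation()` returns them ranked).
* The sign enumeration is exhaustive but the network is only trained on
  the positive-box family; sign patterns whose best explanation lies far
  outside that family are scored against an extrapolating network and
  rank accordingly.
* Voigt fits share no parameters across polarization combinations by
  default; optional sharing is limited to fixing centers.
* The experimental headline numbers of the original study (tilt
  $23 \pm 1.5^\circ$ at minimal susceptibility MSE 0.02) require the
  study's supplementary susceptibility tables, which are not
  redistributable here; the package's synthetic round trips are the
  property-level stand-in.
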