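---
title: "Cross-matching: a rectified correlation model of stereo correspondence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-matching: a rectified correlation model of stereo correspondence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(stereomatch)
library(dplyr)
```

## The model

Binocular neurons and observers must solve the stereo correspondence
problem: which piece of the left eye's image goes with which piece of the
right eye's. For random-dot stereograms (RDSs) — ternary contrast images
$I_L, I_R \in \{-1, 0, +1\}$ (bright dot, background, dark dot) — the
classical window-based solution is the **cross-correlation** at a window
(receptive-field) disparity $d$:

$$C(d) = \left\langle \frac{1}{k} \sum_{(x,y) \in W} I_L(x,y)\, I_R(x-d,y)
\right\rangle,$$

with $W$ a $k$-pixel window and $\langle\cdot\rangle$ the expectation over
independently refreshed dot patterns. Cross-correlation signals the
disparity of correlated RDSs but inverts for anticorrelated RDSs (every dot
contrast-reversed between the eyes) and is blind to half-matched RDSs (half
the dots reversed). Human depth judgments do neither, so the package's
central object is the **cross-matching** operator, which half-wave-rectifies
each pixelwise product before averaging:

$$M(d) = \left\langle \frac{1}{k} \sum_{(x,y) \in W}
\left[ I_L(x,y)\, I_R(x-d,y) \right]^+ \right\rangle.$$

$M$ simply counts the fraction of window pixels forming contrast-*matched*
dotted combinations. A pixel pair at the aligned disparity is matched,
reversed or background with probabilities
$p = \big((1+c)\rho/2,\ (1-c)\rho/2,\ 1-\rho\big)$, where $\rho$ is dot
density and $c$ binocular correlation; at any other disparity
$p = (\rho^2/2, \rho^2/2, 1-\rho^2)$. Window compositions are trinomially
distributed, which gives everything in closed form:

* signal strength (peak minus baseline) of cross-correlation:
  $S_C = c\rho$, odd-symmetric in $c$;
* signal strength of cross-matching:
  $S_M = (c+1)\rho/2 - \rho^2/2$, with zero contour $c = \rho - 1$ and, at
  $c = 0$, a maximum at 50% density;
* the **generalized cross-matching** $G(d)$ rectifies *after* averaging
  over $k$ pixels; its expected signal strength is computed by exact
  trinomial enumeration over $(n_m, n_r)$. $k = 1$ recovers $S_M$ and
  $k = \infty$ the rectified cross-correlation $[c\rho]^+$.

```{r surfaces}
signal_surface("matching") |> autoplot()
signal_strength_generalized(c = 0, rho = 0.5, k = 2)
```

Cross-matching is also exactly equivalent to an ON/OFF-channel model that
rectifies monocular contrast first,
$[I_L]^+[I_R]^+ + [-I_L]^+[-I_R]^+$: `onoff_cross_matching_frame()` and
`cross_matching_frame()` agree bit-for-bit on every ternary input, which the
test suite checks exhaustively for small windows.

## Stimuli

`generate_rds()` draws the standard stimulus: a 32 × 32-px central square
carrying the disparity plane inside a 34 × 34-px surround, per-pixel
Bernoulli($\rho$) dots, bright/dark with equal probability, each dot
contrast-reversed in the right eye with probability $(1-c)/2$. Per-pixel
independent placement makes the trinomial theory exact rather than
approximate, which is why we prefer it to fixed dot counts.

Two geometry choices were genuinely open and are settled here:

* **Symmetric disparity split.** Disparities (stimulus and window alike)
  are applied as a left offset of $\lfloor d/2 \rfloor$ px and a right
  offset of $\lfloor d/2 \rfloor - d$ px. A one-sided shift cannot work:
  with a 34-px surround, a 32-px window at disparity $+2$ would leave the
  image. The split uses the 2-px slack symmetrically so that both the
  crossed (−2 px) and uncrossed (+2 px) configurations fit, and the window
  at disparity $d$ exactly overlays a square of stimulus disparity $d$.
* **Correlated surround.** The surround is a zero-disparity, perfectly
  correlated dot field of the same density — the usual fusible reference in
  psychophysical displays. Misaligned detector windows therefore read a few
  surround columns; those columns pair independent dots and so leave the
  $\rho^2/2$ baseline unchanged.

The sign convention is that sampling $I_R(x-d, y)$ against $I_L(x, y)$
peaks at $d = d_s$; negative disparities are crossed (near). Right-eye
*content* is therefore displaced by $-d_s$ relative to the left.

For the energy-model experiments, `generate_dot_rds()` throws 8 × 8-px dots
(0.14°) at uniformly random positions on a 24 × 24-px field,
`round(ρ · area / dot area)` of them, later dots overwriting earlier ones
and border dots cropped — a windowed view of a larger dot field. Dot and
field sizes are standard for this stimulus class but no placement rule is;
uniform placement with overwrite is the simplest reproducible choice, and
density is calibrated as expected coverage before overlap.

## Variability of the differential signal

Psychophysical decisions rest on the *differential* signal of a near
detector ($d = -2$) and a far detector ($d = +2$), both $k = 1024$.
`sd_surface()` simulates its standard deviation over 1000 fresh patterns
per cell of a correlation × density grid and averages 200 runs (tests and
the acceptance script use 20 runs; the mean of per-run SDs is unbiased
enough at 1000 patterns that more runs only polish the third decimal). The
two windows share right-eye pixels, so their covariance is included
naturally — no independence approximation. The analytic per-pixel oracle
($\sqrt{2 \cdot \mathrm{Var}} / 32$, maximal at $c = 0$, $\rho = 1$) puts
the expected maxima near $\sqrt2/32 \approx 0.044$ for cross-correlation
and $\sqrt2/64 \approx 0.022$ for cross-matching, about 1/20 of the
operators' dynamic ranges.

`operator_distribution()` complements this with the exact single-window
pmf; its 95% interval is the equal-tail cut that leaves at most 2.5%
strictly outside each end (boundary atoms included, so coverage is at least
95% on the discrete support — the convention is ours, as highest-density
intervals are ill-defined for lattice distributions).

## Simulated near/far psychophysics

`psychometric_curve()` simulates two-alternative forced choice: per trial,
16 independent frames, detector outputs averaged over frames, one Gaussian
noise draw (SD 0.1 by default) added to the near − far difference, choice
by sign (exact ties by fair coin; with continuous noise they have measure
zero). Each point pools 1200 trials — 30 crossed + 30 uncrossed per block ×
20 blocks; the blocks are bookkeeping only since trials are independent.
The single noise draw per trial (rather than per frame or per detector)
mirrors a decision stage that corrupts the pooled decision variable once.

The matching model yields the match-based signature: performance near (in
fact slightly below) chance at $c = -1$ for 25% density, well above chance
for half-matched RDSs, and a chance-crossing at $c = \rho - 1$ that is
invariant to the noise SD (checked over 0.025–0.2) because the noise is
symmetric about the zero-signal contour. The correlation model is
odd-symmetric about $(0, 50\%)$. With density 100% the two models coincide,
since $S_M(c, 1) = c/2$ is proportional to $S_C$.

```{r psych, eval = FALSE}
cfg <- decision_config(seed = 1)
density_sweep("matching", cfg = cfg) |> autoplot()
```

## Threshold energy model

The same decision stage can be driven by disparity-energy detectors:
quadrature pairs of Gabor simple cells (envelope SD 0.05°, position
disparity ±0.14° split between the eyes) on the dot-based RDSs, binocular
summation then squaring, subunits summed. The *threshold* energy model
subtracts the monocular components to isolate the binocular interaction
($2\sum \langle RF_L, I_L\rangle \langle RF_R, I_R\rangle$) and half-wave
rectifies it at zero. When the dot size is comparable to the receptive
field — 8 px vs a 2σ diameter of ~5.7 px — the threshold-energy
psychometric family reproduces the cross-matching pattern: below-chance
performance at $c = -1$ that deepens with density, and a chance-crossing
that rises with density.

Two detector parameters are genuinely free and are exposed in
`gabor_params()`:

* **Carrier frequency** (default 10 cycles/°, one cycle per 2σ): any
  stereo-plausible band-pass value preserves the qualitative behavior.
* **Amplitude** (default 14): detector responses are raw inner products of
  unnormalized Gabors with ternary images, and the prescribed decision
  noise is σ = 1000, so the gain is chosen once to put the frame-averaged
  differential on the order of that noise (a few thousand at full
  correlation, 25% density) — the same signal-to-noise calibration logic
  used to pick σ = 0.1 for the pixel detectors. It scales both detectors
  equally, so it cannot move a chance-crossing.

## Numerical choices and problem sizes

* Trinomial probabilities go through `stats::dmultinom()` in log space;
  enumeration of $E[[n_m - n_r]^+]$ marginalizes the background count and
  costs $O(k^2)$, exact up to $k = 1024$ and beyond.
* Heavy RDS simulation (frame generation plus window sums) is compiled
  code sharing one code path with `generate_rds()`; the test suite checks
  they are bit-identical under a common seed. All randomness flows through
  R's RNG, so `set.seed()` reproduces every result, including compiled
  ones.
* Default analysis grids are $c \in \{-1, -0.9, \dots, 1\}$ and
  $\rho \in \{0.05, \dots, 1\}$; the variability surface uses 1000
  patterns × 20 runs per cell in tests and the acceptance script (the
  package default remains 200 runs). Tuning-curve demonstrations use a few
  hundred frames at reduced geometry; convergence tolerances are 3
  Monte-Carlo SEs throughout.

## What the generator does and does not emulate

The synthetic stimuli realize the idealized study conditions exactly:
ternary contrast, per-pixel independence, geometrically perfect disparity
planes, and frame-independent refresh. Real displays and real observers add
luminance calibration error, spatial blur, fixation jitter, vergence noise,
temporal integration beyond simple frame averaging, and lapses — none of
which are modelled. Passing tests therefore validate the computational
claims (operator identities, closed forms, signature patterns of the
psychometric families), not quantitative agreement with any particular
observer's thresholds.

## Known limitations

* Sub-pixel disparities and antialiased dots are out of scope; disparities
  are integer pixel shifts.
* The analytic variance of the near/far covariance is not derived; the
  variability surface is simulation only.
* Odd-symmetric (phase-disparity) energy units, multiple spatial-frequency
  channels, and peak-decoding readouts are not implemented.
* `estimate_zero_crossing()` interpolates linearly between the first
  bracketing pair of levels; very noisy curves can in principle cross more
  than once, and only the first crossing is reported.
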