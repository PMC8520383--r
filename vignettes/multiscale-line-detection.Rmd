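---
title: "Multi-scale line detection of retinal vessels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale line detection of retinal vessels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retline)
```

## The problem and the model

Retinal blood vessels are imaged non-invasively in color fundus photographs,
and changes in their width, angle and branching inform the diagnosis of
diabetes, glaucoma and hypertension. The vessel network is tree-like; the
thin distal branches (about 3–4 px wide at typical resolutions) have low
contrast against the background and blurred boundaries, and they are what
segmentation algorithms most often miss. Thick vessels run 7–8 px.

`retline` segments vessels with an *oriented line detector*. The working
image is the inverted green channel $I_{igc} = 1 - G$ (green carries the
highest vessel/background contrast; inversion makes vessels bright). At each
pixel $P$, with $W = 15$:

$$R_L(P) = \max_{\theta} \; \bar I_{L,\theta}(P) \; - \; \bar I_W(P),$$

where $\bar I_{L,\theta}$ is the mean intensity along a centred discrete
line of length $L$ at orientation $\theta$ (12 orientations, $15^\circ$
apart) and $\bar I_W$ the mean over the $15\times15$ window. When the line
aligns with a vessel through $P$, the line mean exceeds the window mean and
the response is positive. Because the line *mean* wins rather than the
centre pixel, the detector tolerates the bright central reflex of large
vessels. A single scale $L = 15$, however, merges adjacent parallel vessels
and dilates crossings; running all odd scales $L \in \{1, 3, \dots, 15\}$
and averaging repairs both.

The refinement implemented here preprocesses differently per scale group.
Small scales ($L < 9$, matched to thin-vessel widths) are detected on a
*locally* enhanced image $I_1$; large scales ($L \ge 9$) on a *globally*
enhanced image $I_2$. Each per-scale response is standardized to in-FOV mean
0 / sd 1 and the final map is the equal-weight linear fusion

$$F(P) = \frac{1}{n_S + n_G + 1}\Big(\sum_{L \in S} R^{I_1}_L(P)
        + \sum_{L \in G} R^{I_2}_L(P) + I_{igc}(P)\Big),$$

with the un-enhanced inverted green channel occupying the extra slot (it
keeps vessel interiors bright where all line responses are weak). With the
default split ($n_S = n_G = 4$) the divisor is 9, exactly the all-scales
baseline $\frac{1}{n_L+1}(\sum_L R_L + I_{igc})$ that the split mode is
compared against. Setting the large group empty makes `fuse_split()`
reproduce `fuse_baseline()` identically, which the tests assert.

### Enhancement

*Local* (feeds small scales): for each pixel, with $m$ and $\sigma$ the mean
and population standard deviation over a $5\times5$ neighborhood,

$$f = m + A\,(x - m), \qquad A = \min\!\Big(\frac{C}{\sigma + s},\,
\mathrm{cap}\Big),$$

clipped to $[0,1]$. The gain grows where the neighborhood is uniform —
precisely where faint thin vessels hide. *Global* (feeds large scales):
$f_x = g_{mean} + (1 + c_g)(f - g_{mean})$ about the in-FOV mean, which
stretches global contrast and suppresses smooth illumination bias.

The published description of this method names the symbols and the
monotonicity of both transforms but its equations are not printed in a
machine-readable form; the algebraic forms above are the natural ones
consistent with every stated property, and both are isolated behind
`local_enhance()` / `global_enhance()` so an alternative form is a drop-in
replacement.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| detector window $W$ | 15 | px | background mean; fixed across scales |
| orientations | 12 × 15° | — | covers 180° at line-width resolution |
| scales | 1,3,…,15 | px | odd lengths up to $W$ |
| scale split | `{1,3,5,7}` / `{9,11,13,15}` | px | thin vessels are 3–4 px, thick 7–8 px |
| local window | 5 | px | just wider than a thin vessel |
| local $C$ | 3 | — | gain numerator on the $[0,1]$ scale |
| stabilizer $s$ | $10^{-4}$ | — | keeps the gain finite as $\sigma \to 0$ |
| gain cap | 5 | — | bounds noise amplification on flat regions |
| global $c_g$ | 1 | — | doubles contrast about the mean |
| threshold $q$ | 0.104 | fraction | vessel density of an expert annotation of a standard 20-image retinal database (first expert; the second annotates 14.9%) |

$C$ and $c_g$ are described in the source method only as empirical values
and never printed; the defaults here were fixed once on the $[0,1]$
intensity scale and are exposed as arguments. The gain cap is this
package's addition: without it $C/(\sigma + s)$ explodes on flat regions.
Thresholding is likewise unspecified upstream; the default marks the top
$q = 0.104$ of in-FOV response values as vessel so the predicted vessel
area matches the typical true area, with Otsu and fixed thresholds as
alternatives, and `threshold_sweep()` for operating-point studies.

## Numerical choices

* **Intensities** live in $[0,1]$ (8/16-bit inputs normalized on load);
  every enhancement clips back into $[0,1]$.
* **Coordinates** are 0-based in concept, stored 1-based in R matrices,
  `(row, col)` with row 1 at top; orientation $\theta = 0$ points along
  columns (a horizontal vessel), increasing counter-clockwise.
* **Borders**: all window and line means use symmetric reflect padding
  (edge pixel included). FOV-restricted means are a documented alternative
  left unimplemented; reflect padding avoids dark rims that would fire the
  detector along the FOV boundary.
* **Line discretization**: offsets are $\mathrm{round}(k(-\sin\theta,
  \cos\theta))$, $k = -\frac{L-1}{2},\dots,\frac{L-1}{2}$. Products within
  $10^{-9}$ of a half-integer are snapped to it before rounding so that the
  kernel set is exactly closed under 90° rotation despite floating-point
  trig. Rounding collisions are resolved by nudging $k$ along the line in
  0.25 steps (smallest magnitude first, positive first), applied to $k > 0$
  and mirrored, so kernels always contain the origin, are symmetric under
  negation, and hold exactly $L$ distinct pixels.
* **Standard deviations** (local enhancement, standardization) use the
  population denominator.
* **Ties at the threshold** count as vessel; the quantile threshold is the
  $k$-th largest in-FOV value with $k = \max(1, \mathrm{round}(q\,n))$, so
  with distinct values exactly the top-$q$ fraction is selected.
* **Degenerate inputs**: images smaller than $32\times32$ are rejected (a
  $15\times15$ window is meaningless there); zero in-FOV variance makes
  standardization and Otsu fail loudly with the offending scale named.
* **Skeletonization** is Zhang–Suen thinning (8-connected, component-count
  preserving); connected components use an 8-connected labelling written
  for this package because the available image library labels
  4-connectedly.

## The phantom generator

`phantom_spec()` / `phantom_generate()` build synthetic fundus images with
exact ground truth: a smooth planar illumination ramp on a mid-gray
background, straight tubular segments of stated width whose green intensity
drops by `contrast` (rectangular cross-section, antialiased across the
width, hard-cut along the length so axis-aligned pixel counts are exact),
an optional bright central-reflex stripe, i.i.d. Gaussian noise from a
recorded seed (the caller's RNG stream is left untouched), and a circular
FOV outside of which the frame is near black. Truth marks pixels whose
clean vessel coverage exceeds one half — so a width-3, length-40 horizontal
vessel contributes exactly 120 truth pixels.

`phantom_suite()` fixes six named, noise-free fixtures: `thin` (five
width-3 spokes), `thick`, `parallel` (two width-3 vessels with a 4-px
edge-to-edge gap — the merging failure mode), `crossing` (two width-5
vessels at 90° — the dilation failure mode), `reflex`, and `gradient`
(strong illumination ramp). Every fixture carries vessel density near 10%
of the FOV, matching the 10.4% density of real expert annotations; this is
a modelling decision, not a tuning knob — with a fixed top-10.4% threshold,
a phantom with unrealistically sparse vessels would force a floor of false
positives no detector could avoid. `phantom_mixed()` adds Gaussian noise
(sd 0.02, about an eighth of the thin-vessel contrast) over four thin
spokes plus one thick chord for the split-vs-baseline comparisons.

What the phantoms do *not* emulate: curvature, calibre tapering, branching
topology, the optic disc and macula, lesions, JPEG artifacts, and
spatially correlated sensor noise. Passing the phantom suite therefore
demonstrates the detector's geometric behaviour (orientation selectivity,
scale selection, non-merging, non-dilation) under controlled conditions; it
does not certify benchmark accuracy on real databases, which additionally
depends on the unpublished enhancement constants and threshold rule of the
original study and on expert-annotation idiosyncrasies.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on
96×96 (and 64×64) phantoms with a 42-px (27-px) FOV radius, brute-force
per-pixel oracles on 32×32 seeded random images, and ten noisy phantoms for
the matched-FPR comparison — sizes at which the brute-force oracles remain
exact cross-checks of the vectorized code. Every stochastic draw flows from
an explicit seed; a fixed configuration yields bit-identical masks across
runs, which the pipeline tests assert at the PNG byte level.

## Known limitations

* Validated on synthetic phantoms and healthy-retina assumptions only;
  diseased retinas (low contrast, heavy noise) are untested territory.
* The enhancement equations are reconstructions (see above); absolute
  response values will differ from the original study even where rankings
  agree, and its printed STARE/DRIVE figures are not reproducible without
  its unpublished constants.
* Line kernels are straight; strongly curved vessels at large $L$ are
  summarized by their chord.
* No morphological cleanup is applied after thresholding, by design: small
  spurious components would otherwise mask detector regressions in tests.

```{r example, eval = FALSE}
ph <- phantom_suite(seed = 1)$thin
seg <- segment_vessels(ph$image, ph$fov, mode = "split")
segmentation_metrics(confusion_counts(seg$mask, ph$truth, ph$fov))
```
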