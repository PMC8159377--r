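---
title: "Measuring flagellar energy budgets from beating patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring flagellar energy budgets from beating patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagpower)
```

## The physical model

A sperm cell tethered at its head beats in a plane close to a glass wall. We
model the body as an inextensible planar Kirchhoff rod: its geometry at any
instant is fully described by the tangent angle $\psi(s,t)$ along the arc
length $s \in [0, L]$, with curvature $C = \partial\psi/\partial s$ and local
rotation rate $\omega = \partial\psi/\partial t$, which satisfy the
compatibility relation $\partial\omega/\partial s = \partial C/\partial t$.

The head region ($s \le s_N$, with $s_N = 0.1L$) is rigid and rotates about
the tether; the tail is a passive viscoelastic (Kelvin–Voigt) rod driven
internally by unknown motor torques. The passive bending moment is
$M = \kappa(s)\,C + \eta(s)\,\partial\omega/\partial s$, with stiffness
$\kappa$ and internal friction $\eta$ scaling as the fourth power of the
local radius along the linear taper $a(s)$ from $a_N = 0.57\,\mu m$ at the
neck to $a_T = 0.18\,\mu m$ at the tip. Hydrodynamic resistance follows
resistive force theory for a slender body moving parallel to a wall at
distance $h = a_N$: $\zeta_t = 2\pi\mu/\ln(2h/a)$ and $\zeta_n = 2\zeta_t$.

Energy conservation at each cross-section gives the motor power density by
closure,
$$ p_a = \dot\varepsilon - p_s - p_{hd} - p_{id}, $$
where $\dot\varepsilon = \kappa C\,\partial C/\partial t$ is the elastic
storage rate, $p_{hd} = \mathbf v\cdot\mathbf f_h \le 0$ the hydrodynamic
dissipation, $p_{id} = -\eta(\partial\omega/\partial s)^2 \le 0$ the passive
internal dissipation, and
$p_s = \partial(\mathbf v\cdot\mathbf F)/\partial s +
\partial(\omega M)/\partial s$ the stress-power flux, with
$\mathbf F(s) = \int_s^{s_T}\mathbf f_h\,ds'$. The negative part of $p_a$,
integrated along the tail, is power dissipated *inside the motors* when the
moving filament drives them backwards; the positive part is the motor input
proper. Everything on the right-hand side is measurable from the movie.

## Parameters that matter

| parameter | default | unit | note |
|---|---|---|---|
| $\mu$ | 1e-3 | Pa s | aqueous medium |
| $\kappa_N$ | 7e4 | Pa um^4 | geometric mean of published bull/rat values |
| $\eta_N$ | 1e3 | Pa s um^4 | scaling estimate; 0 is allowed and supported |
| $a_N$, $a_T$ | 0.57, 0.18 | um | linear taper; $h = a_N$ |
| $s_N$, $s_T$ | 0.1, 0.85 | of $L$ | neck; largest arc imaged in every frame |
| $P$ | 20 | – | Chebyshev order of the tail fit |
| $M$ | 4 | – | shape modes used downstream (captures >= 95%) |

Regions: mid-piece $s/L \in [0.1, 0.3]$, principal piece $[0.3, 0.85]$.
Internal unit system is Pa–um–s; integrated powers are reported in fW
(1 Pa um^3/s = 1e-3 fW), converted exactly once at reporting.

## Numerical design

**Constrained Chebyshev fit.** The imaged tail is mapped to $\xi\in[-1,1]$
and fitted per frame by a degree-20 series minimizing the Chebyshev-weighted
mean-square error subject to three constraints at $\xi=-1$ (value, first and
second derivative matching the rigid head across the neck, with the
$(s_T-s_N)/2$ chain factors). Because the basis is discretely orthogonal at
the Gauss–Chebyshev nodes, the objective is diagonal in coefficient space and
the KKT system solves in closed form; the boundary rows use
$T_k(-1) = (-1)^k$, $T_k'(-1) = (-1)^{k+1}k^2$,
$T_k''(-1) = (-1)^k k^2(k^2-1)/3$. A dense null-space quadratic-programming
oracle in the test suite confirms the minimizer to 1e-8. Samples are carried
from the uniform arc grid to the nodes by cubic interpolation.

**Normalization constants.** Two requirements pin the basis normalization:
the discrete transform must reproduce polynomial data sampled at the nodes,
and the rescaled polynomials $\tau_k = T_k/\sqrt{\gamma_k}$ must be
orthonormal under the Chebyshev weight. Both force the continuous norms
$\gamma_0 = \pi$, $\gamma_{k>0} = \pi/2$; both properties are asserted by
tests. With $\alpha_k = \sqrt{\gamma_k}\,a_k$, coefficient space is Euclidean
and the POD eigenproblem reduces to diagonalizing the $(P+1)\times(P+1)$
covariance of $\alpha$ — this is what makes the decomposition's spectral
identities (variance sum, reconstruction error) exact rather than approximate.

**Derivatives.** Spatial derivatives use the Chebyshev derivative recurrence
(exact for the representation); shape-coefficient rates use second-order
central differences (one-sided at record ends). The stress-power flux is
differentiated by fourth-order finite differences on the uniform grid because
$\mathbf v\cdot\mathbf F$ is not polynomial. Arc integrals are composite
trapezoids; the motor split applies the same weights to the pointwise
negative/positive parts, so $P_{md} + P_{mi} = \int p_a$ holds exactly.

**Truncation at the imaged end.** Data end at $s_T < L$; the force resultant
is integrated only to $s_T$ (a free imaged end), and the contribution of the
non-imaged distal piece is neglected. Consequently the identity
$\int p_s\,ds = P_{Hd}$ (head power) holds up to the residual moment flux
$\omega M|_{s_T}$; on waveforms whose amplitude decays to zero by the imaged
end the identity is exact to numerical error (<1%), and on the default
synthetic wave the residual is fully accounted for by that flux term. The
storage-rate cycle-mean $\bar{\dot E}$ is computed and reported rather than
silently dropped, even though the balance-based motor-input estimate
neglects it.

**Arc-datum registration.** The arc origin of each frame is wherever the
skeleton's head end happens to land, and per-frame localization jitter of a
micron or two shifts the whole tangent profile along $s$ — on synthetic
movies this jitter, not angle noise, dominates waveform error. Because the
tether is a material point of the rigid head, its arc coordinate is the same
in every frame; the prep stage therefore shifts each frame's arc origin so
that the closest approach to the static tether point sits at a common arc
length (quadratic sub-sample refinement of the closest station, shifts taken
relative to their median). The step is exactly neutral for jitter-free input.

**Angle bookkeeping.** Tangent angles are unwrapped along $s$ from head to
tail; the $2\pi$ branch is then made temporally continuous at the neck
station. Head-end identification uses the wider end (distance-transform
width over the leading 10% of the path), falling back to the brighter end.

**Cycle segmentation.** Cycles start where the polar angle in the
$B_1$–$B_2$ plane crosses zero, i.e. $B_2$ changes sign while $B_1 > 0$; the
shape at $\tau = 0$ is then a positive multiple of mode 1. Whether that locus
is traversed upward or downward depends only on the arbitrary POD sign of
mode 2, so the implementation auto-detects the traversal direction
(configurable). Crossings are refined by linear interpolation and debounced
at a quarter of the median period.

## What the synthetic generator emulates — and what it does not

`synth_truth()` builds $\psi(s,t)$ with a rigid rocking head (rotation
blended C2 into the proximal tail), a traveling tangent-angle wave at 7 Hz
with wavelength 0.8 body lengths, a second harmonic of comparable weight
(real mouse beats are strongly anharmonic, with sharp curvature pulses), and
a counter-propagating component at 0.6 of the outgoing amplitude: the clamped
head reflects bending waves, making tethered beats partially standing; this
is what makes the $B_1$–$B_2$ loop elliptic and modulates power flow within
each cycle. The envelope rises to full amplitude over the proximal quarter of
the tail — where the taper makes $\kappa(s)$ largest, so proximal bending
dominates elastic storage — and decays mildly toward the tip. Amplitudes are
capped at 1.5 rad. `render_movie()` draws the centerline as a Gaussian ridge
whose width follows the radius taper, a wider and brighter head blob,
constant background, and Poisson (shot-like) noise at the study's pixel size
(0.325 um/px).

With a *pure* traveling wave, the net active power never dips negative at
$\eta_N = 0$, whatever the amplitude — elastic-release swing and drag both
scale with amplitude squared. The negative phases (and hence the zero
crossing of the minimum net power as $\eta_N$ sweeps 0 to 1e4) are a property
of partially standing, anharmonic beats; the generator defaults were chosen
to emulate that documented regime and then frozen.

Not emulated: optical aberrations and depth-of-field blur, out-of-plane
excursions, head-shape detail (the head is a blob, not a hook silhouette),
debris and neighboring cells, photobleaching, and beat-to-beat frequency
drift beyond additive angle noise. Passing the pipeline's recovery tests on
these movies therefore demonstrates correctness of the measurement chain on
data satisfying its assumptions, not robustness to every failure mode of real
microscopy.

## Problem sizes

Default desk-scale runs use 200 arc stations, 200 fps, and a 0.8 s rendered
movie (161 frames, 5–6 beat cycles), which keeps a full movie-to-energetics
run at a few minutes on one CPU; identity and oracle tests run on longer
noise-free records (1.5 s, 10 cycles) where imaging is bypassed. Real
recordings (thousands of frames, 40–60 cycles) use the same code paths
unchanged.

## Degenerate inputs and edge behavior

Blank frames (no foreground contrast), masks that skeletonize to loops, paths
shorter than a minimum, and bodies with branches longer than a quarter of the
main path are marked unusable rather than raising; the QC stage discards
frames whose contour length deviates more than 10% from the mean and aborts
only if a gap of more than three consecutive frames must be interpolated.
Degenerate variance in group comparisons short-circuits to exact equality.
An all-zero POD spectrum makes capture efficiency undefined (error).
`eta_N = 0` (purely elastic rod) is supported throughout and zeroes the
internal-dissipation channel exactly.

## Known limitations

- Resistive force theory is local; hydrodynamic interactions between distant
  parts of the flagellum and the detailed wall correction are outside its
  accuracy, and the hydrodynamic moment contribution is neglected (smaller by
  a factor ~ a/L).
- The energy balance attributes everything not explained by the modeled
  channels to the motors; errors in $\kappa_N$ or $\eta_N$ bias the split
  between elastic, internal-friction and motor terms (the sweep utilities
  exist precisely to explore this sensitivity).
- The imaged-end truncation leaves a small un-bookkept moment flux (see
  above); it is quantified, not hidden.
- Torsion and out-of-plane bending are excluded by construction (planar rod).
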