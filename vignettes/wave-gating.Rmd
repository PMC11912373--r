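---
title: "Drawing circuits with inputs: wave gating in critical unitary recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drawing circuits with inputs: wave gating in critical unitary recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavegate)
```

## The model

The network state is a complex field $Z$ on a periodic lattice (1D of
length $N$ or 2D of shape $H \times W$), updated by the single-layer
recurrence

$$Z_{n+1} = \phi\!\left(U \otimes Z_n + I_n\right),$$

where $\otimes$ is periodic convolution, $I_n$ is an input field, and
$\phi(z) = z / \sqrt{1 + |z|^2}$ is a phase-preserving complex sigmoid with
$\phi(0) = 0$, unit slope at the origin, and $0 < \phi'(z) < 1$ elsewhere
($\phi'$ denotes the radial slope $(1+|z|^2)^{-3/2}$ throughout; $\phi$ is
not holomorphic, and this package follows the scalar-slope convention for
every linearization — the conjugate Wirtinger term is deliberately not
modeled).

The coupling kernel $U = e^{\otimes A}$ is the convolutional exponential of
a compact anti-Hermitian generator $A$ (so $A(-x) = -\overline{A(x)}$),
computed by exponentiating the Fourier transform of $A$ element-wise. Since
$\mathcal{F}[A]$ is purely imaginary — this is the dispersion relation —
every eigenvalue of the coupling lies on the unit circle and the linear map
preserves the $L^2$ norm exactly. The quiescent state $Z \equiv 0$ is
therefore *critical*: globally attracting (because $\phi$ is a
contraction), but only marginally stable, with algebraic rather than
exponential relaxation. Waves launched into the network travel without
intrinsic decay.

Two generator presets are built in: `ilap3`, $i$ times the finite-difference
Laplacian stencil ($[1,-2,1]$ in 1D, the five-point stencil in 2D), whose
exponential propagates discrete waves; and `random7`, a seeded random
anti-Hermitian kernel restricted to a disk of radius 3 inside a
$7\times 7$ support. The Laplacian normalization is the unscaled stencil:
no prefactor multiplies $i\Delta$. Any scaling would only rescale the
dispersion relation (and hence wave speeds), not the phenomena.

## The inverse-design formula

A constant input $I^*$ drives the network to a steady state
$Z^* = \phi(U \otimes Z^* + I^*)$, and small perturbations around it evolve
through

$$\Delta Z_{n+1} = \Gamma \odot \left(U \otimes \Delta Z_n + \text{forcing}\right),
\qquad \Gamma = \phi'(U \otimes Z^* + I^*),$$

so the local slope $\Gamma$ acts as a per-site attenuation: waves propagate
freely where $\Gamma = 1$ and are damped where $\Gamma < 1$. (Note the
placement of $\Gamma$: a perturbing input enters the dynamics *through* the
activation, so the forcing is attenuated too. The package's `linear_step()`
uses this form; it is the one consistent with both the first-order expansion
of the full map and the closed-form response below, as the package's
regression tests verify by a Richardson comparison against the full map.)

`design_input()` inverts this relationship: given a requested attenuation
map $0 < \Gamma \le 1$ it computes

$$W = \sqrt{\Gamma^{-2/3} - 1}, \qquad Z^* = \phi(W), \qquad
I^* = W - U \otimes Z^*,$$

taking the nonnegative real branch of the square root. By construction
$U \otimes Z^* + I^* = W$ *exactly*, so $Z^*$ is an exact fixed point and
the realized attenuation $\phi'(W)$ equals the request up to round-off —
including at discontinuities of $\Gamma$, where the spatial mixing by $U$
is absorbed entirely into the structure of $I^*$. The package still
verifies every design by forward iteration from zero and reports the
sup-norm residual, and the acceptance checks exclude a kernel-radius margin
at discontinuities as a conservative precaution; empirically the residuals
vanish there too.

$\Gamma > 1$ is rejected by `design_input()`: the square root turns
imaginary and, more fundamentally, no steady state of the true map can
amplify ($\phi$ is contracting everywhere). Supercritical attenuation maps
are instead evolved with the *modulated map*
`modulated_step()`: $\Delta Z \mapsto \phi(\Gamma \odot (U \otimes \Delta Z))$,
in which $\Gamma > 1$ genuinely amplifies small fields and the activation
saturates the growth. This is a modeling choice for an operation the
original description leaves open (one cannot reach $\Gamma = 1.2$ through
the design formula); it reproduces the intended phenomenology — confined
spontaneous oscillations — and is flagged as an interpretation wherever it
is used.

The scalar theory behind the cubic roots: for a single neuron,
$z^* \approx (2I)^{1/3}$ and the relaxation time
$\tau \approx \tfrac{2}{3}(2I)^{-2/3}$ for small real $I$, so tiny inputs
move the operating point (and the local attenuation) enormously — this
singular sensitivity is what makes input-based circuit drawing cheap.
`scalar_fixed_point()` solves the scalar problem by plain fixed-point
iteration (globally convergent; default tolerance $10^{-12}$, budget
$10^6$ iterations) and reports $\tau = -1/\log\gamma$, with
$\tau = \infty$ at $I = 0$ where relaxation is algebraic.

## Linear response and resonance

Under uniform attenuation $\gamma$ and a point tone
$\alpha \lambda^n \delta_0$, the perturbation relaxes onto
$\Delta Z_n = R^* \lambda^n$ with

$$R^* = \mathcal{F}^{-1}\!\left[\frac{\alpha\,\mathcal{F}[\delta_0]}
{\lambda/\gamma - \mathcal{F}[U]}\right].$$

`closed_form_response()` evaluates this by Fourier division and refuses to
divide across a pole: if $\min |\lambda/\gamma - \mathcal{F}[U]|$ falls
below the guard ($10^{-8}$ by default) it raises a
`wavegate_pole_error` reporting the distance to the nearest eigenvalue.
Off resonance the response decays exponentially with distance from the
injection site; as $\gamma \uparrow 1$ with $\lambda$ at an eigenvalue the
envelope diverges.

At the pole the linear theory fails and the nonlinearity takes over: the
steady response scales as the *cubic root* of the forcing amplitude, the
signature of a forced Hopf critical point. `resonance_scaling_probe()`
measures this on the full nonlinear map. Two forcing profiles are
available, and the distinction matters at desk scale:

* `profile = "mode"` forces every site with the resonant Fourier eigenvector.
  The lattice then reduces exactly to the scalar critically forced map, the
  response equilibrates in $O(\alpha^{-2/3})$ steps, and the fitted
  exponent is clean (0.32 over $\alpha \in [10^{-4}, 10^{-1}]$ at
  $128^2$ in this package's tests, with an off-resonance control exponent
  of 0.98 at amplitudes one decade lower, where the response is linear).
* `profile = "point"` injects the tone at one site, as the gating
  experiments do. The site readout then superimposes the directly forced
  radiating wave (linear in $\alpha$) on the slowly accumulating resonant
  condensate; the condensate equilibrates only after $\sim 10^5$ steps at
  small $\alpha$ and the measured exponent is biased upward (about 0.40 at
  $128^2$). The cubic-root law is a statement about resonant forcing, and
  the modal profile is its canonical realization, so the package's
  validation uses `"mode"`; `"point"` is retained for studying the mixed
  regime.

"Steady" for the probe means the neighborhood RMS averaged over consecutive
windows (default 256 steps) changes by less than 1%.

## The gating experiments

Six scripted experiments (`run_demo()`) exercise the design machinery
end-to-end. All start the evolution *at the designed steady state* $Z^*$
and inject only the probe signal: starting from zero would superimpose the
critical, algebraically decaying relaxation transient of $I^*$ onto the
measurement — at full scale that transient is irrelevant, at desk scale it
dominates trailing-window amplitudes for tens of thousands of steps.
Signal amplitude is read out as the RMS of $|Z - Z^*|$ per site over a
trailing window, and per region as the RMS over a region mask.

* **`fig1_band`** (1D, $N = 1024$): background $\Gamma = 1$, absorbing
  flanks ($\Gamma = 0.5$) to stop wrap-around, and a central band
  $\Gamma_{\text{band}} = e^{-0.01 L}$ for $L = 0,\dots,5$. White noise
  injected in the left box traverses the band, attenuating exponentially in
  space; the steady right-box amplitude decreases strictly with $L$ — a
  continuously graded gate. The package's validation runs 65,536 steps and
  averages the trailing 32,768: in-band log-amplitude then fits a line with
  $R^2 > 0.95$ for $L \ge 2$. The trailing window here is much longer than
  the 1,024-step default used elsewhere because the in-band profile mixes
  noise-driven modes with different group velocities, and the fit residuals
  are dominated by that statistical mixture until the averaging is long.
* **`fig2_boxes`** (2D, $256^2$): two boxes with walls of
  $\Gamma_{\text{walls}} = 0.1$. Wall thickness is 16 sites — several
  attenuation lengths at the default wavenumber, thick enough that an
  intact wall is effectively impenetrable (measured right/left amplitude
  ratio $\sim 10^{-5}$, against a containment criterion of $10^{-4}$),
  while a 12-row hole lets the signal through ($\sim 0.2$). Thin walls are
  physically leaky: at 6 sites the transmitted amplitude is of order
  $10^{-2}$, which is a real property of the dynamics, not an artifact.
* **`fig3_labyrinth`** (2D): a go/no-go maze from thresholded band-passed
  noise, $\Gamma_{\text{go}} = 1$, $\Gamma_{\text{nogo}} = 0.01$. A tone
  injected at a go site fills exactly the connected component of that site
  — the wave dynamics computes flood fill. Detection compares the trailing
  RMS against `3e-4` times the median amplitude over the seed component: a
  threshold chosen between the through-wall leakage floor (measured
  $\lesssim 3\times 10^{-5}$ with the default geometry) and the faintest
  genuinely connected corridors ($\gtrsim 10^{-3}$). Agreement with the
  breadth-first oracle is scored outside a one-kernel-radius margin of the
  walls, where boundaries are physically graded.
* **`fig4_sync`** (2D): the same maze geometry with supercritical
  $\Gamma_{\text{go}} = 1.2$ and damping $\Gamma_{\text{nogo}} = 0.2$,
  evolved with the modulated map from small random noise. Each connected
  domain develops self-sustained oscillations; the per-site frequency is
  estimated from the phase difference between two snapshots 200 steps
  apart. The default kernel for this experiment is `random7` (breaking the
  Laplacian's mode degeneracies, as in the original demonstration).
* **`fig5_lighthouse`** (2D): an annular wall with a quarter-turn gap,
  redesigned at a sequence of rotation angles while a tone radiates from
  the center; emission tracks the gap. The outer border tapers from
  $\Gamma = 1$ to the wall value with a raised cosine over 8 sites so that
  outgoing waves are absorbed instead of wrapping around; the annulus
  edges are smoothed radially and angularly so the gap, not corner
  diffraction, controls the emission direction.
* **`fig6_dense`** (1D, $N = 1024$): the band experiment repeated with a
  *nonconvolutional* coupling — a circulant wave kernel plus random complex
  Gaussian bands at offsets $\pm 1, \pm 2, \pm 3$, anti-Hermitized exactly
  and exponentiated through the eigendecomposition of $-iA$. The disorder
  amplitude is tuned by bisection (`tune_rho_for_half_spanning()`) until
  about half the eigenvectors are system-spanning (participation ratio
  above $N/4$); at $N = 512$ this lands near $\rho \approx 0.06$.
  Disorder-localized modes absorb energy even where $\Gamma = 1$, visible
  as extra attenuation of outgoing waves.

## The synthetic-pattern generators: what they emulate, and what not

All inputs are generated in code; there is no external data. The labyrinth
generator emulates the original band-passed-noise construction with two
desk-scale adaptations, both documented because they change what a passing
test demonstrates. First, the Fourier band defaults scale with the lattice
(radial wavenumbers $\approx 0.015\,m$ to $0.03\,m$ for min-dimension $m$),
keeping corridor widths at several kernel radii. Second, the thresholded
mask is regularized by a morphological closing of the go region (square
structuring element, radius 4), guaranteeing walls at least $\sim 8$ sites
thick in every direction. At publication scale ($2048^2$) band-passed noise
produces such walls automatically; at $128^2$ the raw threshold
occasionally leaves 1–3-site walls, through which waves tunnel and — because
a $\Gamma = 1$ region is a lossless cavity with a high quality factor —
accumulate to amplitudes far above the nominal per-crossing transmission.
The regularized generator therefore demonstrates gating in the regime the
construction intends (impenetrable walls), and does *not* demonstrate that
arbitrarily thin drawn walls block waves — they do not, at any scale, given
enough accumulation time.

Passing tests on these generators show that the design formula and the
gating phenomenology work on piecewise-constant, moderately smooth
patterns with adequate feature sizes. They do not probe: walls thinner
than a few attenuation lengths, attenuation maps with spatially varying
complex phase (out of scope by design), non-periodic boundaries, or
publication-scale lattices.

## Numerical choices

* Convolution is spectral: two FFTs per step, exact for periodic fields.
  Kernel spectra are cached in the `unitary_kernel` object.
* Compact kernels are indexed by signed offsets with the center at offset
  zero; lattice embedding puts offset zero at the DFT origin, so spectra
  are comparable across lattice sizes. Wavenumbers follow standard DFT
  ordering, $k \in [0, N)$ per axis.
* Anti-Hermiticity is enforced by construction (`anti_hermitize()`,
  mirrored disorder bands) and checked exactly where it is an input
  contract (`conv_exp()` errors, naming the violated offset).
* The dense exponential uses the eigendecomposition of the Hermitian
  matrix $-iA$ (LAPACK `zheev` path), giving a machine-precision unitary
  $U = V e^{i\lambda} V^\dagger$ and the localization spectrum for free;
  matrices are guarded at $N \le 4096$.
* Tone sources carry phase $\lambda^{n-1}$ at the step producing state
  $n$, so a steady tone response has envelope exactly $R^*\lambda^n$ —
  this is what makes the closed-form/time-stepping comparison exact rather
  than off by one phase factor.
* Fixed-point verification iterates the full map from zero; uniform maps
  converge at rate $\Gamma$, piecewise maps with $\Gamma = 1$ interiors
  converge through wall absorption of the critical transient
  ($\sim 10^4$ iterations at $64^2$, the budget used in the tests).
* The flood-fill oracle is a queue-based breadth-first search with
  periodic wrap and 4-connectivity (matching the five-point Laplacian's
  propagation footprint; 8-connectivity is available). The test suite
  cross-checks it against an independent iterated-dilation oracle.
* Circular statistics (synchrony) use the resultant length:
  $\mathrm{sd} = \sqrt{-2\log|\overline{e^{i\theta}}|}$, computed on phase
  advances over the snapshot lag and converted to per-step units.

## Problem sizes used in validation

The validation suite runs at desk scale, chosen once: $64^2$/$128^2$ for
kernel and design checks, $128^2$ for response, flood-fill and synchrony
experiments, $256^2$ for the boxes, $N = 1024$ for the 1D band (65,536
steps), $N = 512$ for dense couplings. Publication scale ($2048^2$,
$10^5$–$10^6$ steps) remains one configuration line away but is not
exercised by the tests.

## Known limitations

* The synchrony demonstration is qualitative at desk scale. Small domains
  (up to a few hundred sites) lock to single quantized frequencies within
  4,000 modulated steps; domains of thousands of sites still contain
  competing wave sources after 25,000 steps, so a strict
  "all domains internally synchronized" criterion fails at $128^2$ — the
  original full-scale demonstration likewise shows domains still carrying
  synchronization boundaries after 25,000 steps. The package's strict
  synchrony check reflects this and is expected to fail at desk scale;
  the accompanying qualitative checks (locking of small domains, distinct
  per-domain frequencies) pass.
* The frequency map is a two-snapshot phase difference and aliases at
  $\pm\pi/\mathrm{lag}$; across-domain comparisons at the default lag of
  200 steps can wrap when domains differ by more than
  $\pi/200 \approx 0.016$ rad/step. Shorter lags trade aliasing for
  estimator noise.
* Exact inversion requires $0 < \Gamma \le 1$; amplifying regions exist
  only under the modulated map, whose update rule is an interpretation
  (see above).
* Only the one activation $\phi(z) = z/\sqrt{1+|z|^2}$ is supported; the
  design formula hard-codes the inverse of its slope and would need
  rederivation for any other sigmoid.
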