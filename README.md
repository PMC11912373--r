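# wavegate

Simulate and *program* traveling waves in critical unitary recurrent
networks.

A single-layer convolutional recurrent network with complex state `Z`
evolves by

    Z[n+1] = phi(U ⊗ Z[n] + I[n]),      phi(z) = z / sqrt(1 + |z|²),

where the coupling kernel `U = exp⊗(A)` is the convolutional exponential of
a compact anti-Hermitian generator `A`, so every eigenvalue of the linear
coupling lies on the unit circle. Such a network is *critical*: the
quiescent state attracts only algebraically, and waves travel without
intrinsic decay. A constant input `I*` shifts the local operating point of
the activation, and the slope there,

    Gamma = phi'(U ⊗ Z* + I*)  ∈ (0, 1],

acts as a per-site attenuation for any signal riding on top of the ongoing
activity: waves pass freely where `Gamma = 1` and die where `Gamma << 1`.
The package's central function inverts this relationship in closed form —

    I* = sqrt(Gamma^(-2/3) − 1) − U ⊗ phi(sqrt(Gamma^(-2/3) − 1))

— so *any* grayscale picture of walls and channels can be converted into
the constant input that literally draws that circuit into the network's
ongoing activity, without touching a single synaptic weight. On top of this
core the package provides the linearized perturbation dynamics and its
closed-form point-tone response, resonance probes (cubic-root amplitude
compression at criticality), pattern generators and analysis utilities for
the gating experiments (attenuation bands, walled boxes, flood-fill
labyrinths, synchrony binding, a rotating "lighthouse"), and a dense
(nonconvolutional) disordered 1D variant with Anderson-localization
diagnostics.

Intended users: computational neuroscientists and dynamical-systems
researchers studying input-driven circuit reconfiguration, traveling-wave
gating, and critical network dynamics.

## Worked example: a geometric IF statement

Draw two boxes separated by a wall, convert the drawing into a constant
input, and check that a tone injected in the left box cannot reach the
right one:

```r
library(wavegate)

U <- conv_exp(kernel_ilap3(2), c(64, 64))     # U = exp⊗(i·Laplacian)
print(U)
#> Unitary convolution kernel on 64x64 lattice
#>   generator support: 3x3 (radius 1)
#>   max | |F[U]| - 1 |: 5.55e-16

Gamma <- make_boxes_2d(c(64, 64), wall_gamma = 0.1, wall_thickness = 8)
design <- design_input(Gamma, U, forward_max_iter = 20000)
print(design)
#> Design result on a 64x64 lattice
#>   requested Gamma in [0.1, 1]
#>   max |realized - requested|: 4.16e-17
#>   forward iteration: converged in 5605 steps (final error 9.76e-09)

lambda <- pick_eigenfrequency(U, c(8, 8))     # a resonant wave frequency
src <- source_tone(site = c(32, 16), amplitude = 0.01, frequency = lambda)
traj <- evolve(design$Z_star, U, input_schedule(design$I_star, list(src)),
               n_steps = 2000, rms_window = 512, rms_ref = design$Z_star)

labels <- region_labels(Gamma)
region_rms(traj$rms, labels == 1)   # left box:  0.00124
region_rms(traj$rms, labels == 2)   # right box: 3.25e-06
```

The requested attenuation is realized to machine precision (`4.2e-17`),
forward iteration of the full map confirms the designed state is the
attractor, and the steady signal amplitude in the right box is ~400 times
smaller than in the left: the wall — drawn purely by the input — blocks the
wave. Restore a few rows of the wall with `make_boxes_2d(..., hole = ...)`
and the signal leaks through. At the package's default experiment scale
(256², 16-site walls) the contrast exceeds four orders of magnitude.

Six scripted experiments run end-to-end with `run_demo()`:

```r
run_demo("fig2_boxes")        # geometric IF (above, full scale)
run_demo("fig3_labyrinth")    # wave flood-fill of a connected maze region
run_demo("fig4_sync")         # synchrony binding in amplifying domains
run_demo("fig1_band")         # graded 1D attenuation band
run_demo("fig5_lighthouse")   # rotating directional emitter
run_demo("fig6_dense")        # dense disordered 1D variant
```

each writing fields (RDS/CSV), PNG snapshots of `log|Z|`, and a
`metrics.json` into its output directory. A thin command-line wrapper lives
at `inst/scripts/wavegate.R` (`demo`, `design`, `run` subcommands; YAML
configs; grayscale PNG attenuation maps in, fields out).

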