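# dotrecon

Frequency-domain diffuse optical tomography (FD-DOT) on circular phantoms:
a finite-element forward solver, a synthetic dataset generator, a
Tikhonov-regularized Newton reconstruction baseline, and a compact
convolutional network that maps boundary measurements directly to images of
tissue optical properties.

## The problem

Diffuse optical tomography recovers the absorption coefficient μa and the
reduced scattering coefficient μs′ (mm⁻¹) of soft tissue from near-infrared
light measured at the tissue surface — the physical basis of optical breast
imaging, where elevated μa marks tumors. In the frequency-domain modality,
sources are intensity-modulated at 10–100 MHz and every source–detector
pair yields an amplitude and a phase-shift reading. With `m` sources spaced
around a circular phantom and the remaining `m − 1` positions acting as
detectors, one phantom produces `m × (m−1)` observations per channel (240
for the 16×15 layout, 1260 for 36×35).

Light transport is modeled by the frequency-domain diffusion equation

    −∇·(D ∇Φ) + (μa − iω/c) Φ = S₀,   D = 1/(3(μa + μs′)),

discretized with P1 finite elements under a Robin boundary condition
Φ + 2AD ∂Φ/∂n = 0. The classical inversion repeatedly solves the
Tikhonov-regularized Newton step

    min_Δχ ‖J Δχ − ΔΦ‖² + λ²‖L Δχ‖²,

with an adjoint-assembled Jacobian J. The learned reconstructor replaces
the iteration with a single forward pass: a small CNN (feature → efficient
→ upsample/escalate → dense "encompass" modules, 1,258,308 trainable
parameters for the 16×15 layout) consumes the normalized 2×m×n boundary
image and emits the two 64×64 coefficient maps, sharing all weights between
the two output channels. Reconstructions are scored with MSE, PSNR and the
global structural similarity index (SSIM).

## Worked example

```r
library(dotrecon)

# simulate one phantom and look at its boundary data
spec <- phantom_spec(50, optical_properties(0.0059, 0.69),
                     list(list(center = c(10, 6), radius = 5,
                               props = optical_properties(0.015, 1.4))),
                     frequency_mhz = 20)
bd <- simulate_boundary(spec, acquisition_config(16, 20))
bd
#> boundary_data: 16 x 15 (clean)

# iterative baseline on the noiseless data
res <- reconstruct_tr(bd, spec, acquisition_config(16, 20), max_iter = 8)
round(res$misfit, 1)
#> [1] 179.0 147.4
range(res$image[1, , ])
#> [1] 0.00000000 0.02810107
```

The misfit decreases monotonically; the reconstructed absorption map peaks
near the true inclusion (its top-percentile centroid lands within ~1.4 mm
of the true center in this example) with the blur characteristic of
Tikhonov inversion.

End-to-end learned reconstruction:

```r
bundle <- run_experiment(experiment_config(
  n_sources = 16, n_samples = 1000, epochs = 20, n_tr_samples = 0,
  seed = 1), verbose = TRUE)
print(bundle$metrics$network$aggregate, digits = 3)
#>     channel mse_mean mse_min mse_max psnr_mean psnr_max ssim_mean ssim_max
#>        mu_a   0.0645 0.00572   0.530      13.9     22.4     0.570    0.899
#>  mu_s_prime   0.0821 0.00962   0.722      13.9     20.2     0.499    0.875
```

The generator draws 1000 random phantoms (diameters 60–150 mm, frequencies
10–100 MHz, background μa 0.005–0.03 and μs′ 0.05–3 mm⁻¹, one or two
inclusions), solves the forward problem with 15% measurement noise, and
trains the network for 20 epochs; the aggregate table scores the held-out
test split per channel. The headline figure is the maximum per-sample
absorption SSIM (0.899 here).

A command-line front end over the same functions lives in
`inst/cli/dotrecon.R` (subcommands `generate`, `train`, `predict`,
`reconstruct-tr`, `evaluate`, `run-experiment`).

## Documentation

The methods vignette (`vignettes/fd-dot-reconstruction.Rmd`) describes the
model and its assumptions, every tunable parameter with units and defaults,
the design decisions taken where the architecture or protocol was
under-specified, and what the synthetic benchmark does and does not show.
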