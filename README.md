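# simrecon

Simulation and deep-learning reconstruction of structured illumination
microscopy (SIM) data, self-contained in R.

## What it does, and for whom

SIM doubles the resolution of widefield fluorescence microscopy by
acquiring a stack of raw frames — conventionally 9: three phases of a
sinusoidal stripe pattern at each of three orientations — and
computationally unmixing the frequency content the stripes fold into the
passband. Analytical unmixing needs accurate pattern and OTF estimates, is
noise-fragile, and cannot handle underdetermined stacks. `simrecon` is for
microscopists and method developers who want the learning-based
alternative end to end:

* a **physical forward model** of raw SIM acquisition. Illumination
  `I(x,y) = I0 [1 − (m/2) cos(2π(kx·x + ky·y) + φ)]`, fluorescent response
  `S·I`, blur by the diffraction-limited PSF (ideal incoherent OTF, the
  pupil autocorrelation `(2/π)(arccos ρ − ρ√(1−ρ²))`, cutoff
  `kc = 2·NA/λ`), plus Gaussian noise of standard deviation `η·σ` (σ = the
  noiseless frame's standard deviation) or Poisson noise;
* a **training-data factory**: randomised pattern parameters and noise per
  stack, procedural ground-truth images (no external dataset needed; a
  folder of your own images also works), multi-page float TIFF stacks with
  a JSON manifest that makes every dataset bit-reproducible;
* **reconstruction networks** mapping an N-frame stack to one image at the
  same size: a residual channel-attention architecture (default, 10
  residual groups × 3 residual blocks at full scale), a plain deep
  residual variant, and an encoder–decoder baseline — implemented natively
  (compiled im2col convolutions with hand-derived backpropagation, Adam,
  stepped learning-rate halving);
* an **evaluation harness**: PSNR/SSIM, noise-robustness sweeps over
  `η = 0…9`, frame-subset ablations, and a pattern-parameter recovery
  diagnostic for raw stacks.

## Worked example

Simulate a small paired dataset, train the desk-scale preset, and compare
the model against the widefield baseline (the mean of the 9 raw frames):

```r
library(simrecon)

build_dataset("procedural", n = 32, out_dir = "simdata",
              cfg = optical_config(image_size = 64), seed = 5)
pre <- train_presets("desk", seed = 11)        # tiny net: 2 groups x 2 blocks
ck  <- train_model("simdata", pre$network, pre$train)

ds  <- load_dataset("simdata")
val <- Filter(function(p) p$split == "validation", ds$pairs)
wf  <- mean(sapply(val, function(p)
  psnr(normalise_stack(widefield_projection(p$input)), p$target)))
cat(sprintf("model %.2f dB vs widefield %.2f dB\n", ck$best_val_psnr, wf))
#> model 19.40 dB vs widefield 13.00 dB
```

The ~6 dB gap is the desk-scale learning signal: the network restores
held-out simulated stacks far beyond plain frame averaging. Reconstruction
of a TIFF stack (9 pages, or a multiple for timelapse) is then

```r
save_checkpoint(ck, "model.rds")
reconstruct_file("simdata/stack_0001.tif", "model.rds", "restored.tif")
```

A thin command-line front end with `simulate`, `train`, `reconstruct`,
`evaluate` and `noise-sweep` subcommands is installed at
`inst/cli/simrecon.R`.

Pattern diagnostics on a simulated stack:

```r
cfg <- optical_config()                        # 512 px, NA 1.2, 525 nm, 80 nm px
tf  <- make_otf(cfg)
gt  <- generate_procedural_image(512, seed = 4)
p   <- sample_stack_params(stack_layout(), simulation_ranges(),
                           tf$cutoff_frequency, seed = 14)
st  <- simulate_stack(gt, p, tf)
estimate_pattern_params(st)[, c("k0_hat", "theta_hat", "flagged")]
#>      k0_hat theta_hat flagged
#> 1 0.2794282  3.014321   FALSE
#> 2 0.2789006  0.914763   FALSE
#> 3 0.2793511  1.950571   FALSE
```

(the stack was simulated with a shared `k0 = 0.27923` and orientations
π/3 apart, at 3.0137, 0.9142 and 1.9509 rad modulo π — recovered to
sub-bin precision.)

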