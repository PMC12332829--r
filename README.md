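# cvinverse

Mechanistic modelling and inverse parameter learning for label-free
electrochemical biosensors.

Label-free sensors built on screen-printed carbon electrodes are usually
characterized by cyclic voltammetry (CV) of an outer-sphere redox probe
such as [Ru(NH₃)₆]³⁺/²⁺: the shape of the voltammogram encodes how a
nanocomposite film or an antibody layer changes mass transport and
electron-transfer kinetics at the interface. `cvinverse` turns that
qualitative picture into numbers. It is aimed at electroanalytical
chemists and biosensor developers who want interface parameters — not
just peak currents — out of routine CV scans.

The package provides four connected pieces:

1. **A thin-layer diffusion CV simulator.** One-dimensional Fickian
   diffusion of the oxidized probe,

   ∂c/∂t = D ∂²c/∂z²,

   on a domain of length L = 6·√(2·D·|E_R − E_L|/v), with the
   Butler–Volmer condition at the electrode surface (z = 0),

   ∂c/∂z|₀ = (k₀/D)·[ c|₀·e^(−α·F(E(t)−E_f⁰)/RT) − (c_b − c|₀)·e^((1−α)·F(E(t)−E_f⁰)/RT) ],

   bulk far-field and uniform initial conditions, and Faradaic current
   i(t) = F·A·D·∂c/∂z|₀ with A the electrochemically active surface
   area (ECSA). The PDE is discretized by an implicit finite-volume
   scheme on 500 equally spaced nodes and each time step is solved with
   the tridiagonal Thomas algorithm (compiled C++).

2. **A genetic-algorithm inverse learner.** An elitist non-dominated
   sorting GA searches bounded (D, k₀, α, ECSA) to minimize the three
   percent relative errors between experimental and simulated features,

   min [ ΔI_ox, ΔI_red, ΔE_pp ],  Δx = 100·(x_exp − x_sim)/x_exp,

   and selects the Pareto-front point closest to the origin of the
   error space. Runs are repeated (3 by default) and the per-parameter
   median is reported with its run-to-run dispersion.

3. **Assay statistics.** Four-parameter logistic (4PL) calibration
   y = d + (a − d)/(1 + (x/c)^b), its inverse, the IUPAC limit of
   detection (3.3 × SD of the lowest significantly responding group,
   converted through the local 4PL slope), signal-to-noise ratio against
   interferents, and the Brown–Anson surface-concentration estimate.

4. **Plain-text I/O and a CLI.** Voltammograms and calibration tables
   are delimited text, configurations are YAML, and the
   `simulate`/`synth`/`features`/`invert`/`calibrate`/`snr` subcommands
   (`inst/cli/cvinverse`) wrap the same functions for shell use. A
   seeded synthetic-voltammogram generator doubles as the test-fixture
   backbone.

## Worked example

Simulate a quasi-reversible voltammogram for a bare carbon electrode
(D = 1×10⁻⁵ cm²/s, k₀ = 4.5×10⁻³ cm/s), then recover those two
parameters from the curve alone:

```r
library(cvinverse)

couple <- redox_couple(c_b = 1e-5, E_f0 = -0.25)   # 10 mM probe
prot   <- cv_protocol(E_L = -0.6, E_R = 0.1, v = 0.1)
truth  <- interface_params(D = 1e-5, k0 = 4.5e-3, alpha = 0.5,
                           ECSA = 0.1256)
grid   <- make_grid(domain_length(truth$D, prot), 500L)

target <- simulate_cv(truth, couple, prot, grid)
extract_features(target)
#> CV features [A]: I_ox = 0.0002144, I_red = -0.0002953, E_pp = 115.7 mV

bounds <- parameter_bounds(D = c(1e-6, 1e-4), k0 = c(4.5e-4, 4.5e-2),
                           alpha = c(0.5, 0.5),      # fixed
                           ECSA = c(0.1256, 0.1256)) # fixed
res <- invert_parameters(target, bounds, ga_config(seed = 7),
                         couple, prot, grid)
print(res)
#> Inverse-learning result (median of 3 repeats):
#> Interface parameters:
#>   D     = 9.999e-06 cm^2/s
#>   k0    = 0.004499 cm/s
#>   alpha = 0.5
#>   ECSA  = 0.1256 cm^2
#>   best-run |error| norm: 0.009485 %
#>   run-to-run dispersion: D 0.1%, k0 0.1%, alpha 0.0%, ECSA 0.0%
```

The peak separation of 116 mV (vs ~59 mV for a reversible one-electron
couple) is the signature of quasi-reversible kinetics; the inversion
recovers D and k₀ to within 0.1% here because the target is noise-free
and the two-parameter problem is well posed. Fitting a calibration
curve:

```r
truth <- four_pl(a = -15.2, b = -0.64, c = 8.92, d = -12.5)
x <- 10^seq(0, 3, length.out = 8)   # 1 .. 1000 pg/mL
fit_4pl(calibration_data(x, predict_4pl(truth, x)))
#> 4PL: a = -15.2, b = -0.64, c (EC50) = 8.92, d = -12.5  (R^2 = 1.0000)
```

See `vignettes/inverse-cv-modelling.Rmd` for the model assumptions,
parameter identifiability, and numerical choices.

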