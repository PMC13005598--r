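# iplendo

Self-calibrated tissue optics for endoscopic (hollow-cylinder) geometry:
locating the **iso-pathlength (IPL) point** of diffuse reflectance and
using it to retrieve the absorption coefficient without knowing the
scattering.

## The science

Light re-emitted from a turbid medium normally depends on both the
absorption coefficient μa and the reduced scattering coefficient
μs′ = μs(1 − g). On the wall of a cylindrical lumen (an air hole through
tissue — the geometry an endoscope sees) there exists a position, the IPL
point, where the detected intensity is insensitive to μs′: the common
crossing of normalized full scattering profiles (FSPs) measured on media
that differ only in scattering. Because the mean photon pathlength at
that position is fixed by geometry, a Beer–Lambert relation

    I_t / I_0 = exp(−μa · DPF₀ · L),   L = D · sin((180° − θ_IPL)/2)

turns intensity ratios at the IPL angle θ_IPL (lumen diameter D) into
absorption coefficients, with a single zero-absorption differential
pathlength factor DPF₀ calibrated from one sample of known μa.

The package implements the full chain:

* **Dual-source diffusion model** — curvature-corrected major/minor
  isotropic source pairs with extrapolated-boundary image sources,
  predicting azimuthal and longitudinal FSPs
  (`theory_fsp()`, `theory_fsp_family()`).
* **Monte Carlo photon transport** — compiled simulator of a cylindrical
  air hole in scattering tissue (exponential steps, Henyey–Greenstein
  scattering, exact segment/cylinder detection), bit-reproducible per
  seed (`mc_config()`, `run_simulation()`, `mc_fsp_family()`).
* **IPL estimation** — pairwise crossing detection on curve families with
  windowed normalization, mirror averaging and smoothing
  (`estimate_ipl()`, `find_crossing()`).
* **Absorption retrieval** — DPF₀ calibration and μa inversion at the IPL
  point with interval propagation (`dpf0_from_reference()`,
  `mu_a_from_dpf0()`).
* **Image pipeline** — beam/lumen center detection, row-band and annulus
  profile extraction from endoscope-style frames
  (`longitudinal_profile()`, `azimuthal_profile()`).
* **Synthetic data** — rendered frames, curve families with exact
  constructed crossings, and three-sample absorption studies with known
  ground truth (`render_frame()`, `make_crossing_family()`,
  `make_absorption_study()`).

See the methods vignette (`vignettes/iplendo-methods.Rmd`) for the model
equations, conventions, numerical choices and known limitations.

## Worked example

```r
library(iplendo)

geom <- cylinder_geometry(0.5)          # 0.5 cm lumen radius

## where is the scattering-invariant point? (diffusion model)
fam <- theory_fsp_family("azimuthal", geom, c(22, 26, 30, 34))
estimate_ipl(fam)
#> IPL estimate (azimuthal): 166 deg (spread 0.74 deg, 6 pair crossings)
#>   in window [95, 175]

## the same question asked of the Monte Carlo simulator
mc <- mc_fsp_family(geom, c(16, 18, 22, 26), n_photons = 6e5, seed = 41)
estimate_ipl(mc$azimuthal, normalize = "none")
#> IPL estimate (azimuthal): 117 deg (spread 4.1 deg, 2 pair crossings,
#>   4 pairs without crossing) in window [95, 175]

## self-calibrated absorption retrieval at a measured IPL angle:
## reference / calibrator (mu_a = 0.25 /cm) / unknown, 2% intensity noise
st <- make_absorption_study(mu_a_truth = 0.94, dpf0_truth = 3.44,
                            diameter = 1.6, theta_ipl = 144,
                            noise_sd = 0.02, n_rep = 1000, seed = 2)
median(recover_absorption(st))
#> [1] 0.9383153

arc_length(1, 144)                      # IPL angle -> chord distance, cm
#> [1] 0.309017
```

The first two results show the two forward routes agreeing on the
qualitative laws (a single crossing exists; its angle grows with lumen
radius; the longitudinal crossing is radius-invariant) while placing the
point at different angles — the diffusion model is a near-field
approximation and the simulator resolves the full transport, so their
crossings need not coincide. The third result shows the retrieval chain
recovering a known absorption within 1% in the median at realistic noise.

A command-line interface wraps the same functions
(`exec/iplendo theory|mc|find-ipl|extract-mua|process-frames|synth|table1`);
every run writes a JSON manifest with its resolved configuration and
seed. `ipl_table()` reproduces the full radius-by-radius comparison of
theory and simulation in both directions.

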