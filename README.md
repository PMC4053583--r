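# apitv — few-view CT reconstruction with an adaptive prior image

Reducing the number of projection views is a direct way to cut radiation
dose and scan time in computed tomography, but analytic reconstruction
(filtered backprojection, FBP) of few-view data is dominated by streak
artifacts. `apitv` is an R package for people who study or teach
iterative CT reconstruction: it implements constrained total-variation
(TV) reconstruction of fan-beam data, with and without guidance from a
prior image of the same object acquired in an earlier dense-view scan
(a routine situation in image-guided radiotherapy).

The core problem is

```
minimize   alpha * ||f - f_p||_TV + (1 - alpha) * ||f||_TV
subject to ||M f - g|| <= epsilon,   f >= 0
```

where `f` is the image, `g` the measured sinogram, `M` the ray/pixel
intersection (system) matrix, `f_p` the prior image, and `||.||_TV` the
isotropic discrete total variation. It is solved by interlaced
projections: ART (Kaczmarz) sweeps for data consistency, a positivity
clamp, and normalized steepest-descent steps on the blended TV
objective — the **API-TV** algorithm. Setting `alpha = 0` removes the
prior and yields the **ASD-POCS** baseline exactly; disabling the TV
phase yields plain **ART**.

The package includes:

* an analytic Shepp-Logan phantom generator (standard and high-contrast
  variants) with exact ellipse rasterization and closed-form line
  integrals;
* a matched Siddon forward/back projector pair (Rcpp) for circular
  fan-beam geometry, exact to an independently assembled system matrix;
* flat-detector fan-beam FBP (Ram-Lak / Shepp-Logan / Hann filters) and
  a dense-view prior builder;
* the ART, ASD-POCS and API-TV reconstructors with per-iteration
  residual and error histories;
* an additive white-noise model, image-error metrics, line profiles and
  convergence curves;
* scripted end-to-end simulation studies and a small CLI
  (`inst/cli/apitv.R`).

## Worked example

The reference few-view study: a 256×256 high-contrast Shepp-Logan
phantom scanned with 60 views over 360° (source radius 500 mm,
source-to-detector 1000 mm, 512-element 1 mm flat panel), with a prior
image reconstructed by FBP from a 360-view scan.

```r
library(apitv)

geom  <- default_sim_geometry()
spec  <- shepp_logan_spec("high_contrast")
truth <- rasterize(spec, geom$image_n)
sino  <- forward_project(truth, geom)      # noise-free few-view data
prior <- make_prior(spec, geom)            # 360-view FBP prior

params <- recon_params(n_main = 30)        # alpha = 0.85 by default
api <- api_tv_reconstruct(sino, geom, prior = prior, params = params,
                          truth = truth)
asd <- asd_pocs_reconstruct(sino, geom, params = params, truth = truth)
api
#> <recon_result> API-TV, 30 iterations, final residual 53.5554, final image error 6.3468
asd
#> <recon_result> ASD-POCS, 30 iterations, final residual 6.16008, final image error 0.496882
image_error(prior, truth)
#> [1] 1118.3
```

The "image error" is the plain sum of squared pixel differences against
the ground-truth phantom over all 65,536 pixels (`image_error()`; a
per-pixel RMSE variant is `image_rmse()`). Both TV arms are orders of
magnitude more accurate than plain ART (whose error at matched
iterations is in the hundreds). On *noise-free* data the ASD-POCS arm
converges extremely fast because data, TV and positivity alone pin down
the piecewise-constant phantom, while the API-TV arm is held at the
fidelity of its FBP prior (error ≈ 1118, concentrated at the phantom's
sharp skull rim) — the prior's guidance pays off on noisy, inconsistent
data, where API-TV matches or beats ASD-POCS at every matched
iteration (see `run_noisy_study()` and the methods vignette for the
full discussion).

`run_noise_free_study()` / `run_noisy_study()` run all arms, collect
final errors, 128th-row profiles and convergence curves, and can write
images (32-bit float TIFF), curves (CSV) and a full parameter manifest
(YAML) to an output directory. `dose_ratio(120, 360)` gives the dose
fraction of a few-view protocol relative to a full scan (1/3).

## Layout

```
R/            phantoms, geometry, projector, fbp, tv, recon, noise,
              metrics, experiments, io
src/          Siddon traversal, projectors and ART sweep (Rcpp)
tests/        testthat suite (unit, property and end-to-end tests)
scripts/      acceptance.R
inst/cli/     command-line front end
vignettes/    methods vignette (model, parameters, design decisions)
```
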