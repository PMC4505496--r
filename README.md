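# tubequant

Quantitative image analysis for protein sorting and clathrin assembly on
supported membrane tubes (SMrT templates), with a ground-truth simulator.

## The problem

Clathrin-mediated endocytosis proceeds through membrane intermediates whose
curvature spans an order of magnitude. Budded SMrT templates reproduce that
range on one continuous membrane: narrow (~47 nm) flow-extruded tubes
carrying ~408 nm buds, imaged by multi-channel time-lapse fluorescence
microscopy (lipid dye / labeled adaptor protein / labeled clathrin). This
package implements the quantitative readouts such experiments need:

* **Curvature sorting.** Tubes and buds are diffraction-limited, so an
  object's net fluorescence is proportional to its membrane area and the
  protein:lipid ratio is proportional to protein surface density. The
  bud-normalized enrichment
  `ratio_tube = (F_prot/F_lip)_tube / mean[(F_prot/F_lip)_bud]`
  is ~1 for curvature-insensitive recruitment and >10 for strong curvature
  sensors such as PIP2-bound epsin.
* **Assembly kinetics.** Kymographs along each tube are fitted per pixel
  with a plateau followed by a one-phase exponential rise,
  `F(t) = F0 + A(1 - exp(-(t - t0)/tau))` for `t > t0`, after in-situ
  flow-cell dead-time removal; fits with `R² ≥ 0.8` are kept, contiguous
  pixels are collapsed to single events (smallest onset wins), and the
  long-tailed time constants are summarized by their geometric mean with a
  log-space 95% CI.
* **Foci density.** Clathrin foci per 100 um of tube at a fixed 5-min
  incubation, detected as prominent local maxima along the traces, with a
  hard-core (resolution dead-zone) correction that keeps the Poisson rate
  estimate unbiased.
* **Binding affinity.** One-site isotherm fits
  `F = Fmax [P] / (Kd + [P])` of template titrations.
* **SEM geometry.** Coating-layer correction of measured diameters
  (each layer subtracted twice, once per side).

A forward simulator (`simulate_budded_template()`,
`simulate_assembly_movie()`, `simulate_binding_titration()`) renders
area-proportional fluorescence through a Gaussian PSF with shot and read
noise, and returns the ground truth for every object, focus and parameter —
so each analysis stage is validated end to end without any external data.
See the methods vignette (`vignettes/tubequant-methods.Rmd`) for the models
and the design choices.

## Worked example

```r
library(tubequant)

## SEM diameters, corrected for 4.4 nm streptavidin + 4 nm gold coats
correct_diameter(c(63.3, 425.0), c(4.4, 4.0))
#>   measured_nm corrected_nm corrected_round_nm
#> 1        63.3         46.5                 47
#> 2       425.0        408.2                408

## binding titration at 5% noise, 8 templates per concentration
tit <- simulate_binding_titration(kd = 36, fmax = 1000,
  concentrations = c(0.5, 1, 2, 5, 10, 20, 36, 75, 150, 300, 600, 1000),
  noise_frac = 0.05, n_templates = 8, seed = 1)
fit_one_site(tit$concentration_nM, tit$fluorescence)
#> One-site binding fit (n = 96 points)
#>   Kd   = 35.4 nM (SE 1.6)
#>   Fmax = 1009 a.u. (SE 11)
#>   R^2  = 0.9855

## curvature sorting on a simulated budded field, enrichment 13.2
cfg <- sim_config(image_shape = c(100, 160), n_tubes = 6, n_buds = 5,
                  enrichment_E = 13.2, seed = 1)
sim <- simulate_budded_template(cfg)
res <- analyze_ratio_field(sim$movie)
res$summary
#>   class     mean         sd n
#> 1   bud  1.00000 0.02358613 5
#> 2  tube 13.51558 0.11131300 6
```

The tube mean recovers the configured 13.2-fold enrichment within a few
percent; the bud mean is 1 by construction (it is the normalizer), and the
Welch test separates the classes at `p = 1.3e-12`.

```r
## clathrin assembly kinetics on a simulated movie (25 foci, tau ~ 74 s)
kcfg <- sim_config(image_shape = c(80, 256), n_tubes = 4, n_frames = 100,
                   frame_interval = 5, dead_time = 30, n_foci = 25,
                   tau_geomean = 74, tau_geosd = 1.8, seed = 2)
ksim <- simulate_assembly_movie(kcfg)
kin <- analyze_kinetics_movie(ksim$movie)
kin$dead_time_s
#> [1] 30
kin$tau_summary
#>   geomean_s ci_low_s ci_high_s  n
#> 1  80.51802 62.64432  103.4914 22
```

The estimated dead time matches the configured 30 s, and the 22 recovered
events (a few of the 25 merge at close spacing) summarize to a geometric
mean bracketing the configured 74 s.

## Command line

A thin CLI over the same workflows lives at `inst/cli/tubequant.R`:

```sh
Rscript inst/cli/tubequant.R kinetics --seed 7 --out out/
```

writes events, a summary JSON and a manifest (parameters, derived seeds,
file checksums) for any of `curvature | kinetics | foci | binding`.

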