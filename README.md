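# patchdyn

Quantitative analysis of membrane-associated MreB patch dynamics in
rod-shaped bacteria imaged by TIRF microscopy, for microbiologists and
biophysicists studying cell-wall elongation.

Bacterial actin homologues (MreB, Mbl) form diffraction-limited membrane
patches that move with the peptidoglycan elongation machinery. Only a
fraction of patches move processively around the cell circumference;
that fraction, its speed and its density link directly to how fast the
sidewall grows. `patchdyn` provides the whole analysis chain as tested,
reusable R functions, plus a synthetic-movie generator with ground truth
so that every stage is verifiable without proprietary microscope data:

* **simulate** — directed (circumferential), Brownian and confined
  patch trajectories on a cylindrical cell under evanescent
  illumination (penetration depth *h*, visible fraction
  arccos(1 − 2h/D)/π), rendered as 16-bit TIFF movies with Gaussian
  PSF, Poisson shot noise and camera read noise, with a per-spot
  ground-truth table.
* **detect** — difference-of-Gaussians enhancement (σ₁ = 1 px,
  σ₂ = 4 px), watershed segmentation at 4 s.d. with 1 s.d. steps,
  sub-pixel centroids; Otsu cell contour from the maximum-intensity
  projection; patch density ρ = mean count / cell area; kymographs.
* **track** — gated frame-to-frame optimal assignment (3 px search
  radius, no gap closing, no merge/split).
* **classify** — time-averaged MSD (lags ≤ 7/8 of track duration),
  fits of MSD = (νt)² and MSD = 4Dt through the origin, classes
  directed / random / constrained / unclassified by the R² ≥ 0.8 and
  0.05 µm² plateau rules, diffusion from the cumulative distribution of
  squared displacements, per-cell fractions θ with bootstrap errors.
* **growthmodel** — full turns per generation FT = N_d·ν·τ/(πD), the
  inserted PG band width ω = (L − D)/FT and ω = ln 2/(τ·ν·ρ_d), the
  cross-cell (L − D) vs FT regression, whole-cell patch extrapolation,
  nutrient-upshift time courses and growth rates from area series.
* **pg_lattice** — event-level bookkeeping of the 3-for-1 and
  3-under-2 glycan-insertion models (per event: +2 bridges / 1 strand
  released, vs +1 bridge / turnover deferred to layer shedding).

## Worked example

Simulate one cell at the reference conditions (ρ = 2 patches µm⁻²,
ν = 55 nm/s, equal thirds of directed/Brownian/confined motion, 64 nm
pixels, 1 s frames, 2-min movie) and run the full pipeline:

```r
library(patchdyn)

geom <- cell_geometry(length_um = 3, diameter_um = 0.89)
cfg  <- sim_config(n_frames = 120, seed = 7)
res  <- run_pipeline(cfg, geom = geom)

res$summary[, c("rho_um2", "theta_d", "theta_r", "theta_c", "theta_u",
                "nu_um_s")]
#>   rho_um2 theta_d theta_r theta_c theta_u nu_um_s
#> 1    2.07   0.404    0.21   0.322  0.0639    0.05
```

The recovered density (2.07 µm⁻²) and directed fraction (0.40; single
cells scatter around the ground-truth 1/3) come from ~40 tracks in one
cell. Against the simulation's ground truth:

```r
ev <- res$evaluation
sprintf("recall (isolated spots): %.2f, localization error: %.2f px",
        ev$recall_isolated, ev$median_loc_error_px)
#> "recall (isolated spots): 0.99, localization error: 0.20 px"
```

Feed the measured kinetics into the growth model (generation time τ is
an input, here 1350 s):

```r
nd <- directed_count(res$summary$rho_d_um2, geom)
ft <- full_turns(nd, res$summary$nu_um_s, tau_s = 1350, d_cell_um = 0.89)
c(N_d = nd, FT = ft,
  omega_nm = 1000 * band_width_refined(1350, res$summary$nu_um_s,
                                       res$summary$rho_d_um2))
#>  N_d = 4.2, FT = 100 turns/generation, omega = 12.3 nm
```

i.e. the cell's directed patches complete ~100 full turns per
generation, each inserting a PG band a dozen nanometres wide — the
regime where sidewall elongation is fully accounted for by
circumferential patch motion.

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate_movies.R    # synthetic single-cell cohort
Rscript analysis/02_patch_analysis.R     # detect/track/classify/summarize
Rscript analysis/03_growth_models.R      # FT, omega, regressions, upshift
Rscript analysis/04_pg_lattice.R         # insertion-model trajectories
```

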