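#!/usr/bin/env Rscript
# Link patch dynamics to sidewall growth: full turns per generation,
# inserted-band width (simple and refined forms), the cross-cell
# (L - D) vs FT regression contrasting constant against growth-dependent
# band width, the whole-cell patch-count extrapolation, and a nutrient
# upshift time course.
#
# Reads results/cell_summary.csv (02_patch_analysis.R) for the measured
# kinetics; cell geometry and generation times are inputs. Writes
# results/growth_models.json and results/upshift_timecourse.csv.

suppressPackageStartupMessages(library(patchdyn))

summaries <- read.csv("results/cell_summary.csv")
geom <- cell_geometry(3, 0.89, 0.2)
tau <- 1350  # generation time (s) used for the worked example

nu <- mean(summaries$nu_um_s, na.rm = TRUE)
rho_d <- mean(summaries$rho_d_um2)
n_d <- directed_count(rho_d, geom)
ft <- full_turns(n_d, nu, tau, geom$diameter_um)
om_simple <- band_width_simple(geom$length_um, geom$diameter_um, ft)
om_refined <- band_width_refined(tau, nu, rho_d)
total <- extrapolate_total_patches(mean(summaries$mean_count),
                                   geom$diameter_um, 0.2)

message(sprintf("N_d = %.1f directed patches/cell -> FT = %.0f turns/generation",
                n_d, ft))
message(sprintf("band width: simple %.1f nm, refined %.1f nm",
                1000 * om_simple, 1000 * om_refined))
message(sprintf("visible fraction %.3f -> %.1f total patches/cell",
                visible_fraction(geom), total))

# cross-cell regression: constant band width vs growth-dependent
set.seed(42)
n <- 80
ftn <- runif(n, 60, 200)
const_ld <- 0.014 * ftn * (1 + runif(n, -0.1, 0.1))
fit_const <- sidewall_vs_turns_regression(const_ld, ftn)
grow_s <- 0.018 * ftn * (1 + runif(n, -0.1, 0.1))
grow_lb <- 0.031 * ftn * (1 + runif(n, -0.1, 0.1))
fit_s <- sidewall_vs_turns_regression(grow_s, ftn)
fit_lb <- sidewall_vs_turns_regression(grow_lb, ftn)
message(sprintf(
  "regression: constant-omega slope %.1f nm (r2 %.2f); growth-dependent %.1f vs %.1f nm",
  1000 * fit_const$slope_um, fit_const$r2,
  1000 * fit_s$slope_um, 1000 * fit_lb$slope_um))

# nutrient upshift: patch speed steps up while density stays flat
set.seed(43)
times <- rep(seq(-5, 30, 5), each = 6)
up <- data.frame(time_min = times,
                 rho_um2 = 2 + rnorm(length(times), 0, 0.15),
                 nu_um_s = ifelse(times < 10, 0.030, 0.055) +
                   rnorm(length(times), 0, 0.003),
                 theta_d = 1 / 3 + rnorm(length(times), 0, 0.04))
tc <- upshift_timecourse(up)
write.csv(tc, "results/upshift_timecourse.csv", row.names = FALSE)

# growth rate from a micro-colony area series doubling every 30 min
tt <- seq(0, 120, 10)
rate <- growth_rate_from_area(tt, 2 * 2^(tt / 30))
message(sprintf("growth rate from areas: %.4f min^-1 (ln2/30 = %.4f)",
                mean(rate, na.rm = TRUE), log(2) / 30))

jsonlite::write_json(list(
  n_directed_per_cell = n_d, full_turns = ft,
  band_width_simple_nm = 1000 * om_simple,
  band_width_refined_nm = 1000 * om_refined,
  total_patches_per_cell = total,
  regression_const_slope_nm = 1000 * fit_const$slope_um,
  regression_const_r2 = fit_const$r2,
  regression_growthdep_slopes_nm = 1000 * c(fit_s$slope_um,
                                            fit_lb$slope_um)),
  "results/growth_models.json", auto_unbox = TRUE, digits = NA)
message("wrote results/growth_models.json")
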