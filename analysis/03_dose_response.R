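#!/usr/bin/env Rscript
# Dose-response structure of the tent trial: pooled vs stratified fits and
# the Abbott-correction sensitivity.
#
# Reads the 24 h pouch concentrations written by 02_tent_pipeline.R (or
# regenerates them if absent), draws synthetic mortality, and compares the
# pooled linear fit with per-level stratified fits and with
# control-corrected mortality. Writes results/dose_response/fits.csv.

suppressPackageStartupMessages(library(srvolume))
out_dir <- "results/dose_response"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

conc_path <- "results/tent24/pouch_concentrations.csv"
if (!file.exists(conc_path)) {
  message("pouch concentrations not found; running the tent pipeline first")
  source("analysis/02_tent_pipeline.R")
}
conc <- read.csv(conc_path)

gen <- generator_config(seed = 42, true_slope = 9, true_intercept = 0.1,
                        control_mortality = 0.05)
obs <- generate_pouch_mortality(conc$c_ppmv, gen, site_id = conc$site_id,
                                level_label = conc$level_label,
                                period_h = 24)

pooled <- suppressWarnings(
  concentration_for_mortality(fit_linear(obs), 1.0))
by_level <- suppressWarnings(
  stratified_fits(obs, by = "level_label", target = 1.0))

# Abbott sensitivity: correct for the generator's control mortality
obs_abbott <- obs
obs_abbott$mortality <- suppressWarnings(
  abbott_correction(obs$mortality, gen$control_mortality))
abbott_fit <- suppressWarnings(
  concentration_for_mortality(fit_linear(obs_abbott, stratum = "abbott"), 1.0))

tab <- rbind(fits_to_table(pooled), fits_to_table(by_level$fits),
             fits_to_table(abbott_fit))
write.csv(tab, file.path(out_dir, "fits.csv"), row.names = FALSE)
print(tab[, c("stratum", "slope", "intercept", "r2", "c_target_ppm")])
if (length(by_level$skipped)) {
  cat("skipped strata:\n"); print(by_level$skipped)
}
cat("\nControl correction shifts the intercept down and C100 up slightly;\n")
cat("per-level fits quantify how much less concentration the lower pouches\n")
cat("need for the same predicted mortality.\n")
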