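#!/usr/bin/env Rscript
# Diffusion-weighted MRI analysis on seeded pellet phantoms: ADC recovery at
# the study acquisition settings and the percent-diffusivity-increase
# reporter contrast, plus a rendered diffusion map.

suppressMessages(library(aqpquant))
dir.create("results", showWarnings = FALSE)
seed <- 20260101L

# Two-compartment pellet: control cells at D0 = 1.0 um^2/ms, reporter-
# expressing cells at D = 1.794 um^2/ms (the 79.4% increase measured in
# HT22 cells), imaged at 4 b-values in 1-3 ms/um^2, 5 averages, SNR 50.
spec <- pellet_phantom_spec(
  compartments = list(
    list(center = c(20, 32), radius = 12, D = 1.0, S0 = 1000),
    list(center = c(46, 32), radius = 12, D = 1.794, S0 = 1000)),
  snr = 50, averages = 5L, noise = "rician", seed = seed)
ph <- make_pellet_phantom(spec)

sigma <- estimate_noise_sigma(ph$series, ph$truth$label == 0)
message(sprintf("estimated noise sigma: %.2f a.u. (true %.2f)",
                sigma, ph$truth$sigma))

fit_one <- function(lab) {
  dec <- roi_mean_signal(ph$series, ph$truth$label == lab)
  list(roi = fit_adc(dec, method = "rician", sigma = sigma),
       map = fit_adc_map(ph$series, ph$truth$label == lab, sigma = sigma,
                         method = "rician"))
}
gfp <- fit_one(1); aqp <- fit_one(2)

tab <- data.frame(
  compartment = c("GFP", "Aqp1"),
  D_true = c(1.0, 1.794),
  D_roi_fit = c(gfp$roi$D, aqp$roi$D),
  D_roi_se = c(gfp$roi$se_D, aqp$roi$se_D),
  D_map_median = c(median(gfp$map$D[gfp$map$valid]),
                   median(aqp$map$D[aqp$map$valid])))
tab$rel_err_pct <- 100 * (tab$D_roi_fit - tab$D_true) / tab$D_true
write.csv(format(tab, digits = 10), "results/dwi_adc_recovery.csv",
          row.names = FALSE)

dd <- percent_delta_diffusivity(aqp$roi$D, gfp$roi$D)
message(sprintf("reporter contrast dD/D0 = %.1f%% (planted 79.4%%)", dd))
write.csv(data.frame(delta_d_over_d0_pct = dd, planted_pct = 79.4),
          "results/dwi_contrast.csv", row.names = FALSE)

# full-pellet diffusion map, median-filtered, 8-bit scale 0.2-2.5 um^2/ms
full <- fit_adc_map(ph$series, ph$truth$label > 0, sigma = sigma)
write_rendered_png(render_diffusion_map(full, 0.2, 2.5, kernel = 3),
                   "results/dwi_diffusion_map.png")
message("wrote results/dwi_adc_recovery.csv, dwi_contrast.csv, dwi_diffusion_map.png")
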