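#!/usr/bin/env Rscript
# Generate every synthetic dataset the downstream analyses consume, with
# ground truth sidecars: telegraph-promoter MS2 cohorts (the burst and
# elongation experiments), pulsatile nuclear-YAP cohorts (pulse detection),
# a dose-response snapshot population, and one 3D spot stack.
#
# Outputs under results/data/. Everything derives from one master seed.

suppressPackageStartupMessages(library(yapburst))
seed <- 7
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## MS2 cohorts: a WT-like and a KO-like condition (k_on x13, r x4.4), plus
## dark/lit cohorts at the optogenetic 90-s sampling
wt <- promoter_params(k_on = 0.5 / 60, k_off = 2 / 60, r = 2, w = 8,
                      dt = 30, sigma_noise = 1.5)
ko <- promoter_params(k_on = 6.5 / 60, k_off = 2 / 60, r = 8.8, w = 8,
                      dt = 30, sigma_noise = 1.5)
for (nm in c("wt", "ko")) {
  pp <- get(nm)
  co <- simulate_trace_cohort(pp, 80, 400, seed = derive_seed(seed, nm))
  write_trace_csv(co$traces, file.path(out, paste0("ms2_", nm, ".csv")),
                  ground_truth = co$ground_truth["params"])
}
dark <- promoter_params(k_on = 0.6 / 60, k_off = 2 / 60, r = 2, w = 3,
                        dt = 90, sigma_noise = 1.5)
lit <- promoter_params(k_on = 2.1 / 60, k_off = 2 / 60, r = 2, w = 3,
                       dt = 90, sigma_noise = 1.5)
for (nm in c("dark", "lit")) {
  co <- simulate_trace_cohort(get(nm), 100, 300,
                              seed = derive_seed(seed, nm))
  write_trace_csv(co$traces, file.path(out, paste0("ms2_", nm, ".csv")),
                  ground_truth = co$ground_truth["params"])
}
message("MS2 cohorts written")

## nuclear-YAP cohorts: pulsing (differentiating-like) and pulse-free
## control for the false-positive estimate
pulsing <- simulate_yap_cohort(yap_pulse_params(pulse_rate = 1,
                                                noise_cv = 0.05),
                               n_cells = 150, hours = 16,
                               seed = derive_seed(seed, "yap"))
write_trace_csv(pulsing$traces, file.path(out, "yap_pulsing.csv"))
readr::write_csv(pulsing$ground_truth$pulses,
                 file.path(out, "yap_pulsing_truth.csv"))
control <- simulate_yap_cohort(yap_pulse_params(pulse_rate = 0,
                                                noise_cv = 0.05),
                               n_cells = 200, hours = 16,
                               seed = derive_seed(seed, "ctrl"))
write_trace_csv(control$traces, file.path(out, "yap_control.csv"))
message("YAP cohorts written")

## dose-response snapshot populations (two replicates, WT reporter)
pops <- purrr::map_dfr(1:2, function(r) {
  simulate_dose_population(dose_pop_params(n_cells = 2000),
                           seed = derive_seed(seed, "dose", r),
                           replicate = r)$cells
})
readr::write_csv(pops, file.path(out, "dose_population.csv"))
message("dose population written")

## one spot stack (TIFF) with its scene ground truth
scene <- spot_scene(c(15, 64, 64),
                    tibble::tibble(x0 = c(20.3, 45.7), y0 = c(30.6, 22.2),
                                   z0 = c(7.4, 8.6),
                                   amplitude = c(400, 300),
                                   sigma_xy = c(1.3, 1.5), sigma_z = c(2, 2)),
                    mcp_level = 100, noise_sd = 10)
stack <- simulate_spot_stack(scene, seed = derive_seed(seed, "spots"))
write_stack_tiff(stack$stack, file.path(out, "spot_stack.tif"))
jsonlite::write_json(list(stack_shape = scene$stack_shape,
                          spots = scene$spots, mcp_level = scene$mcp_level,
                          noise_sd = scene$noise_sd),
                     file.path(out, "spot_stack_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("spot stack written")
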