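#!/usr/bin/env Rscript
# Equivalent-current-dipole fits of the four M100 components at 600 ms
# (40-ms windows, peak +/- 20 ms, per hemisphere). The generator displaces
# the first syllable's source 5 mm laterally; the fits should recover the
# first-syllable dipole as more lateral than those of syllables 2-4.

suppressMessages(library(segwin))
dir.create("results", showWarnings = FALSE)

arr <- default_sensor_array()
stim <- generate_stimulus_set()[["600"]]
ep <- simulate_epochs(stim, arr, default_sim_config(), seed = 7001)
ev <- suppressWarnings(preprocess_epochs(ep))
dc <- detect_counts(ev, arr, ep$ground_truth$onsets_ms)

fits <- do.call(rbind, lapply(c("left", "right"), function(h)
  fit_all_components(ev, arr, dc[[h]]$components, h)))
write.csv(fits, "results/dipole_fits_600ms.csv", row.names = FALSE)
print(fits[, c("component_index", "hemisphere", "x_mm", "y_mm", "z_mm", "gof")],
      row.names = FALSE)

lat1 <- abs(fits$x_mm[fits$component_index == 1])
latk <- abs(fits$x_mm[fits$component_index > 1])
cat(sprintf("\nfirst-syllable dipole more lateral by %.1f mm (generator truth: 5 mm)\n",
            mean(lat1) - mean(latk)))
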