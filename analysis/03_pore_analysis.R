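#!/usr/bin/env Rscript
# Pore-size distributions and porosity from synthetic micrographs.
#
# Two genotypes are emulated as 750 x 500 nm scenes: the wild-type-like
# sample is rich in small pores, the mutant-like sample shifted toward
# larger pores, at comparable overall porosity (~0.05, the magnitude
# reported for real walls). Each scene runs through the full
# segmentation pipeline: Otsu threshold -> opening (erode + dilate) ->
# 8-connected labelling -> 5-300 nm^2 area filter -> 15 nm^2-wide bins
# over 5-305 nm^2 -> coverage porosity.

library(pectinporo)

seed <- 20260301
dir.create("results", showWarnings = FALSE)

scenes <- list(
  Col0 = gen_pore_image(n_pores = 150, seed = seed,
                        area_dist = list(type = "lognormal",
                                         meanlog = log(45), sdlog = 0.55),
                        blur_sigma = 0.6, noise_sd = 0.03),
  sfr8 = gen_pore_image(n_pores = 110, seed = seed + 1,
                        area_dist = list(type = "lognormal",
                                         meanlog = log(95), sdlog = 0.55),
                        blur_sigma = 0.6, noise_sd = 0.03)
)

dists <- list()
for (lab in names(scenes)) {
  img <- scenes[[lab]]$image
  mask <- morph_filter(threshold_pores(img))
  recs <- filter_pores(label_pores(mask, img), 5, 300)
  write.csv(recs, sprintf("results/pores_%s.csv", lab), row.names = FALSE)
  dists[[lab]] <- size_histogram(recs)
  est <- porosity_estimate(recs, 750 * 500)
  jsonlite::write_json(est, sprintf("results/porosity_%s.json", lab),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d pores in range, mean area %.1f nm^2, phi = %.4f (planted coverage %.4f)\n",
              lab, est$n_pores, est$mean_pore_area, est$phi,
              scenes[[lab]]$truth$coverage))
}

hist_tab <- data.frame(bin_lo = dists$Col0$bin_edges[-21],
                       bin_hi = dists$Col0$bin_edges[-1],
                       freq_Col0 = dists$Col0$freq,
                       freq_sfr8 = dists$sfr8$freq)
write.csv(hist_tab, "results/pore_size_distributions.csv", row.names = FALSE)

cmp <- compare_distributions(dists$Col0, dists$sfr8)
if (!is.na(cmp$crossover_nm2)) {
  cat(sprintf("\nSmall/large-pore balance crosses over at %g nm^2 (mutant richer in larger pores above it)\n",
              cmp$crossover_nm2))
} else {
  # sampling noise in sparse bins can flip the per-bin sign more than once;
  # the net shift still shows in the cumulative difference
  below <- sum(cmp$table$diff[cmp$table$bin_hi <= 65])
  above <- sum(cmp$table$diff[cmp$table$bin_lo >= 65])
  cat(sprintf("\nNo single-bin crossover; net frequency shift: %+0.3f below 65 nm^2, %+0.3f above (mutant richer in larger pores)\n",
              below, above))
}
cat("Wrote results/pores_*.csv, results/porosity_*.json, results/pore_size_distributions.csv\n")
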