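#!/usr/bin/env Rscript
# Preprocess the simulated coronal volumes: flat-fielding, axial stripe
# removal, percentile contrast normalization, isotropic check.  Demonstrates
# the chain on one fibrotic phantom and records how much each artifact mode
# was suppressed (results/analysis/preprocess_report.csv).

library(hepamorph)

dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

cfg <- phantom_config(
  shape = c(128, 128, 128), seed = 101,
  tree_params = list(root_radius = 10, depth = 3, radius_ratio = 0.7,
                     root_length = 90, n_central = 1, n_portal = 1),
  sinusoid_params = list(node_density = 7e4, tube_radius = 2.5),
  steatosis_params = list(band_edges = c(0, 30, 60, 90, 120),
                          band_probabilities = c(0.68, 0.56, 0.30, 0.18),
                          droplet_radius = c(3, 6)))
ph <- generate_phantom(cfg)
raw <- ph$gray

stripe_amp <- function(g, period = 24) {
  prof <- apply(g$data, 3, mean)
  k0 <- round(length(prof) / period)
  Mod(stats::fft(prof - mean(prof)))[k0 + 1]
}

g1 <- correct_bias(raw, 32, iterations = 2, clip_log = 0.69)
g2 <- remove_stripes(g1, axis = 3)
g3 <- denoise_and_normalize(g2, 0, 0.5, 99.5)
g4 <- resample_isotropic(g3, 1)

rep <- data.frame(
  stage = c("raw", "bias_corrected", "destriped", "normalized"),
  mean = c(mean(raw$data), mean(g1$data), mean(g2$data), mean(g3$data)),
  sd = c(sd(raw$data), sd(g1$data), sd(g2$data), sd(g3$data)),
  stripe_amplitude = c(stripe_amp(raw), stripe_amp(g1), stripe_amp(g2),
                       stripe_amp(g3)))
write.csv(rep, "results/analysis/preprocess_report.csv", row.names = FALSE)

cat(sprintf(
  "stripe amplitude %.4f -> %.2e; output grid %s at %g um\n",
  stripe_amp(g1), stripe_amp(g2),
  paste(dim(g4$data), collapse = "x"), g4$spacing[1]))
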