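#!/usr/bin/env Rscript
# Stage 1: generate the synthetic instrument datasets used by the
# downstream stages, with ground truth recorded in YAML manifests.
# All parameters are the study conditions the generators default to.

library(aavheat)

seed <- 1L
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

## nano-DSF: triplicate thermograms for a VP1/VP2-containing full
## particle (two transitions) and an empty particle (major transition
## only, VP1 N-termini intrinsically unfolded)
dsf <- do.call(rbind, lapply(1:3, function(r) {
  fp <- simulate_thermogram(first = list(Tm_C = 62.0, dH = 1.46e5),
                            second = list(Tm_C = 73.7, dH = 3.21e5),
                            noise_sd = 1e-3, seed = seed * 100L + r)
  ep <- simulate_thermogram(NULL,
                            second = list(Tm_C = 73.8, dH = 2.78e5),
                            noise_sd = 1e-3, seed = seed * 100L + 10L + r)
  fp$sample_id <- "FP_LD"; ep$sample_id <- "EP"
  fp$replicate <- r; ep$replicate <- r
  rbind(fp, ep)
}))
write_output_table(dsf, file.path(outdir, "thermograms.tsv"), seed)

## mass photometry: a control full-particle run and a heated run in
## which part of the population has ejected its genome (EP component),
## plus the VP3-only unbinding behaviour
ctrl <- simulate_mp_events(
  data.frame(label = "FP", mean = 4.51e6, sd = 0.12e6, weight = 1),
  n_events = 5000, unbinding_prob = 0.373, seed = seed + 20L)
heated <- simulate_mp_events(
  data.frame(label = c("EP", "FP", "OP"),
             mean = c(3.73e6, 4.51e6, 5.3e6),
             sd = c(0.12e6, 0.12e6, 0.15e6),
             weight = c(0.2, 0.6, 0.2)),
  n_events = 5000, unbinding_prob = 0.426, seed = seed + 21L)
ctrl$sample_id <- "control"; heated$sample_id <- "heated_60C"
write_output_table(rbind(ctrl, heated),
                   file.path(outdir, "mp_events.tsv"), seed)
write_manifest(attr(heated, "ground_truth"),
               file.path(outdir, "mp_events_manifest.yaml"))

## SV-AUC: the 60 C-heated peak table (ejected-tethered, EP-like and
## shifted-FP species with their area ratios)
peaks <- simulate_auc_peaks(
  data.frame(s_S = c(54.6, 66.0, 84.7), fraction = c(0.2, 0.2, 0.6),
             ratio_260_230 = c(0.58, 0.16, 0.47),
             label = c("tethered_truth", "EP_truth", "FP_truth")),
  jitter = 0, seed = seed + 30L)
write_output_table(peaks, file.path(outdir, "auc_peaks.tsv"), seed)

## HDX-MS: a VP1u peptide that unfolds on heating, a 5-fold-axis
## peptide with increased dynamics, and an unchanged VP3 peptide
peps <- data.frame(
  start = c(101, 205, 562), end = c(131, 229, 578),
  modification = c("", "acetyl", ""),
  plateau_control = c(6.0, 5.0, 4.0), rate_control = c(0.02, 0.02, 0.02),
  plateau_heated = c(7.5, 6.0, 4.0), rate_heated = c(0.02, 0.02, 0.02))
hdx <- simulate_hdx(peps, noise_sd = 0.05, seed = seed + 40L)
write_output_table(hdx, file.path(outdir, "hdx_uptake.tsv"), seed)
write_manifest(attr(hdx, "ground_truth"),
               file.path(outdir, "hdx_manifest.yaml"))

cat("Synthetic datasets written to", outdir, "\n")
cat(sprintf("  thermograms: %d points, %d sample/replicate series\n",
            nrow(dsf), length(unique(paste(dsf$sample_id, dsf$replicate)))))
cat(sprintf("  MP events: %d control + %d heated\n",
            nrow(ctrl), nrow(heated)))
cat(sprintf("  AUC peaks: %d; HDX records: %d\n", nrow(peaks), nrow(hdx)))
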