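#!/usr/bin/env Rscript
# Generate one example of every synthetic input the pipeline consumes and
# write them under results/simulated/ (16-bit TIFF + JSON sidecar for the
# micrograph, CSV for traces and tables). Downstream drivers regenerate
# their own data in memory; these files document the formats.

suppressMessages(library(sarcomech))
seed <- 20260101L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

m <- gen_em_micrograph(c(512, 512), d_nm = 40, r_nm = 9, nm_per_pixel = 1,
                       jitter_sd = 1, noise_sd = 0.05, seed = seed)
write_micrograph(m, file.path(out, "em_example.tif"))
write.csv(m$truth, file.path(out, "em_example_truth.csv"), row.names = FALSE)
cat(sprintf("micrograph: %d filaments rendered (d = 40 nm, r = 9 nm)\n",
            nrow(m$truth)))

write_trace(gen_mechanics_data("ktr", list(F_max = 1, k_tr = 10, F_res = 0.05),
                               noise_sd = 0.05, seed = seed),
            file.path(out, "ktr_trace.csv"))
write_trace(gen_mechanics_data("shortening", list(A = 0.1, k = 20, C = 0.9),
                               noise_sd = 0.002, duration = 0.25, seed = seed),
            file.path(out, "shortening_trace.csv"))
write.csv(gen_mechanics_data("pca", list(pCa50 = 6, n_H = 4), noise_sd = 0.03,
                             seed = seed),
          file.path(out, "tension_pca.csv"), row.names = FALSE)
write.csv(gen_mechanics_data("force_velocity", list(a = 0.25, b = 0.5, P0 = 1),
                             noise_sd = 0.01, seed = seed),
          file.path(out, "force_velocity.csv"), row.names = FALSE)

r <- gen_tremor_signal(duration = 60, f0 = 60, burst_times = c(5, 15, 25, 35, 45),
                       burst_dur = 0.5, amp = 0.5, noise_sd = 0.05, seed = seed)
write.csv(data.frame(time_s = (seq_along(r$signal) - 1) / r$fs, volts = r$signal),
          file.path(out, "tremor_recording.csv"), row.names = FALSE)
write.csv(r$events, file.path(out, "tremor_truth_events.csv"), row.names = FALSE)

dd <- rbind(gen_ddpcr_counts(900, 0, seed = seed, sample_id = "wt1", genotype = "WT"),
            gen_ddpcr_counts(450, 450, seed = seed + 1, sample_id = "ki1",
                             genotype = "KI"))
write.csv(dd, file.path(out, "ddpcr_counts.csv"), row.names = FALSE)

cat("wrote example inputs to", out, "(seed", seed, ")\n")
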