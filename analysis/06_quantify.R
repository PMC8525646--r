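#!/usr/bin/env Rscript
# Small quantifications: ddPCR allelic expression normalized to the WT
# group, and kyphotic index from spinal landmarks.

suppressMessages(library(sarcomech))
dir.create("results", showWarnings = FALSE)

# six WT samples (WT allele only) and six heterozygous samples with
# balanced allele expression, 20,000 droplets each
dd <- rbind(
  do.call(rbind, lapply(1:6, function(i)
    gen_ddpcr_counts(900, 0, seed = 800 + i, sample_id = paste0("wt", i),
                     genotype = "WT"))),
  do.call(rbind, lapply(1:6, function(i)
    gen_ddpcr_counts(450, 450, seed = 850 + i, sample_id = paste0("ki", i),
                     genotype = "KI"))))
fa <- ddpcr_fractional_abundance(dd, reference_genotype = "WT")
write.csv(fa, "results/ddpcr_fractional_abundance.csv", row.names = FALSE)
cat(sprintf("normalized WT-allele fractional abundance: WT %.3f, KI %.3f\n",
            mean(fa$fa_normalized[fa$genotype == "WT"]),
            mean(fa$fa_normalized[fa$genotype == "KI"])))

# kyphotic index: control-like vs kyphotic-like landmark sets (mm);
# the kyphotic spine has a deeper dorsal apex relative to the C7-L6 chord
ky <- data.frame(
  group = c(rep("WT", 4), rep("KI", 4)),
  animal = c(paste0("wt", 1:4), paste0("ki", 1:4)),
  index = c(
    sapply(1:4, function(i) kyphotic_index(c(0, 0), c(62, 0), c(31, 8 + 0.5 * i))),
    sapply(1:4, function(i) kyphotic_index(c(0, 0), c(55, 0), c(27, 13 + 0.5 * i)))))
write.csv(ky, "results/kyphotic_index.csv", row.names = FALSE)
cs <- cohort_summary(ky, "index", "group", tests = "mann-whitney")
cat(sprintf("kyphotic index: WT %.2f +/- %.2f vs KI %.2f +/- %.2f (MW p = %.2g)\n",
            cs$summary$mean[cs$summary$group == "WT"],
            cs$summary$sem[cs$summary$group == "WT"],
            cs$summary$mean[cs$summary$group == "KI"],
            cs$summary$sem[cs$summary$group == "KI"], cs$tests$p_value))
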