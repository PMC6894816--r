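#!/usr/bin/env Rscript

# Step 2 — per-sample QC from the cohort VCFs.
#
# Reads each species' multi-sample VCF back through the variant layer and
# tabulates coverage breadth and mean depth per sample, with the inclusion
# decision (breadth > 30% and mean depth > 3.5 are required for a sample to
# enter pairwise comparisons).

suppressMessages(library(wsstrack))

cohort_dir <- "results/cohort"
params <- jsonlite::read_json(file.path(cohort_dir, "params.json"),
                              simplifyVector = TRUE)
vcfs <- list.files(cohort_dir, pattern = "\\.vcf$", full.names = TRUE)

metrics <- do.call(rbind, lapply(vcfs, function(v) {
  species_id <- sub("\\.vcf$", "", basename(v))
  profiles <- read_multisample_vcf(v, species_id, params$reference_length)
  sample_metrics_table(profiles)
}))

write_tsv_table(metrics, "results/sample_metrics.tsv")
cat("QC for", nrow(metrics), "sample x species combinations ->",
    "results/sample_metrics.tsv\n")
cat(sprintf("Breadth range %.3f-%.3f, mean depth range %.2f-%.2f, %d fail\n",
            min(metrics$breadth), max(metrics$breadth),
            min(metrics$mean_depth), max(metrics$mean_depth),
            sum(!metrics$pass_filter)))
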