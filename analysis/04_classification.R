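#!/usr/bin/env Rscript

# Step 4 — relatedness calls against empirical per-species cut-offs.
#
# Cut-offs are estimated per species as the maximum WSS score among
# truth-unrelated comparisons (samples from different twin pairs), the most
# conservative choice against false relatedness. Each twin pair's score is
# then called related (score > cut-off), unrelated, or indeterminate (no
# usable window or a sample failing QC), and the unrelated comparisons give
# the empirical misclassification rate per species.

suppressMessages(library(wsstrack))

comparisons <- utils::read.delim("results/pair_comparisons.tsv",
                                 stringsAsFactors = FALSE)

unrel <- comparisons[!comparisons$within_pair & comparisons$pass_filter, ]
cutoffs <- estimate_cutoffs(split(unrel$wss_score, unrel$species_id))
write_cutoff_table(cutoffs, "results/cutoffs.tsv")

within <- comparisons[comparisons$within_pair, ]
calls <- classify_pairs(within, cutoffs)
write_tsv_table(
  calls[, c("species_id", "pair_id", "sample_a", "sample_b", "wss_score",
            "cutoff", "call")],
  "results/classifications.tsv")

mis <- do.call(rbind, lapply(split(unrel, unrel$species_id), function(u) {
  r <- misclassification_rate(u$wss_score, cutoffs$cutoffs[[u$species_id[1L]]])
  data.frame(species_id = u$species_id[1L], n_exceed = r$n_exceed,
             n_total = r$n_total, rate_percent = r$rate_percent)
}))
write_tsv_table(mis, "results/misclassification.tsv")

cat("Cut-offs (", cutoffs$provenance, "):\n", sep = "")
print(round(cutoffs$cutoffs, 1))
cat("Twin-pair calls:\n")
print(table(calls$species_id, calls$call))
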