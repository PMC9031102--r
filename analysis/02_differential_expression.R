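#!/usr/bin/env Rscript
# Stage 2: differential isoform expression.
#
# Reads the simulated count matrix and design, filters isoforms detected in
# fewer than three samples, fits the zero-inflated negative binomial model
# per isoform, tests treatment, region, interaction and excess-zero effects,
# adjusts p-values per effect family (BH), and partitions isoforms into the
# interaction / both-main / treatment-only / region-only categories. Writes
# the long results table and a category summary, and reports how well the
# planted truth was recovered.

library(zinbsplice)

counts <- read_counts("results/simulated/counts.tsv")
design <- read_design("results/simulated/design.tsv")
truth <- utils::read.delim("results/simulated/truth.tsv")

out <- run_de(counts, design, q_interaction = 0.10, q_main = 0.05,
              min_samples = 3, verbose = TRUE)

write_de_results(out$results, "results/de_results.tsv",
                 header_comment = "stage 02: ZINB differential expression")
utils::write.table(as.data.frame(out$category_counts),
                   "results/de_category_counts.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# recovery against the planted truth
planted <- with(truth, ifelse(log_fc_interaction != 0, "interaction",
                       ifelse(log_fc_treatment != 0, "treatment",
                       ifelse(log_fc_region != 0, "region", "null"))))
cat_of <- out$categories$category[match(truth$isoform_id,
                                        out$categories$isoform_id)]
tab <- table(planted = planted, category = cat_of, useNA = "ifany")
message("planted effect vs assigned category:")
print(tab)
utils::write.table(as.data.frame(tab), "results/de_truth_recovery.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

n_sig_zero <- with(out$results,
                   sum(effect == "zero_inflation" & q_value < 0.05,
                       na.rm = TRUE))
message(sprintf(
  paste("isoforms with significant excess zeros after FDR: %d of %d --",
        "the generator plants pi = 0.2, so the boundary test should fire",
        "on most rows; on data without structural zeros it stays quiet"),
  n_sig_zero, length(unique(out$results$isoform_id))))
message("wrote results/de_results.tsv, de_category_counts.tsv, de_truth_recovery.tsv")
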