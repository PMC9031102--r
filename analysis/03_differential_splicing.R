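#!/usr/bin/env Rscript
# Stage 3: differential alternative splicing.
#
# Reads the simulated skipped-exon junction-count table, computes
# length-adjusted inclusion levels (PSI) per group, tests each event with the
# beta-binomial likelihood-ratio test between treatment groups — jointly and
# within each region — adjusts p-values by BH, and tallies significant events
# by type.

library(zinbsplice)

design <- read_design("results/simulated/design.tsv")
events <- read_splicing_events(
  "results/simulated/SE.MATS.JC.txt", "SE",
  sample_ids_group1 = design$sample_id[design$treatment == "NTG"],
  sample_ids_group2 = design$sample_id[design$treatment == "CON"])
truth <- utils::read.delim("results/simulated/splicing_truth.tsv")

out <- run_splice(events, q_threshold = 0.10, strata = TRUE, design = design)

for (cmp in names(out)) {
  res <- out[[cmp]]$results
  write_splice_results(res, sprintf("results/splice_%s.tsv", cmp))
  message(sprintf("%-5s comparison: %d events, %d significant at q < 0.10",
                  cmp, nrow(res), sum(res$q_value < 0.10, na.rm = TRUE)))
}

# recovery: the first 30 events are null (psi 0.5 vs 0.5), the last 30 carry
# a planted inclusion difference of 0.3
joint <- out$joint$results
sig <- joint$q_value < 0.10
is_alt <- truth$psi_group1 != truth$psi_group2
message(sprintf("planted differential events detected: %d / %d",
                sum(sig & is_alt, na.rm = TRUE), sum(is_alt)))
message(sprintf("null events flagged: %d / %d",
                sum(sig & !is_alt, na.rm = TRUE), sum(!is_alt)))
message(sprintf("mean estimated inclusion difference among planted events: %.3f (truth 0.3)",
                mean(joint$inc_level_diff[is_alt], na.rm = TRUE)))

tl <- out$joint$tally
utils::write.table(tl$significant, "results/splice_tally_significant.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/splice_{joint,NAc,TG}.tsv and splice_tally_significant.tsv")
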