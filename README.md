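# zinbsplice

Differential expression of transcript isoforms and differential alternative
splicing under a 2x2 treatment-by-region design, built for count data with
excess zeros.

Neuropeptide prohormone and receptor genes produce short, often lowly
expressed isoforms whose RNA-seq read counts contain zeros of two kinds:
*sampling zeros* (the isoform was expressed but not captured at finite depth)
and *structural zeros* (the isoform is genuinely absent from that sample).
This package analyzes such data for a design crossing a treatment (NTG,
nitroglycerin-elicited hyperalgesia, vs CON control) with a brain region
(NAc, nucleus accumbens, vs TG, trigeminal ganglia), five replicates per
cell.

## What it computes

**Isoform expression.** Counts for isoform *i*, sample *j* follow a
zero-inflated negative binomial,

    Y_ij ~ pi_i * delta_0 + (1 - pi_i) * NB2(mu_ij, alpha_i),
    log mu_ij = x_j' beta_i + o_j,

with NB2 variance mu + alpha mu^2 and an intercept-only zero-inflation
probability pi. Likelihood-ratio tests cover the treatment, region and
interaction effects (with a Bartlett-type small-sample correction so the
tests hold their nominal size at n = 20) and excess zeros (ZINB vs NB on the
boundary mixture 1/2 chi2_0 + 1/2 chi2_1). P-values are BH-adjusted per
effect family; isoforms are categorized as interaction / both main effects /
treatment-only / region-only. Isoforms detected in fewer than three samples
are filtered. Reference cell is CON x TG, so exp(beta_treatment) is the
NTG/CON fold change and exp(beta_region) the NAc/TG fold change.

**Alternative splicing.** For SE / A3SS / A5SS / MXE / RI events with
inclusion and skipping junction counts, the length-adjusted inclusion level

    psi = (IJC / lI) / (IJC / lI + SJC / lS)

is compared between groups with a beta-binomial likelihood-ratio test
(shared overdispersion, 1 df), jointly and within each region, with BH
adjustment and per-type tallies.

**Sequence-match classification.** BLAST-style matches of de novo assembled
transcripts against references are classified complete (full identity, no
gap openings, full subject coverage) / partial (>= 95% identity, no gap
openings) / unmatched, and summarized as per-gene detection frequencies by
treatment-by-region group.

**Synthetic data.** `simulate_counts()` and `simulate_splicing()` generate
ZINB count matrices and beta-binomial junction-count tables with recorded
ground truth, replacing the original sequencing data in all validation.

## Worked example

```r
library(zinbsplice)

# simulate 60 isoforms: 30 null, 30 with a 4-fold treatment effect
cfg <- sim_config(n_isoforms = 60, baseline_mean = 50,
                  log_fc_treatment = rep(c(0, log(4)), each = 30),
                  dispersion = 0.5, zero_inflation = 0.2, seed = 7)
sim <- simulate_counts(cfg)
out <- run_de(sim$counts, sim$design)
out$category_counts
#>    interaction           none treatment_only
#>              1             33             26
```

25 of the 30 planted isoforms land in `treatment_only`; 28 of the 30 null
rows stay `none`, with two false positives at the 0.10 screening threshold.
One planted row in detail:

```r
subset(out$results, effect == "treatment" & isoform_id == "ISO00031")
#>  isoform_id    effect  lr_stat    p_value     q_value fold_change direction       category
#>    ISO00031 treatment 13.53873 0.00143985 0.006170788    7.094128       NTG treatment_only
```

The fold change is `exp(beta_treatment)` (here 7.1 against a planted 4 —
single-isoform estimates at n = 20 are noisy; across the 500-isoform
recovery simulation the mean of `beta_treatment` is within 0.05 of the
truth). A splicing event with higher inclusion in group 1:

```r
ev <- splicing_event("SE_1", "TAC1", "SE",
                     ijc_group1 = c(61, 75, 70, 64, 58),
                     sjc_group1 = c(39, 25, 30, 36, 42),
                     ijc_group2 = c(34, 28, 41, 30, 37),
                     sjc_group2 = c(66, 72, 59, 70, 63))
test_differential_psi(ev)
#>  event_id      psi1      psi2 inc_level_diff lr_stat     p_value
#>      SE_1 0.4882595 0.2049237      0.2833358 21.4465 3.44102e-05
```

With the default SE lengths (lI = 2, lS = 1) a raw inclusion-read fraction
of ~0.66 maps to psi ~0.49: half the transcripts include the exon.

## Analysis workflow

Numbered drivers under `analysis/` run the full pipeline on synthetic data
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R                 # counts, design, truth, events
Rscript analysis/02_differential_expression.R  # ZINB tests + categories
Rscript analysis/03_differential_splicing.R    # PSI tests, joint + per region
Rscript analysis/04_match_classification.R     # detection summary
```

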