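#!/usr/bin/env Rscript
# Cross-species oral-delivery transfer of the most-effective genes.
#
# Each tiered gene gets an ortholog in the second species; its oral potency
# is the injected potency scaled by a lognormal species/delivery factor, so
# transfer succeeds for some genes and fails for others — the variability
# the success criterion (>50 percentage points over control) is meant to
# absorb. Successful tier-1 genes form the superior target set.

suppressPackageStartupMessages(library(rnaitier))
cfg <- pipeline_config()
set.seed(11)

asg <- utils::read.delim("results/assignments.tsv")
truth <- utils::read.delim("results/sim/truth.tsv")

tested <- asg$gene_id[asg$tier %in% 1:3]
orth <- data.frame(source_gene = tested, target_species = "P_cochleariae",
                   target_gene = sprintf("PC%04d", seq_along(tested)))
utils::write.table(orth, "results/sim/orthologs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# oral delivery shifts per-gene potency by a lognormal factor (median 30x
# less sensitive, 10-fold spread); controls sit at low background mortality
ti <- match(tested, truth$gene_id)
shift <- exp(rnorm(length(tested), log(30), log(10) / 2))
treated <- vapply(seq_along(tested), function(i) {
  prof <- list(lc50 = truth$lc50[ti[i]] * shift[i], hill = truth$hill[ti[i]],
               max_lethality = truth$max_lethality[ti[i]],
               onset_day = truth$onset_day[ti[i]])
  100 * mean(stats::rbinom(1, 10, expected_lethality(prof, 30, 10, 0.03))) / 10
}, numeric(1))
assays <- data.frame(source_gene = tested, species = "P_cochleariae",
                     dose_g_ha = 30, day = 10, treated_pct = treated,
                     control_pct = 3)

evaluated <- evaluate_transfer(assays, cfg)
utils::write.table(evaluated, "results/transfer.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
rates <- transfer_rates(evaluated, asg)
print(rates)

superior <- define_superior(evaluated, asg, cfg)
writeLines(superior, "results/superior.txt")
cat(length(superior), "superior target genes (successful tier-1 transfers)\n")
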