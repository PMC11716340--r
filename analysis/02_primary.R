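#!/usr/bin/env Rscript
# Score the primary screen and select target genes.
#
# A gene is a target at >=90% lethality; batches whose buffer controls show
# elevated mortality are held to the stricter 100% cutoff. Genes at <=50%
# form the low-mortality background used later as the enrichment universe.

suppressPackageStartupMessages(library(rnaitier))
cfg <- pipeline_config()

primary <- read_screen_table("results/sim/primary_screen.tsv")

# flag contaminated batches from their own controls: mean control mortality
# above twice the overall baseline
ctrl <- primary[primary$gene_id == "CONTROL", ]
ctrl_rate <- tapply(ctrl$n_dead / ctrl$n_injected, ctrl$batch, mean)
contaminated <- names(ctrl_rate)[ctrl_rate > 2 * median(ctrl_rate) + 0.05]
cat("contaminated batches:", paste(contaminated, collapse = ", "), "\n")

calls <- score_screen(primary, day_by_phase = c(I = 11, II = 7),
                      technical_death_day = cfg$technical_death_day)
partition <- select_primary_targets(calls, cfg, contaminated)
utils::write.table(partition, "results/partition.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

print(summarize_selection(partition, universe_size = nrow(partition)))

truth <- utils::read.delim("results/sim/truth.tsv")
hit <- truth$true_tier[match(partition$gene_id[partition$set == "target"],
                             truth$gene_id)]
cat("planted tiers among selected targets:",
    paste(names(table(hit)), table(hit), sep = ":", collapse = " "), "\n")
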