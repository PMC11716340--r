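#!/usr/bin/env Rscript
# Term over-representation in the target set.
#
# Annotations here are synthetic: three "core process" terms preferentially
# annotate potent genes (tiers 1-3), three neutral terms annotate at random.
# Enrichment compares targets against the low-mortality background with the
# hypergeometric upper tail (>=5 study genes, P <= 0.01).

suppressPackageStartupMessages(library(rnaitier))
cfg <- pipeline_config()
set.seed(7)

partition <- utils::read.delim("results/partition.tsv")
truth <- utils::read.delim("results/sim/truth.tsv")

potent <- truth$gene_id[truth$true_tier %in% 1:3]
rest <- setdiff(truth$gene_id, potent)
pick <- function(pool, p) pool[runif(length(pool)) < p]
ann <- rbind(
  do.call(rbind, lapply(sprintf("GO:%07d", 1:3), function(t)
    data.frame(term_id = t, gene_id = c(pick(potent, 0.6), pick(rest, 0.05)),
               term_name = "core process", ontology = "BP"))),
  do.call(rbind, lapply(sprintf("GO:%07d", 4:6), function(t)
    data.frame(term_id = t, gene_id = pick(truth$gene_id, 0.2),
               term_name = "neutral process", ontology = "BP"))))
path <- "results/sim/annotation.tsv"
utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)

uni <- build_universe(partition, cfg)
cat("study", length(uni$study), "genes vs universe", length(uni$universe),
    "(intermediates excluded)\n")
res <- enrich_terms(uni$study, uni$universe, read_annotation_map(path), cfg)
utils::write.table(res, "results/enrichment.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("terms passing the >=5-gene, P<=0.01 filters:\n")
print(res[, c("term_id", "term_name", "x", "n_term", "p_value",
              "percent_of_term")])
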