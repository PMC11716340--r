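# Shared fixture builders: everything is generated in code at test time.

make_screen_df <- function(gene_id, dose, day, n_dead,
                           phase = "validation", n_injected = 10,
                           batch = "B001", species = "T_castaneum") {
  data.frame(gene_id = gene_id, phase = phase, dose_ng_ul = dose, day = day,
             n_injected = n_injected, n_dead = n_dead, batch = batch,
             species = species, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small validation-screen record set encoding explicit per-gene profiles:
# `spec` is a list of lists(gene, day, doses = named lethality fractions).
records_from_profiles <- function(spec) {
  rows <- lapply(spec, function(s) {
    do.call(rbind, lapply(names(s$doses), function(d) {
      make_screen_df(s$gene, as.numeric(d), s$day,
                     round(10 * s$doses[[d]]))
    }))
  })
  do.call(rbind, rows)
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every m-subset of
# an N-gene universe and count those overlapping the term in >= x genes.
hyper_tail_enum <- function(x, m, n_term, N) {
  draws <- utils::combn(N, m)
  mean(apply(draws, 2, function(d) sum(d <= n_term) >= x))
}

# Agreement metric used by the recovery checks (external to the clusterer).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Run the tier-recovery experiment: simulate planted tiers under binomial
# noise, build and impute profiles, cluster at k = 5, tier, and compare to
# the planted truth.
run_recovery <- function(n_genes = 200, seed = 1L) {
  cfg <- pipeline_config(seed = seed)
  sc <- sim_config(n_genes = n_genes,
                   tier_proportions = c(0, .2, .2, .2, .2, .2),
                   days = 7, episodes = list(), seed = seed)
  truth <- plant_truth(sc)
  screen <- simulate_screen(sc, truth)
  profiles <- impute_high_dose(build_profiles(screen, cfg), cfg)
  features <- profile_features(profiles, cfg)
  asg <- assign_tiers(cluster_genes(features, 5, seed = seed), features)
  planted <- truth$true_tier[match(asg$gene_id, truth$gene_id)]
  eff <- define_most_effective(asg, cfg)
  tier1 <- truth$gene_id[truth$true_tier == 1]
  list(ari = ari(planted, asg$tier),
       tier1_recovery = mean(tier1 %in% eff),
       assignments = asg, truth = truth)
}
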