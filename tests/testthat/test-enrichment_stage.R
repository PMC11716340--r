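test_that("hypergeometric upper tail matches exhaustive enumeration", {
  # all-overlap draw from a 10-gene universe: 1 / C(10, 5) = 1/252
  expect_equal(hypergeom_upper_tail(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_upper_tail(0, 5, 5, 10), 1)

  set.seed(33)
  for (i in 1:30) {
    N <- sample(4:12, 1)
    m <- sample(1:N, 1)
    n_term <- sample(1:N, 1)
    x <- sample(0:min(m, n_term), 1)
    expect_equal(hypergeom_upper_tail(x, m, n_term, N),
                 hyper_tail_enum(x, m, n_term, N),
                 tolerance = 1e-12,
                 label = sprintf("x=%d m=%d n_term=%d N=%d", x, m, n_term, N))
  }
  expect_error(hypergeom_upper_tail(6, 5, 5, 10), "exceeds")
  expect_error(hypergeom_upper_tail(1, 5, 11, 10), "bounds")
})

test_that("hypergeometric tail agrees with phyper and is monotone in x", {
  for (x in 0:8)
    expect_equal(hypergeom_upper_tail(x, 10, 8, 40),
                 stats::phyper(x - 1, 8, 32, 10, lower.tail = FALSE),
                 tolerance = 1e-12)
  p <- vapply(0:8, function(x) hypergeom_upper_tail(x, 10, 8, 40), numeric(1))
  expect_true(all(diff(p) <= 0))
  # log-space accumulation stays finite deep in the tail
  expect_gt(hypergeom_upper_tail(43, 905, 69, 3000), 0)
})

test_that("the universe is targets plus background, intermediates excluded", {
  part <- data.frame(
    gene_id = letters[1:5],
    set = factor(c("target", "target", "background", "background",
                   "intermediate"),
                 levels = c("target", "background", "intermediate")))
  uni <- build_universe(part, pipeline_config())
  expect_setequal(uni$study, c("a", "b"))
  expect_equal(length(uni$universe), 4)
  expect_true(all(uni$study %in% uni$universe))

  full <- build_universe(part, pipeline_config(enrichment_universe = "full"))
  expect_equal(length(full$universe), 5)

  set.seed(12)
  part2 <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      set = factor(sample(c("target", "background",
                                            "intermediate"), 20, TRUE),
                                   levels = c("target", "background",
                                              "intermediate")))
  if (any(part2$set == "background")) {
    uni2 <- build_universe(part2, pipeline_config())
    expect_equal(length(uni2$universe),
                 sum(part2$set %in% c("target", "background")))
  }
  none <- part[part$set == "target", ]
  expect_error(build_universe(none, pipeline_config()), "background")
})

test_that("term enrichment reports counts, percents and filtered p-values", {
  universe <- sprintf("u%04d", 1:800)
  study <- universe[1:100]
  ann <- data.frame(term_id = character(), gene_id = character())
  add_term <- function(ann, id, study_n, bg_n) {
    rbind(ann,
          data.frame(term_id = id,
                     gene_id = c(study[seq_len(study_n)],
                                 universe[101:800][seq_len(bg_n)])))
  }
  ann <- add_term(ann, "ko03010", 43, 26)   # 43/69 -> 62.3%
  ann <- add_term(ann, "ko03050", 22, 13)   # 22/35 -> 62.9%
  ann <- add_term(ann, "GO:0000001", 4, 1)  # x = 4 < 5 -> filtered
  ann <- add_term(ann, "GO:0000002", 5, 600) # depleted, p near 1 -> filtered
  annotations <- read_annotation_map(write_tsv(ann))
  res <- enrich_terms(study, universe, annotations, pipeline_config())
  expect_setequal(res$term_id, c("ko03010", "ko03050"))
  expect_equal(res$percent_of_term[res$term_id == "ko03010"], 62.3)
  expect_equal(res$percent_of_term[res$term_id == "ko03050"], 62.9)
  # p-values match the tail statistic applied by hand, sorted ascending
  for (i in seq_len(nrow(res)))
    expect_equal(res$p_value[i],
                 hypergeom_upper_tail(res$x[i], res$m[i], res$n_term[i],
                                      res$N[i]))
  expect_true(!is.unsorted(res$p_value))
  # BH adjustment is computed over all tested terms before filtering
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("percent_of_term is invariant under universe size changes", {
  ann <- read_annotation_map(write_tsv(data.frame(
    term_id = "GO:0000010",
    gene_id = c(sprintf("s%02d", 1:8), sprintf("b%02d", 1:4)))))
  cfg <- pipeline_config(enrichment_alpha = 1)
  small <- enrich_terms(sprintf("s%02d", 1:8),
                        c(sprintf("s%02d", 1:8), sprintf("b%02d", 1:12)),
                        ann, cfg)
  big <- enrich_terms(sprintf("s%02d", 1:8),
                      c(sprintf("s%02d", 1:8), sprintf("b%02d", 1:4),
                        sprintf("x%03d", 1:500)),
                      ann, cfg)
  expect_equal(small$percent_of_term, big$percent_of_term)
})

test_that("min-gene and alpha filters commute", {
  set.seed(5)
  universe <- sprintf("u%03d", 1:120)
  study <- sample(universe, 40)
  ann <- do.call(rbind, lapply(1:12, function(i)
    data.frame(term_id = sprintf("GO:%07d", i),
               gene_id = sample(universe, sample(5:40, 1)))))
  annotations <- read_annotation_map(write_tsv(ann))
  cfg <- pipeline_config()
  res <- enrich_terms(study, universe, annotations, cfg)
  # recompute unfiltered, then filter in the opposite order
  all_res <- enrich_terms(study, universe, annotations,
                          pipeline_config(enrichment_min_genes = 0,
                                          enrichment_alpha = 1))
  byp <- all_res[all_res$p_value <= cfg$enrichment_alpha, ]
  byp <- byp[byp$x >= cfg$enrichment_min_genes, ]
  expect_setequal(res$term_id, byp$term_id)
  expect_error(enrich_terms(c(study, "stranger"), universe, annotations, cfg),
               "inside universe")
})
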