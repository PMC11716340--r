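test_that("profiles use the latest available scoring day per gene", {
  recs <- rbind(
    make_screen_df("G1", 30, c(7, 8), c(6, 8)),   # both days -> day 8
    make_screen_df("G2", 30, 7, 5))               # day 7 only
  prof <- build_profiles(recs, pipeline_config())
  expect_equal(prof$scoring_day[prof$gene_id == "G1"], 8)
  expect_equal(prof$leth_30[prof$gene_id == "G1"], 80)
  expect_equal(prof$scoring_day[prof$gene_id == "G2"], 7)

  cfg_early <- pipeline_config(day_rule = "earliest")
  prof_e <- build_profiles(recs, cfg_early)
  expect_equal(prof_e$leth_30[prof_e$gene_id == "G1"], 60)
})

test_that("genes without a scoring-day record are excluded with a warning", {
  recs <- rbind(make_screen_df("G1", 30, 7, 5),
                make_screen_df("G2", 30, 4, 5))
  expect_warning(prof <- build_profiles(recs, pipeline_config()), "excluded")
  expect_equal(prof$gene_id, "G1")
  expect_equal(attr(prof, "dropped"), "G2")
})

test_that("allow-lists restrict profiles to validated genes", {
  recs <- records_from_profiles(list(
    list(gene = "A", day = 7, doses = c(`30` = .8)),
    list(gene = "B", day = 7, doses = c(`30` = .9)),
    list(gene = "C", day = 7, doses = c(`30` = .1))))
  prof <- build_profiles(recs, pipeline_config(),
                         validated_genes = c("A", "B"))
  expect_setequal(prof$gene_id, c("A", "B"))
})

test_that("high-dose imputation copies the universal dose, idempotently", {
  recs <- records_from_profiles(list(
    list(gene = "A", day = 7, doses = c(`3` = .2, `30` = .8)),
    list(gene = "B", day = 7, doses = c(`3` = .2, `30` = .8, `300` = .9))))
  cfg <- pipeline_config()
  prof <- build_profiles(recs, cfg)
  imp <- impute_high_dose(prof, cfg)
  expect_equal(imp$leth_300[imp$gene_id == "A"], 80)
  expect_true(imp$imputed_300[imp$gene_id == "A"])
  # observed values never overwritten
  expect_equal(imp$leth_300[imp$gene_id == "B"], 90)
  expect_false(imp$imputed_300[imp$gene_id == "B"])
  # idempotence
  expect_identical(impute_high_dose(imp, cfg), imp)
  # imputation never changes which doses were tested
  expect_equal(imp$imputed_3, prof$imputed_3)
  expect_equal(is.na(imp$leth_3), is.na(prof$leth_3))
})

test_that("profiles missing both upper doses warn and stay unclusterable", {
  recs <- records_from_profiles(list(
    list(gene = "A", day = 7, doses = c(`3` = .2))))
  cfg <- pipeline_config()
  prof <- build_profiles(recs, cfg)
  expect_warning(imp <- impute_high_dose(prof, cfg), "missing both")
  expect_true(is.na(imp$leth_300))
  expect_warning(sub <- clustering_subset(imp, cfg), "empty")
  expect_equal(nrow(sub), 0)
})

test_that("flat selection takes exact 100% at the observed universal dose", {
  recs <- records_from_profiles(list(
    list(gene = "A", day = 7, doses = c(`30` = 1)),
    list(gene = "B", day = 7, doses = c(`30` = .9)),
    list(gene = "C", day = 7, doses = c(`3` = 1))))
  cfg <- pipeline_config()
  prof <- suppressWarnings(impute_high_dose(build_profiles(recs, cfg), cfg))
  expect_equal(flat_selection(prof, cfg), "A")
})

test_that("clustering subset matches a brute-force filter on known profiles", {
  spec <- list(
    list(gene = "P1", day = 7, doses = c(`3` = .9, `30` = 1,  `300` = 1)),
    list(gene = "P2", day = 7, doses = c(`3` = .1, `30` = .8, `300` = 1)),
    list(gene = "P3", day = 7, doses = c(`3` = .1, `30` = .7, `300` = 1)),
    list(gene = "P4", day = 8, doses = c(`30` = 1, `300` = 1)),
    list(gene = "P5", day = 7, doses = c(`3` = 0,  `30` = .75)),
    list(gene = "P6", day = 7, doses = c(`3` = .5, `30` = .2, `300` = .4)))
  cfg <- pipeline_config()
  prof <- impute_high_dose(build_profiles(records_from_profiles(spec), cfg),
                           cfg)
  sub <- clustering_subset(prof, cfg)
  # brute force over the stated rule: tested at 3 AND lethality(30) >= 75
  want <- vapply(spec, function(s)
    "3" %in% names(s$doses) && s$doses[["30"]] * 100 >= 75, logical(1))
  expect_setequal(sub$gene_id, vapply(spec, `[[`, "", "gene")[want])
  expect_true(all(sub$gene_id %in% prof$gene_id))
})

test_that("lowering the clustering lethality gate never shrinks the subset", {
  set.seed(7)
  spec <- lapply(1:40, function(i)
    list(gene = sprintf("g%02d", i), day = 7,
         doses = c(`3` = runif(1), `30` = runif(1), `300` = runif(1))))
  recs <- records_from_profiles(spec)
  sizes <- vapply(c(100, 90, 75, 50, 0), function(minl) {
    cfg <- pipeline_config(clustering_min_lethality_pct = minl)
    prof <- impute_high_dose(build_profiles(recs, cfg), cfg)
    nrow(suppressWarnings(clustering_subset(prof, cfg)))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})
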