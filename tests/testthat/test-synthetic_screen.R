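test_that("plant_truth apportions tiers by largest remainder, deterministically", {
  sc <- sim_config(n_genes = 10, tier_proportions = c(1, 0, 0, 0, 0, 0),
                   seed = 3)
  truth <- plant_truth(sc)
  expect_equal(nrow(truth), 10)
  expect_true(all(truth$true_tier == 0))
  expect_true(all(!is.finite(truth$lc50)))

  sc2 <- sim_config(n_genes = 200,
                    tier_proportions = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1),
                    seed = 5)
  counts <- table(factor(plant_truth(sc2)$true_tier, levels = 0:5))
  expect_equal(as.integer(counts), c(100L, 20L, 20L, 20L, 20L, 20L))

  # largest remainder on a non-trivial split: 7 * (0.4, 0.35, 0.25, 0, 0, 0)
  # quotas 2.8/2.45/1.75 -> floors 2/2/1, remainders .8/.45/.75 -> 3/2/2
  sc3 <- sim_config(n_genes = 7,
                    tier_proportions = c(0.4, 0.35, 0.25, 0, 0, 0), seed = 1)
  counts3 <- table(factor(plant_truth(sc3)$true_tier, levels = 0:2))
  expect_equal(as.integer(counts3), c(3L, 2L, 2L))

  expect_identical(plant_truth(sc2), plant_truth(sc2))
  expect_error(sim_config(tier_proportions = rep(0.2, 6)), "sum to 1")
})

test_that("expected_lethality follows the Hill form with hazard-combined background", {
  p <- list(lc50 = 30, hill = 2, max_lethality = 1, onset_day = 3)
  expect_equal(expected_lethality(p, dose = 0, day = 7, background = 0), 0)
  expect_equal(expected_lethality(p, dose = 30, day = 7, background = 0), 0.5)
  expect_equal(expected_lethality(p, dose = 300, day = 7, background = 0),
               90000 / 90900)  # dose^2 / (dose^2 + lc50^2)
  # before onset only background acts; hazards combine independently
  expect_equal(expected_lethality(p, dose = 300, day = 2, background = 0.1), 0.1)
  expect_equal(expected_lethality(p, dose = 30, day = 7, background = 0.2),
               1 - 0.8 * 0.5)
})

test_that("expected_lethality is monotone in dose and day and bounded", {
  set.seed(42)
  for (i in 1:25) {
    p <- list(lc50 = exp(runif(1, -1, 6)), hill = runif(1, 0.5, 3),
              max_lethality = runif(1), onset_day = sample(1:8, 1))
    doses <- sort(runif(8, 0, 1000))
    bg <- runif(1, 0, 0.5)
    along_dose <- expected_lethality(p, doses, day = 9, background = bg)
    expect_true(all(diff(along_dose) >= -1e-12))
    along_day <- vapply(0:10, function(d)
      expected_lethality(p, 100, d, bg), numeric(1))
    expect_true(all(diff(along_day) >= -1e-12))
    expect_true(all(along_dose >= bg - 1e-12 & along_dose <= 1 + 1e-12))
  }
})

test_that("simulate_screen is deterministic, valid, and saturates at p = 1", {
  sc <- sim_config(n_genes = 12, tier_proportions = c(0, 1, 0, 0, 0, 0),
                   days = c(7, 8), episodes = list(),
                   baseline_mortality = 0, seed = 9)
  truth <- plant_truth(sc)
  truth$lc50 <- 1e-6  # dose >> lc50, max_lethality 1 -> certain death
  screen <- simulate_screen(sc, truth)
  expect_silent(validate_screen_records(screen))
  treated <- screen[screen$gene_id != "CONTROL", ]
  expect_true(all(treated$n_dead == 10))
  expect_identical(simulate_screen(sc, truth), screen)
})

test_that("deaths are cumulative over days and controls carry background only", {
  sc <- sim_config(n_genes = 30, tier_proportions = c(0, 0, .5, .5, 0, 0),
                   days = c(5, 7, 8), seed = 21)
  screen <- simulate_screen(sc, plant_truth(sc))
  by_series <- split(screen, paste(screen$gene_id, screen$dose_ng_ul))
  for (s in by_series) {
    s <- s[order(s$day), ]
    expect_true(all(diff(s$n_dead) >= 0))
  }
  ctrl <- screen[screen$gene_id == "CONTROL", ]
  expect_true(all(ctrl$dose_ng_ul == 0))
  expect_equal(sort(unique(ctrl$batch)), sort(unique(screen$batch)))
})

test_that("simulated deaths match the binomial mean within 3 sigma", {
  # lc50 = dose and max 1 gives p = 0.5 exactly at every scoring day
  n_genes <- 1000
  sc <- sim_config(n_genes = n_genes, tier_proportions = c(0, 1, 0, 0, 0, 0),
                   doses = 30, days = 7, episodes = list(),
                   baseline_mortality = 0, seed = 17)
  truth <- plant_truth(sc)
  truth$lc50 <- 30; truth$hill <- 1; truth$max_lethality <- 1
  truth$onset_day <- 1
  screen <- simulate_screen(sc, truth)
  dead <- screen$n_dead[screen$gene_id != "CONTROL"]
  se <- sqrt(10 * 0.5 * 0.5 / n_genes)
  expect_lt(abs(mean(dead) - 5), 3 * se)
})

test_that("subsetting genes never reshuffles another gene's draws", {
  sc <- sim_config(n_genes = 20, tier_proportions = c(0, 0, 1, 0, 0, 0),
                   episodes = list(), seed = 13)
  truth <- plant_truth(sc)
  full <- simulate_screen(sc, truth)
  sub <- simulate_screen(sc, truth[6:10, ])
  sub_t <- sub[sub$gene_id != "CONTROL", ]
  full_t <- full[full$gene_id %in% sub_t$gene_id, ]
  key <- function(d) d[order(d$gene_id, d$dose_ng_ul, d$day),
                       c("gene_id", "dose_ng_ul", "day", "n_dead")]
  a <- key(full_t); b <- key(sub_t)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("background episodes raise mortality in the flagged batches", {
  sc <- sim_config(n_genes = 80, tier_proportions = c(1, 0, 0, 0, 0, 0),
                   batch_size = 20, days = 7,
                   episodes = list(list(batches = "B002",
                                        extra_mortality = 0.6)),
                   baseline_mortality = 0.02, seed = 8)
  screen <- simulate_screen(sc, plant_truth(sc))
  treated <- screen[screen$gene_id != "CONTROL", ]
  hit <- treated$n_dead[treated$batch == "B002"]
  clean <- treated$n_dead[treated$batch != "B002"]
  expect_gt(mean(hit), mean(clean) + 3)
})
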