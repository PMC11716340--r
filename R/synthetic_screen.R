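# Synthetic lethality-screen generator with planted ground truth.
#
# Each gene carries a log-logistic (Hill) dose-response with a hard onset
# day; treatment and background mortality combine as independent hazards so
# probabilities never exceed 1. Potency tiers 1-5 span the range from
# "kills at the lowest dose" to "partial kill at the highest dose only";
# tier 0 is non-lethal.

# Per-tier presets, spread along the admissible monotone dose-response
# range so adjacent tier centroids stay well separated (>= 40 percentage
# points apart in feature space) against binomial noise at cohort size 10.
# Approximate mean lethality (%) at 3/30/300 ng/uL, day 7:
#   tier 1: 95/100/100   tier 2: 30/95/100   tier 3:  2/45/97
#   tier 4:  0/ 8/ 60    tier 5:  0/ 1/ 10   tier 0:  0/ 0/  0
.TIER_PRESETS <- data.frame(
  true_tier     = 0:5,
  lc50          = c(Inf, 0.16, 5.0, 34, 216, 420),
  hill          = c(1, 1, 1.65, 1.60, 1.24, 1.20),
  max_lethality = c(0, 1, 1, 1, 1, 0.25),
  onset_day     = c(1, 3, 4, 4, 5, 6)
)

#' Simulation configuration
#'
#' Describes one synthetic screen: cohort size 10, the validation doses
#' 3/30/300 ng/uL scored on days 7 and 8 by default, a small baseline
#' control mortality, and optional episodes of elevated background mortality
#' affecting whole injection batches (emulating husbandry problems during a
#' long screen). With `episodes = NULL`, one episode covering roughly every
#' tenth batch with 30 extra percentage points of background mortality is
#' planted.
#'
#' @param n_genes number of genes to simulate.
#' @param tier_proportions six fractions (tiers 0-5, tier 0 = non-lethal)
#'   summing to 1.
#' @param n_injected animals per experiment.
#' @param doses dsRNA doses (ng/uL).
#' @param days scoring days post-injection.
#' @param episodes list of `list(batches = <labels>, extra_mortality = <frac>)`,
#'   `NULL` for the default planted episode, or `list()` for none.
#' @param baseline_mortality control mortality in unaffected batches.
#' @param batch_size genes injected per batch.
#' @param seed integer master seed of the keyed simulation stream.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200,
                       tier_proportions = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1),
                       n_injected = 10,
                       doses = c(3, 30, 300),
                       days = c(7, 8),
                       episodes = NULL,
                       baseline_mortality = 0.02,
                       batch_size = 40,
                       seed = 1L) {
  if (length(tier_proportions) != 6)
    .fail("tier_proportions must have 6 entries (tiers 0-5)")
  if (abs(sum(tier_proportions) - 1) > 1e-9)
    .fail("tier_proportions must sum to 1")
  if (any(tier_proportions < 0)) .fail("tier_proportions must be >= 0")
  if (baseline_mortality < 0 || baseline_mortality >= 1)
    .fail("baseline_mortality must lie in [0, 1)")
  n_batches <- max(1L, ceiling(n_genes / batch_size))
  if (is.null(episodes)) {
    hit <- if (n_batches >= 5L)
      sprintf("B%03d", seq(5L, n_batches, by = 10L)) else character()
    episodes <- if (length(hit)) {
      list(list(batches = hit, extra_mortality = 0.3))
    } else {
      list()
    }
  }
  for (ep in episodes) {
    if (ep$extra_mortality < 0 || ep$extra_mortality > 1)
      .fail("episode extra_mortality must lie in [0, 1]")
  }
  structure(list(n_genes = as.integer(n_genes),
                 tier_proportions = tier_proportions,
                 n_injected = as.integer(n_injected),
                 doses = doses, days = sort(days),
                 episodes = episodes,
                 baseline_mortality = baseline_mortality,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Largest-remainder apportionment of n among proportions p.
.largest_remainder <- function(n, p) {
  quota <- n * p
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(quota - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Plant ground-truth potency profiles
#'
#' Draws one potency profile per gene: a tier from the configured
#' proportions (largest-remainder apportionment, then a seeded shuffle so
#' batches mix tiers), the tier's preset Hill parameters, and a small
#' per-gene lognormal jitter on the LC50 so genes within a tier are not
#' identical.
#'
#' @param cfg a [sim_config()].
#' @return data frame gene_id, lc50, hill, max_lethality, onset_day,
#'   true_tier.
#' @export
plant_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- .largest_remainder(cfg$n_genes, cfg$tier_proportions)
  tiers <- rep(0:5, counts)
  .with_seed(cfg$seed, {
    tiers <- sample(tiers)
    jitter <- exp(stats::rnorm(cfg$n_genes, 0, 0.1))
  })
  idx <- match(tiers, .TIER_PRESETS$true_tier)
  out <- data.frame(
    gene_id = sprintf("SG%05d", seq_len(cfg$n_genes)),
    lc50 = .TIER_PRESETS$lc50[idx] * jitter,
    hill = .TIER_PRESETS$hill[idx],
    max_lethality = .TIER_PRESETS$max_lethality[idx],
    onset_day = .TIER_PRESETS$onset_day[idx],
    true_tier = tiers,
    stringsAsFactors = FALSE
  )
  out$lc50[out$true_tier == 0] <- Inf
  out
}

#' Expected lethality of one profile
#'
#' Hill dose-response gated by a hard onset day, combined with background
#' mortality as independent hazards:
#' `1 - (1 - background) * (1 - L)` with
#' `L = max_lethality * dose^h / (dose^h + lc50^h)` for days at or past
#' onset, else 0. Monotone non-decreasing in dose and day and bounded in
#' `[background, 1]`.
#'
#' @param profile one-row data frame (or list) with lc50, hill,
#'   max_lethality, onset_day.
#' @param dose dose in ng/uL (vectorized).
#' @param day integer day post-injection (vectorized).
#' @param background background mortality fraction.
#' @return expected dead fraction in `[0, 1]`.
#' @export
expected_lethality <- function(profile, dose, day, background = 0) {
  stopifnot(all(dose >= 0), all(day >= 0),
            background >= 0, background <= 1)
  dh <- dose^profile$hill
  lh <- profile$lc50^profile$hill
  L <- ifelse(dose > 0 & is.finite(profile$lc50),
              profile$max_lethality * dh / (dh + lh), 0)
  L <- ifelse(day >= profile$onset_day, L, 0)
  1 - (1 - background) * (1 - L)
}

# Background mortality of a batch under the configured episodes.
.batch_background <- function(batch, cfg) {
  bg <- cfg$baseline_mortality
  for (ep in cfg$episodes) {
    if (batch %in% ep$batches) bg <- 1 - (1 - bg) * (1 - ep$extra_mortality)
  }
  bg
}

#' Simulate a screen table from planted truth
#'
#' One record per (gene, dose, day) plus one dose-0 buffer-control record
#' per batch and day (gene_id "CONTROL"). Deaths are cumulative over days:
#' each animal draws a single uniform per (gene, dose) from a stream keyed
#' by (seed, gene, dose) and is dead by day d when the uniform falls below
#' the expected lethality at d — so each record's n_dead is marginally
#' Binomial(n, p) while deaths never decrease over time, and subsetting
#' genes never reshuffles another gene's draws.
#'
#' @param cfg a [sim_config()].
#' @param truth profile table from [plant_truth()].
#' @param phase phase label written into the records.
#' @return validated screen-record data frame.
#' @export
simulate_screen <- function(cfg, truth, phase = "validation") {
  stopifnot(inherits(cfg, "sim_config"))
  need <- c("gene_id", "lc50", "hill", "max_lethality", "onset_day")
  if (!all(need %in% names(truth))) .fail("truth table is missing columns")
  n_genes <- nrow(truth)
  batch_of <- sprintf("B%03d", (seq_len(n_genes) - 1L) %/% cfg$batch_size + 1L)
  rows <- vector("list", n_genes * length(cfg$doses) + 1L)
  ri <- 1L
  for (i in seq_len(n_genes)) {
    prof <- truth[i, ]
    bg <- .batch_background(batch_of[i], cfg)
    for (dose in cfg$doses) {
      u <- .with_seed(.sub_seed(cfg$seed, prof$gene_id, dose),
                      stats::runif(cfg$n_injected))
      p_day <- vapply(cfg$days, function(d)
        expected_lethality(prof, dose, d, bg), numeric(1))
      rows[[ri]] <- data.frame(
        gene_id = prof$gene_id, phase = phase, dose_ng_ul = dose,
        day = cfg$days,
        n_injected = cfg$n_injected,
        n_dead = vapply(p_day, function(p) sum(u < p), numeric(1)),
        batch = batch_of[i], species = "T_castaneum",
        stringsAsFactors = FALSE)
      ri <- ri + 1L
    }
  }
  ctrl <- lapply(unique(batch_of), function(b) {
    bg <- .batch_background(b, cfg)
    u <- .with_seed(.sub_seed(cfg$seed, paste0("CONTROL@", b), 0),
                    stats::runif(cfg$n_injected))
    data.frame(gene_id = "CONTROL", phase = phase, dose_ng_ul = 0,
               day = cfg$days, n_injected = cfg$n_injected,
               n_dead = vapply(cfg$days, function(d) sum(u < bg), numeric(1)),
               batch = b, species = "T_castaneum",
               stringsAsFactors = FALSE)
  })
  rows[[ri]] <- do.call(rbind, ctrl)
  validate_screen_records(do.call(rbind, rows))
}

#' Write a ground-truth profile table
#'
#' @param truth table from [plant_truth()].
#' @param path destination TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
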