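# Primary-screen lethality scoring and target selection.

#' Compute a lethality call for one gene/dose series
#'
#' Deaths recorded on or before `technical_death_day` are attributed to the
#' injection itself and excluded from both numerator and denominator (those
#' animals are treated as never enrolled). Death counts are cumulative over
#' days within the series.
#'
#' @param records screen records of a single gene, dose, batch and species
#'   at one or more days.
#' @param day scoring day; a record at this day must exist.
#' @param technical_death_day deaths up to and including this day are
#'   technical (0 disables the exclusion).
#' @return one-row data frame: gene_id, dose_ng_ul, day, batch, species,
#'   n_effective, dead_effective, lethality_pct (half-up, one decimal).
#' @export
compute_lethality <- function(records, day, technical_death_day = 2) {
  if (!nrow(records)) .fail("no records supplied")
  if (length(unique(records$gene_id)) != 1 ||
      length(unique(records$dose_ng_ul)) != 1)
    .fail("records must belong to a single gene and dose")
  at <- records[records$day == day, , drop = FALSE]
  if (!nrow(at)) .fail("no record at day ", day, " for gene ",
                       records$gene_id[1])
  at <- at[1, ]
  tech <- records[records$day <= technical_death_day, , drop = FALSE]
  tech_dead <- if (nrow(tech)) max(tech$n_dead) else 0
  n_eff <- at$n_injected - tech_dead
  if (n_eff < 1)
    stop(structure(class = c("degenerate_cohort", "error", "condition"),
                   list(message = paste0("whole cohort lost to technical ",
                                         "deaths for gene ", at$gene_id),
                        call = NULL)))
  dead_eff <- max(0, at$n_dead - tech_dead)
  data.frame(gene_id = at$gene_id, dose_ng_ul = at$dose_ng_ul, day = day,
             batch = at$batch, species = at$species,
             n_effective = n_eff, dead_effective = dead_eff,
             lethality_pct = round_half_up(100 * dead_eff / n_eff, 1),
             stringsAsFactors = FALSE)
}

#' Score every experiment of a screen table
#'
#' Applies [compute_lethality()] per (gene, dose, batch, species) group at
#' the phase's scoring day. Control rows (gene "CONTROL") are skipped.
#' Groups whose cohort is entirely lost to technical deaths are flagged in
#' the `degenerate` attribute rather than scored.
#'
#' @param records validated screen-record table.
#' @param day_by_phase named vector mapping phase to scoring day
#'   (default `c(I = 11, II = 7)`); phases absent from the map use
#'   `default_day`.
#' @param default_day scoring day for unmapped phases.
#' @param technical_death_day see [compute_lethality()].
#' @return calls data frame; attribute `degenerate` lists flagged gene ids.
#' @export
score_screen <- function(records, day_by_phase = c(I = 11, II = 7),
                         default_day = 7, technical_death_day = 2) {
  records <- records[records$gene_id != "CONTROL", , drop = FALSE]
  key <- paste(records$gene_id, records$phase, records$dose_ng_ul,
               records$batch, records$species, sep = "\r")
  calls <- list()
  degenerate <- character()
  for (grp in split(records, key)) {
    phase <- grp$phase[1]
    day <- if (phase %in% names(day_by_phase)) day_by_phase[[phase]] else default_day
    if (!any(grp$day == day)) next
    res <- tryCatch(compute_lethality(grp, day, technical_death_day),
                    degenerate_cohort = function(e) NULL)
    if (is.null(res)) {
      degenerate <- c(degenerate, grp$gene_id[1])
    } else {
      res$phase <- phase
      calls[[length(calls) + 1L]] <- res
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gene_id = character(), dose_ng_ul = numeric(),
               day = numeric(), batch = character(), species = character(),
               n_effective = numeric(), dead_effective = numeric(),
               lethality_pct = numeric(), phase = character())
  rownames(out) <- NULL
  attr(out, "degenerate") <- unique(degenerate)
  out
}

#' Partition genes into target / background / intermediate
#'
#' A gene is a target when its lethality reaches the primary threshold —
#' raised to the contamination cutoff for genes scored in a contaminated
#' batch, since episodes of elevated background mortality make sub-100%
#' calls unreliable there. Genes at or below the background ceiling form the
#' low-mortality background used later as the enrichment universe; the rest
#' are intermediate. The partition is exhaustive and disjoint.
#'
#' @param calls one lethality call per gene (columns gene_id,
#'   lethality_pct, and batch when `contaminated_batches` is non-empty).
#' @param cfg a [pipeline_config()].
#' @param contaminated_batches batch labels with elevated background
#'   mortality.
#' @return data frame gene_id, lethality_pct, contaminated_batch, set
#'   (factor target/background/intermediate).
#' @export
select_primary_targets <- function(calls, cfg = pipeline_config(),
                                   contaminated_batches = character()) {
  if (anyDuplicated(calls$gene_id))
    .fail("gene scored twice: ",
          calls$gene_id[duplicated(calls$gene_id)][1])
  contaminated <- if (length(contaminated_batches) && !is.null(calls$batch))
    calls$batch %in% contaminated_batches else rep(FALSE, nrow(calls))
  thr <- ifelse(contaminated, cfg$contamination_cutoff_pct,
                cfg$primary_threshold_pct)
  set <- ifelse(calls$lethality_pct >= thr, "target",
                ifelse(calls$lethality_pct <= cfg$background_max_lethality_pct,
                       "background", "intermediate"))
  out <- data.frame(gene_id = as.character(calls$gene_id),
                    lethality_pct = calls$lethality_pct,
                    contaminated_batch = contaminated,
                    set = factor(set, levels = c("target", "background",
                                                 "intermediate")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize a selection partition
#'
#' @param partition output of [select_primary_targets()].
#' @param universe_size total number of screened genes; must be at least the
#'   number of partitioned genes.
#' @return data frame set, n, pct_of_universe (half-up, one decimal).
#' @export
summarize_selection <- function(partition, universe_size) {
  if (universe_size <= 0) .fail("universe_size must be positive")
  if (universe_size < nrow(partition))
    .fail("universe_size smaller than the partitioned gene count")
  n <- table(partition$set)
  data.frame(set = names(n), n = as.integer(n),
             pct_of_universe = round_half_up(100 * as.integer(n) /
                                               universe_size, 1),
             stringsAsFactors = FALSE)
}
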