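# Cross-species transfer bioassays: success calls, per-tier rates, and the
# superior target-gene set.

#' Evaluate transfer success
#'
#' Default (absolute) mode: success when treated lethality exceeds control
#' lethality by strictly more than `cfg$transfer_delta_pct` percentage
#' points. Relative mode: success when treated > control * (1 + delta/100).
#' Both lethality values must be present — control mortality is never
#' imputed.
#'
#' @param records transfer table (columns source_gene, species,
#'   treated_pct, control_pct; see [read_transfer_table()]).
#' @param cfg a [pipeline_config()].
#' @return `records` with a logical `success` column and a `mode` attribute.
#' @export
evaluate_transfer <- function(records, cfg = pipeline_config()) {
  if (anyNA(records$treated_pct)) .fail("missing treated lethality")
  if (anyNA(records$control_pct)) .fail("missing control lethality")
  records$success <- if (cfg$transfer_mode == "absolute") {
    (records$treated_pct - records$control_pct) > cfg$transfer_delta_pct
  } else {
    records$treated_pct >
      records$control_pct * (1 + cfg$transfer_delta_pct / 100)
  }
  attr(records, "mode") <- cfg$transfer_mode
  records
}

#' Per-tier transfer rates
#'
#' @param records evaluated transfer table (with `success`).
#' @param assignments tiered assignment table; every tested source gene
#'   must carry a tier.
#' @return data frame tier, n_tested, n_success, rate_pct (rounded to the
#'   nearest integer; tiers with no tested genes are absent from the table,
#'   never reported as 0%).
#' @export
transfer_rates <- function(records, assignments) {
  tier <- assignments$tier[match(records$source_gene, assignments$gene_id)]
  if (anyNA(tier))
    .fail("tested gene without a tier: ",
          records$source_gene[which(is.na(tier))[1]])
  tab <- lapply(split(seq_len(nrow(records)), tier), function(idx) {
    data.frame(tier = tier[idx[1]], n_tested = length(idx),
               n_success = sum(records$success[idx]))
  })
  out <- do.call(rbind, tab)
  out$rate_pct <- as.integer(round_half_up(100 * out$n_success /
                                             out$n_tested, 0))
  out <- out[order(out$tier), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The superior target-gene set
#'
#' Source genes that transferred successfully and sit in efficacy tier 1.
#'
#' @param records evaluated transfer table.
#' @param assignments tiered assignment table.
#' @param cfg a [pipeline_config()] (unused thresholds kept for symmetry).
#' @return character vector of gene ids.
#' @export
define_superior <- function(records, assignments, cfg = pipeline_config()) {
  tier <- assignments$tier[match(records$source_gene, assignments$gene_id)]
  unique(records$source_gene[records$success & !is.na(tier) & tier == 1])
}
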