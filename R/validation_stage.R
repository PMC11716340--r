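# Validation screen: dose-response profiles, high-dose imputation, and the
# two selection outputs (flat 100%-at-middle-dose list; clustering subset).

.dose_col <- function(dose) sprintf("leth_%g", dose)

#' Build per-gene dose-response profiles
#'
#' For each gene the scoring day is resolved among `cfg$scoring_days`
#' according to `cfg$day_rule` (default: the latest day observed for that
#' gene), then lethality at each tested dose is computed with the technical
#' exclusion of [compute_lethality()]. Genes with no record at any scoring
#' day are excluded with a warning. When a gene/dose was run in several
#' batches, per-batch lethality fractions are pooled weighted by effective
#' cohort size.
#'
#' @param records validation-phase screen records.
#' @param cfg a [pipeline_config()].
#' @param validated_genes optional allow-list restricting profiles to these
#'   genes (the validation screen typically covers a curated subset of the
#'   primary targets).
#' @return data frame gene_id, scoring_day, one `leth_<dose>` column per
#'   validation dose (NA when untested) and one `imputed_<dose>` flag per
#'   dose (all FALSE here; see [impute_high_dose()]).
#' @export
build_profiles <- function(records, cfg = pipeline_config(),
                           validated_genes = NULL) {
  records <- records[records$gene_id != "CONTROL", , drop = FALSE]
  if (!is.null(validated_genes))
    records <- records[records$gene_id %in% validated_genes, , drop = FALSE]
  doses <- cfg$validation_doses
  genes <- unique(records$gene_id)
  rows <- vector("list", length(genes))
  dropped <- character()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    grec <- records[records$gene_id == g, , drop = FALSE]
    days_here <- sort(intersect(unique(grec$day), cfg$scoring_days))
    if (!length(days_here)) { dropped <- c(dropped, g); next }
    day <- switch(as.character(cfg$day_rule),
                  latest = max(days_here),
                  earliest = min(days_here),
                  {
                    d <- suppressWarnings(as.numeric(cfg$day_rule))
                    if (is.na(d) || !(d %in% days_here)) {
                      dropped <- c(dropped, g); next
                    }
                    d
                  })
    row <- list(gene_id = g, scoring_day = day)
    for (dose in doses) {
      drec <- grec[grec$dose_ng_ul == dose, , drop = FALSE]
      val <- NA_real_
      if (nrow(drec) && any(drec$day == day)) {
        per_batch <- lapply(split(drec, drec$batch), function(b) {
          tryCatch(compute_lethality(b, day, cfg$technical_death_day),
                   degenerate_cohort = function(e) NULL,
                   error = function(e) NULL)
        })
        per_batch <- Filter(Negate(is.null), per_batch)
        if (length(per_batch)) {
          cb <- do.call(rbind, per_batch)
          val <- round_half_up(
            100 * sum(cb$dead_effective) / sum(cb$n_effective), 1)
        }
      }
      row[[.dose_col(dose)]] <- val
      row[[sprintf("imputed_%g", dose)]] <- FALSE
    }
    rows[[gi]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("excluded ", length(dropped),
            " gene(s) with no record at any scoring day: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else {
    tmpl <- list(gene_id = character(), scoring_day = numeric())
    for (dose in doses) {
      tmpl[[.dose_col(dose)]] <- numeric()
      tmpl[[sprintf("imputed_%g", dose)]] <- logical()
    }
    as.data.frame(tmpl, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "doses") <- doses
  attr(out, "dropped") <- dropped
  out
}

#' Impute the highest dose from the universal dose
#'
#' Profiles missing the highest-dose observation have that value copied from
#' the universal (middle) dose and flagged as imputed; observed values are
#' never overwritten, so the operation is idempotent. Imputation runs only
#' toward the highest dose — the rationale being that the middle dose is a
#' conservative lower bound for response at a tenfold higher dose, which
#' does not hold in the other direction. Profiles missing both doses are
#' left untouched with a warning (they cannot enter clustering).
#'
#' @param profiles output of [build_profiles()].
#' @param cfg a [pipeline_config()].
#' @return profiles with the highest-dose column filled where possible.
#' @export
impute_high_dose <- function(profiles, cfg = pipeline_config()) {
  doses <- cfg$validation_doses
  hi <- .dose_col(doses[length(doses)])
  mid <- .dose_col(doses[length(doses) - 1])
  hi_flag <- sprintf("imputed_%g", doses[length(doses)])
  fillable <- is.na(profiles[[hi]]) & !is.na(profiles[[mid]])
  hopeless <- is.na(profiles[[hi]]) & is.na(profiles[[mid]])
  if (any(hopeless))
    warning(sum(hopeless), " profile(s) missing both ", mid, " and ", hi,
            "; excluded from clustering")
  profiles[[hi]][fillable] <- profiles[[mid]][fillable]
  profiles[[hi_flag]][fillable] <- TRUE
  profiles
}

#' Flat selection: complete kill at the universal dose
#'
#' Genes whose observed (never imputed) lethality at the universal middle
#' dose is exactly 100%.
#'
#' @param profiles profile table.
#' @param cfg a [pipeline_config()].
#' @return character vector of gene ids.
#' @export
flat_selection <- function(profiles, cfg = pipeline_config()) {
  doses <- cfg$validation_doses
  mid <- .dose_col(doses[length(doses) - 1])
  mid_flag <- sprintf("imputed_%g", doses[length(doses) - 1])
  keep <- !is.na(profiles[[mid]]) & !profiles[[mid_flag]] &
    profiles[[mid]] == 100
  profiles$gene_id[keep]
}

#' Clustering-eligible subset
#'
#' Keeps profiles tested at the lowest dose whose (post-imputation)
#' lethality at the universal dose reaches
#' `cfg$clustering_min_lethality_pct`. Run after [impute_high_dose()].
#'
#' @param profiles profile table, imputation applied.
#' @param cfg a [pipeline_config()].
#' @return subset of `profiles`.
#' @export
clustering_subset <- function(profiles, cfg = pipeline_config()) {
  doses <- cfg$validation_doses
  lo <- .dose_col(doses[1])
  lo_flag <- sprintf("imputed_%g", doses[1])
  mid <- .dose_col(doses[length(doses) - 1])
  hi <- .dose_col(doses[length(doses)])
  keep <- !is.na(profiles[[lo]]) & !profiles[[lo_flag]] &
    !is.na(profiles[[mid]]) & !is.na(profiles[[hi]]) &
    profiles[[mid]] >= cfg$clustering_min_lethality_pct
  out <- profiles[keep, , drop = FALSE]
  if (!nrow(out)) warning("clustering subset is empty")
  rownames(out) <- NULL
  attr(out, "doses") <- cfg$validation_doses
  out
}

#' Dose-response feature matrix
#'
#' @param profiles profile table (usually the clustering subset).
#' @param cfg a [pipeline_config()].
#' @return numeric matrix, one row per gene, one column per dose, rownames
#'   gene ids.
#' @export
profile_features <- function(profiles, cfg = pipeline_config()) {
  cols <- vapply(cfg$validation_doses, .dose_col, character(1))
  m <- as.matrix(profiles[, cols, drop = FALSE])
  rownames(m) <- profiles$gene_id
  if (anyNA(m)) .fail("feature matrix has missing values; impute first")
  m
}

#' Write a profile table
#'
#' @param profiles profile table.
#' @param path destination TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
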