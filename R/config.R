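#' Pipeline configuration
#'
#' Collects every screen constant used along the prioritization cascade.
#' Defaults mirror the screen design they encode: a 90% lethality threshold
#' for primary target calls, raised to 100% for genes scored in batches with
#' elevated background mortality; validation doses of 3/30/300 ng/uL scored
#' at day 7 or 8 post-injection; deaths on or before day 2 treated as
#' technical; a >=75% lethality-at-30 gate for clustering eligibility; five
#' k-means tiers with tiers 1-3 defining the most-effective set; >=5 study
#' genes and P <= 0.01 for enrichment reporting; <=50% mortality defining the
#' enrichment background; and a >50 percentage-point lethality increase over
#' controls for a successful cross-species transfer.
#'
#' @param primary_threshold_pct lethality (percent) at or above which a gene
#'   is a primary target.
#' @param contamination_cutoff_pct stricter threshold applied to genes scored
#'   in contaminated batches.
#' @param validation_doses dsRNA doses (ng/uL) of the validation screen,
#'   strictly increasing; the middle dose is injected for every gene, the
#'   highest dose is the imputation recipient.
#' @param scoring_days candidate scoring days for dose-response profiles;
#'   the latest day observed per gene is used.
#' @param technical_death_day deaths on or before this day post-injection are
#'   excluded from both numerator and denominator (0 disables).
#' @param clustering_min_lethality_pct minimum lethality at the universal
#'   (middle) dose for a profile to enter clustering.
#' @param k_range integers scanned by the elbow method.
#' @param k_fixed if non-NULL, overrides elbow selection with a fixed k.
#' @param most_effective_tiers efficacy tiers pooled into the
#'   most-effective set.
#' @param enrichment_min_genes minimum study-set genes in a term for the term
#'   to be reported.
#' @param enrichment_alpha raw p-value cutoff for reported terms.
#' @param enrichment_universe `"target_background"` (default) restricts the
#'   enrichment universe to targets plus low-mortality background;
#'   `"full"` uses every scored gene.
#' @param min_genes_on `"study"` (default) applies `enrichment_min_genes` to
#'   study-set genes in the term; `"term"` applies it to term size.
#' @param adjust_p compute Benjamini-Hochberg adjusted p-values (reported
#'   alongside, never used for filtering).
#' @param background_max_lethality_pct mortality at or below which a gene
#'   belongs to the low-mortality background.
#' @param transfer_delta_pct lethality increase over controls required for
#'   transfer success.
#' @param transfer_mode `"absolute"` (default): success when
#'   treated - control > delta percentage points; `"relative"`: success when
#'   treated > control * (1 + delta/100).
#' @param day_rule `"latest"` (default), `"earliest"`, or a fixed day as a
#'   number: which scoring day to use when several are observed.
#' @param standardize_features z-score dose-response features before
#'   clustering (off by default; all features share the 0-100 percent scale).
#' @param n_restarts k-means restarts per k.
#' @param seed integer seed governing clustering restarts.
#'
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(primary_threshold_pct = 90,
                            contamination_cutoff_pct = 100,
                            validation_doses = c(3, 30, 300),
                            scoring_days = c(7, 8),
                            technical_death_day = 2,
                            clustering_min_lethality_pct = 75,
                            k_range = 1:10,
                            k_fixed = 5,
                            most_effective_tiers = c(1, 2, 3),
                            enrichment_min_genes = 5,
                            enrichment_alpha = 0.01,
                            enrichment_universe = c("target_background", "full"),
                            min_genes_on = c("study", "term"),
                            adjust_p = TRUE,
                            background_max_lethality_pct = 50,
                            transfer_delta_pct = 50,
                            transfer_mode = c("absolute", "relative"),
                            day_rule = "latest",
                            standardize_features = FALSE,
                            n_restarts = 25,
                            seed = 1L) {
  enrichment_universe <- match.arg(enrichment_universe)
  min_genes_on <- match.arg(min_genes_on)
  transfer_mode <- match.arg(transfer_mode)
  pcts <- c(primary_threshold_pct, contamination_cutoff_pct,
            clustering_min_lethality_pct, background_max_lethality_pct,
            transfer_delta_pct)
  if (any(pcts < 0 | pcts > 100))
    .fail("all percentage thresholds must lie in [0, 100]")
  if (any(diff(validation_doses) <= 0))
    .fail("validation_doses must be strictly increasing")
  if (enrichment_alpha <= 0 || enrichment_alpha > 1)
    .fail("enrichment_alpha must lie in (0, 1]")
  if (!is.null(k_fixed) && (k_fixed < 1 || k_fixed != round(k_fixed)))
    .fail("k_fixed must be a positive integer or NULL")
  structure(list(
    primary_threshold_pct = primary_threshold_pct,
    contamination_cutoff_pct = contamination_cutoff_pct,
    validation_doses = validation_doses,
    scoring_days = sort(scoring_days),
    technical_death_day = technical_death_day,
    clustering_min_lethality_pct = clustering_min_lethality_pct,
    k_range = k_range,
    k_fixed = k_fixed,
    most_effective_tiers = most_effective_tiers,
    enrichment_min_genes = enrichment_min_genes,
    enrichment_alpha = enrichment_alpha,
    enrichment_universe = enrichment_universe,
    min_genes_on = min_genes_on,
    adjust_p = adjust_p,
    background_max_lethality_pct = background_max_lethality_pct,
    transfer_delta_pct = transfer_delta_pct,
    transfer_mode = transfer_mode,
    day_rule = day_rule,
    standardize_features = standardize_features,
    n_restarts = n_restarts,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their `pipeline_config()` defaults; unknown
#' keys are an error, so typos never silently fall back to defaults.
#'
#' @param path path to a YAML file of `pipeline_config()` arguments.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .fail("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) .fail("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-30s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}
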