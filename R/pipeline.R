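# End-to-end orchestration: primary selection -> validation profiles ->
# tier clustering -> enrichment -> transfer, with a machine-readable run
# report. Stages whose inputs are absent are skipped and logged.

.as_table <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the prioritization pipeline
#'
#' Executes every stage whose input is present, in order. Each input may be
#' a TSV path or an already-loaded data frame. The returned report carries
#' the resolved configuration, per-stage summaries, every warning any stage
#' emitted, and the selection chain (primary targets -> validated ->
#' clustering subset -> most effective -> superior), whose counts are
#' non-increasing by construction.
#'
#' @param inputs list with any of: `primary` (screen table),
#'   `validation` (screen table), `annotation` (annotation table),
#'   `transfer` (transfer table); each a path or data frame.
#' @param cfg a [pipeline_config()].
#' @param contaminated_batches batch labels under elevated background
#'   mortality (stricter primary cutoff).
#' @param validated_genes optional allow-list for the validation stage;
#'   defaults to the primary target set.
#' @param universe_size total screened genes for percentage reporting;
#'   defaults to the number of scored genes.
#' @param day_by_phase scoring-day map for the primary screen.
#' @param out_dir if non-NULL, stage outputs (TSVs) and the report are
#'   written here.
#' @return a `run_report` list; stage result tables are in its `tables`
#'   element.
#' @export
run_pipeline <- function(inputs, cfg = pipeline_config(),
                         contaminated_batches = character(),
                         validated_genes = NULL,
                         universe_size = NULL,
                         day_by_phase = c(I = 11, II = 7),
                         out_dir = NULL) {
  warnings <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  report <- list(config = unclass(cfg), seed = cfg$seed,
                 stage_summaries = list(), selection_chain = list())
  tables <- list()

  primary <- .as_table(inputs$primary, read_screen_table)
  partition <- NULL
  if (!is.null(primary)) {
    stage("primary", {
      calls <- collect(score_screen(primary, day_by_phase = day_by_phase,
                                    technical_death_day =
                                      cfg$technical_death_day))
      partition <- collect(select_primary_targets(calls, cfg,
                                                  contaminated_batches))
      usize <- if (is.null(universe_size)) nrow(partition) else universe_size
      tables$partition <- partition
      report$stage_summaries$primary <- list(
        genes_scored = nrow(partition),
        degenerate = length(attr(calls, "degenerate")),
        summary = summarize_selection(partition, usize))
      report$selection_chain$primary_targets <-
        sum(partition$set == "target")
    })
  }

  validation <- .as_table(inputs$validation, read_screen_table)
  tiered <- NULL
  if (!is.null(validation)) {
    stage("validation", {
      allow <- validated_genes
      if (is.null(allow) && !is.null(partition))
        allow <- partition$gene_id[partition$set == "target"]
      profiles <- collect(build_profiles(validation, cfg, allow))
      profiles <- collect(impute_high_dose(profiles, cfg))
      flat <- flat_selection(profiles, cfg)
      subset <- collect(clustering_subset(profiles, cfg))
      tables$profiles <- profiles
      tables$clustering_subset <- subset
      report$stage_summaries$validation <- list(
        profiles = nrow(profiles),
        imputed = sum(profiles[[sprintf("imputed_%g",
          cfg$validation_doses[length(cfg$validation_doses)])]]),
        flat_selection = length(flat),
        clustering_eligible = nrow(subset))
      report$selection_chain$validated <- nrow(profiles)
      report$selection_chain$clustering_subset <- nrow(subset)
      if (nrow(subset) >= 2) {
        res <- stage("clustering", tier_profiles(subset, cfg))
        tiered <- res$assignments
        tables$assignments <- tiered
        tables$elbow <- res$elbow
        eff <- define_most_effective(tiered, cfg)
        tables$most_effective <- eff
        report$stage_summaries$clustering <- list(
          k = res$k,
          tier_sizes = as.list(table(tiered$tier)),
          most_effective = length(eff))
        report$selection_chain$most_effective <- length(eff)
      }
    })
  }

  annotation <- .as_table(inputs$annotation, read_annotation_map)
  if (!is.null(annotation) && !is.null(partition)) {
    stage("enrichment", {
      uni <- build_universe(partition, cfg)
      enr <- enrich_terms(uni$study, uni$universe, annotation, cfg)
      tables$enrichment <- enr
      report$stage_summaries$enrichment <- list(
        study = length(uni$study), universe = length(uni$universe),
        terms_reported = nrow(enr))
    })
  }

  transfer <- .as_table(inputs$transfer, read_transfer_table)
  if (!is.null(transfer) && !is.null(tiered)) {
    stage("transfer", {
      ev <- evaluate_transfer(transfer, cfg)
      rates <- transfer_rates(ev, tiered)
      superior <- define_superior(ev, tiered, cfg)
      tables$transfer <- ev
      tables$transfer_rates <- rates
      tables$superior <- superior
      report$stage_summaries$transfer <- list(
        tested = nrow(ev), successes = sum(ev$success),
        rates = rates, superior = length(superior))
      report$selection_chain$superior <- length(superior)
    })
  }

  report$warnings <- warnings
  report$tables <- tables
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) if (!is.null(df))
      utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    wt(tables$partition, "partition")
    wt(tables$profiles, "profiles")
    wt(tables$assignments, "assignments")
    wt(tables$elbow, "elbow")
    wt(tables$enrichment, "enrichment")
    if (!is.null(tables$transfer)) wt(tables$transfer, "transfer")
    wt(tables$transfer_rates, "transfer_rates")
    write_report(report, file.path(out_dir, "report"))
  }
  report
}

#' Write a run report
#'
#' Writes `<path>.json` (structured, timestamp-free, hence byte-identical
#' across reruns with the same seed and inputs) and `<path>.txt` (a short
#' human-readable summary).
#'
#' @param report a `run_report`.
#' @param path destination path without extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- report[c("config", "seed", "stage_summaries", "selection_chain",
                   "warnings")]
  jsonlite::write_json(json, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  con <- file(paste0(path, ".txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("RNAi target prioritization run (seed %d)", report$seed)
  chain <- report$selection_chain
  if (length(chain))
    w("selection chain: %s",
      paste(sprintf("%s=%s", names(chain), unlist(chain)), collapse = " -> "))
  for (nm in names(report$stage_summaries))
    w("stage %-11s %s", nm, paste(utils::capture.output(
      utils::str(report$stage_summaries[[nm]], give.attr = FALSE))[1],
      collapse = ""))
  if (length(report$warnings)) {
    w("warnings:")
    for (msg in report$warnings) w("  - %s", msg)
  }
  invisible(path)
}

#' Read back a run report
#'
#' @param path path without extension, as given to [write_report()].
#' @return the report structure parsed from JSON.
#' @export
read_report <- function(path) {
  jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  chain <- x$selection_chain
  cat("<run_report> seed", x$seed, "\n")
  if (length(chain))
    cat("  ", paste(sprintf("%s=%s", names(chain), unlist(chain)),
                    collapse = " -> "), "\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
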