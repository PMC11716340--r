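# Tabular I/O for screen records, annotation maps and ortholog maps.
# All files are TSV with a mandatory header and dot-decimal numerals.

.SCREEN_COLS <- c("gene_id", "phase", "dose_ng_ul", "day",
                  "n_injected", "n_dead", "batch", "species")
.PHASES <- c("I", "II", "validation", "transfer")

#' Validate a screen-record table
#'
#' Enforces the screen-record contract on an in-memory data frame: cohort
#' counts within range, non-negative doses and days, known phase labels and
#' unique (gene, phase, dose, day, batch, species) keys. Every rejection
#' names the offending row.
#'
#' @param df data frame with the screen-table columns.
#' @return the validated data frame, row order preserved.
#' @export
validate_screen_records <- function(df) {
  missing <- setdiff(.SCREEN_COLS, names(df))
  if (length(missing))
    .fail("screen table is missing column(s): ", paste(missing, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  df$phase <- as.character(df$phase)
  df$batch <- as.character(df$batch)
  df$species <- as.character(df$species)
  for (col in c("dose_ng_ul", "day", "n_injected", "n_dead")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) .fail("non-numeric value in ", col, row = bad[1])
    df[[col]] <- v
  }
  chk <- function(cond, what) {
    bad <- which(!cond)
    if (length(bad)) .fail(what, row = bad[1])
  }
  chk(!is.na(df$gene_id) & nzchar(df$gene_id), "empty gene_id")
  chk(df$phase %in% .PHASES,
      paste0("phase must be one of ", paste(.PHASES, collapse = "/")))
  chk(!is.na(df$dose_ng_ul) & df$dose_ng_ul >= 0, "dose must be >= 0")
  chk(!is.na(df$day) & df$day >= 0 & df$day == round(df$day),
      "day must be a non-negative integer")
  chk(!is.na(df$n_injected) & df$n_injected >= 1 &
        df$n_injected == round(df$n_injected),
      "n_injected must be a positive integer")
  chk(!is.na(df$n_dead) & df$n_dead >= 0 & df$n_dead == round(df$n_dead),
      "n_dead must be a non-negative integer")
  chk(df$n_dead <= df$n_injected, "n_dead exceeds n_injected")
  key <- paste(df$gene_id, df$phase, df$dose_ng_ul, df$day, df$batch,
               df$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    .fail("duplicate (gene, phase, dose, day, batch, species) key", row = dup[1])
  rownames(df) <- NULL
  df
}

#' Read a screen table
#'
#' Reads a TSV of injection/feeding experiments (one row per gene, dose and
#' scoring day) and validates it. A file with a header and no rows yields an
#' empty, correctly typed table.
#'
#' @param path TSV path with columns gene_id, phase, dose_ng_ul, day,
#'   n_injected, n_dead, batch, species.
#' @param phase_hint optional phase label; if given, rows of any other phase
#'   are rejected.
#' @return validated data frame of screen records.
#' @export
read_screen_table <- function(path, phase_hint = NULL) {
  if (!file.exists(path)) .fail("screen table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  df <- validate_screen_records(df)
  if (!is.null(phase_hint)) {
    bad <- which(df$phase != phase_hint)
    if (length(bad))
      .fail("expected phase ", phase_hint, ", found ", df$phase[bad[1]],
            row = bad[1])
  }
  df
}

#' Write a screen table
#'
#' @param df validated screen-record data frame.
#' @param path destination TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(df, path) {
  df <- validate_screen_records(df)
  utils::write.table(df[, .SCREEN_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an annotation map
#'
#' Reads term-to-gene annotations (GO or KEGG style) and aggregates genes per
#' term with set semantics: a duplicated (term, gene) pair is stored once.
#' Accepts the native dialect (term_id, gene_id, optional term_name and
#' ontology) or, with `dialect = "gaf"`, GAF 2.2 column order (gene in
#' column 2, term in column 5) with comment lines skipped; no evidence-code
#' or qualifier semantics are applied.
#'
#' @param path TSV path.
#' @param dialect `"native"` or `"gaf"`.
#' @return data frame with one row per term: term_id, term_name, ontology,
#'   n_genes, and a list-column `gene_ids`.
#' @export
read_annotation_map <- function(path, dialect = c("native", "gaf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .fail("annotation file not found: ", path)
  if (dialect == "gaf") {
    raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                             comment.char = "!", colClasses = "character")
    if (nrow(raw) && ncol(raw) < 5)
      .fail("GAF input needs at least 5 columns")
    df <- if (nrow(raw)) {
      data.frame(term_id = raw[[5]], gene_id = raw[[2]],
                 term_name = "", ontology = "",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(term_id = character(), gene_id = character(),
                 term_name = character(), ontology = character())
    }
  } else {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
    if (!all(c("term_id", "gene_id") %in% names(df)))
      .fail("annotation table needs term_id and gene_id columns")
    if (is.null(df$term_name)) df$term_name <- ""
    if (is.null(df$ontology)) df$ontology <- ""
  }
  if (!nrow(df)) {
    warning("annotation file has no rows: ", path)
    return(data.frame(term_id = character(), term_name = character(),
                      ontology = character(), n_genes = integer(),
                      gene_ids = I(list())))
  }
  bad <- which(!grepl("^(GO:\\d{7}|ko\\d{5}|[A-Za-z][\\w:.-]*)$", df$term_id))
  if (length(bad)) .fail("malformed term identifier: ", df$term_id[bad[1]],
                         row = bad[1])
  df <- df[nzchar(df$gene_id), , drop = FALSE]
  split_genes <- split(df$gene_id, df$term_id)
  terms <- names(split_genes)
  first <- match(terms, df$term_id)
  out <- data.frame(term_id = terms,
                    term_name = df$term_name[first],
                    ontology = df$ontology[first],
                    stringsAsFactors = FALSE)
  out$gene_ids <- I(lapply(split_genes, function(g) sort(unique(g))))
  out$n_genes <- vapply(out$gene_ids, length, integer(1))
  out <- out[out$n_genes > 0, c("term_id", "term_name", "ontology",
                                "n_genes", "gene_ids")]
  rownames(out) <- NULL
  out
}

#' Read an ortholog map
#'
#' One row per (source gene, target species); an empty target_gene marks a
#' source gene without an ortholog in that species (`mapped = FALSE`).
#' Duplicate (source, species) rows with conflicting targets are rejected.
#'
#' @param path TSV path with columns source_gene, target_species, target_gene.
#' @return data frame source_gene, target_species, target_gene, mapped.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) .fail("ortholog map not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("source_gene", "target_species", "target_gene")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .fail("ortholog map is missing column(s): ", paste(missing, collapse = ", "))
  df$target_gene[is.na(df$target_gene)] <- ""
  key <- paste(df$source_gene, df$target_species, sep = "\r")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      tg <- unique(df$target_gene[key == k])
      if (length(tg) > 1)
        .fail("conflicting targets for (",
              gsub("\r", ", ", k), "): ", paste(tg, collapse = " vs "))
    }
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df$mapped <- nzchar(df$target_gene)
  rownames(df) <- NULL
  df[, c(need, "mapped")]
}

#' Read a transfer-bioassay table
#'
#' @param path TSV with columns source_gene, species, dose_g_ha, day,
#'   treated_pct, control_pct.
#' @return validated data frame.
#' @export
read_transfer_table <- function(path) {
  if (!file.exists(path)) .fail("transfer table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  need <- c("source_gene", "species", "dose_g_ha", "day",
            "treated_pct", "control_pct")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .fail("transfer table is missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("treated_pct", "control_pct")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0 | df[[col]] > 100)
    if (length(bad)) .fail(col, " must lie in [0, 100]", row = bad[1])
  }
  bad <- which(df$day > 10)
  if (length(bad)) .fail("assay day exceeds the 10-day protocol limit",
                         row = bad[1])
  rownames(df) <- NULL
  df
}
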