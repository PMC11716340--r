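# Hypergeometric over-representation of annotation terms in the target set
# against the low-mortality background.

#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `x` term genes when `m` genes are drawn
#' without replacement from a universe of `N` genes of which `n_term` carry
#' the term:
#' p = sum_{i=x}^{min(m, n_term)} C(n_term, i) C(N - n_term, m - i) / C(N, m).
#' Terms are accumulated in log space (lchoose + log-sum-exp) so deeply
#' significant terms do not underflow.
#'
#' @param x observed study-set genes in the term.
#' @param m study-set size.
#' @param n_term term size in the universe.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(x, m, n_term, N) {
  if (any(c(x, m, n_term, N) < 0) || n_term > N || m > N)
    .fail("invalid hypergeometric bounds")
  if (x > min(m, n_term))
    .fail("x exceeds min(m, n_term)")
  if (x == 0) return(1)
  i <- x:min(m, n_term)
  lt <- lchoose(n_term, i) + lchoose(N - n_term, m - i) - lchoose(N, m)
  lt <- lt[is.finite(lt)]
  if (!length(lt)) return(0)
  mx <- max(lt)
  min(1, exp(mx + log(sum(exp(lt - mx)))))
}

#' Build the enrichment study set and universe
#'
#' The study set is the primary target genes; the universe is, by default,
#' targets plus the low-mortality background, excluding intermediate genes
#' (the comparison is "lethal versus clearly non-lethal"). Genes without any
#' annotation stay in the universe count.
#'
#' @param partition output of [select_primary_targets()].
#' @param cfg a [pipeline_config()]; `cfg$enrichment_universe = "full"`
#'   includes intermediate genes.
#' @return list with `study` and `universe` character vectors.
#' @export
build_universe <- function(partition, cfg = pipeline_config()) {
  study <- partition$gene_id[partition$set == "target"]
  background <- partition$gene_id[partition$set == "background"]
  if (!length(background)) .fail("empty low-mortality background")
  universe <- if (cfg$enrichment_universe == "full")
    partition$gene_id else c(study, background)
  list(study = study, universe = unique(universe))
}

#' Term over-representation in the study set
#'
#' Restricts each term to the universe, computes the upper-tail
#' hypergeometric p-value for its overlap with the study set, adjusts over
#' all tested terms (Benjamini-Hochberg) when enabled, then keeps terms with
#' at least `cfg$enrichment_min_genes` study genes and raw
#' p <= `cfg$enrichment_alpha`, sorted by ascending p. `percent_of_term` is
#' the share of a term's universe genes that are study genes — a pure count
#' ratio independent of N.
#'
#' @param study character vector of study-set gene ids (subset of universe).
#' @param universe character vector of universe gene ids.
#' @param annotations annotation table from [read_annotation_map()].
#' @param cfg a [pipeline_config()].
#' @return data frame term_id, term_name, ontology, x, m, n_term, N,
#'   p_value, p_adjusted, percent_of_term.
#' @export
enrich_terms <- function(study, universe, annotations,
                         cfg = pipeline_config()) {
  study <- unique(study)
  universe <- unique(universe)
  if (!all(study %in% universe)) .fail("study set must lie inside universe")
  m <- length(study)
  N <- length(universe)
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    genes <- intersect(annotations$gene_ids[[i]], universe)
    n_term <- length(genes)
    if (n_term == 0) return(NULL)
    x <- length(intersect(genes, study))
    data.frame(term_id = annotations$term_id[i],
               term_name = annotations$term_name[i],
               ontology = annotations$ontology[i],
               x = x, m = m, n_term = n_term, N = N,
               p_value = hypergeom_upper_tail(x, m, n_term, N),
               percent_of_term = round_half_up(100 * x / n_term, 1),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      ontology = character(), x = integer(), m = integer(),
                      n_term = integer(), N = integer(), p_value = numeric(),
                      p_adjusted = numeric(), percent_of_term = numeric()))
  res <- do.call(rbind, rows)
  res$p_adjusted <- if (cfg$adjust_p) stats::p.adjust(res$p_value, "BH")
                    else NA_real_
  size <- if (cfg$min_genes_on == "study") res$x else res$n_term
  res <- res[size >= cfg$enrichment_min_genes &
               res$p_value <= cfg$enrichment_alpha, , drop = FALSE]
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("term_id", "term_name", "ontology", "x", "m", "n_term", "N",
          "p_value", "p_adjusted", "percent_of_term")]
}
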