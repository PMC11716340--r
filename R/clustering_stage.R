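# k-means tiering of dose-response features with elbow-based k selection.
# Features are raw percentages (all on the same 0-100 scale); standardize
# via cfg$standardize_features if desired.

.kmeans_w <- function(features, k, seed, n_restarts) {
  .with_seed(seed, stats::kmeans(features, centers = k, nstart = n_restarts,
                                 iter.max = 100))
}

#' Within-cluster sum-of-squares curve
#'
#' Runs seeded, multi-restart k-means for each k and records the total
#' within-cluster sum of squares W(k).
#'
#' @param features numeric matrix (rows = genes).
#' @param k_range integer ks to scan; shrunk with a warning when it exceeds
#'   the number of distinct rows.
#' @param seed integer seed.
#' @param n_restarts restarts per k.
#' @return data frame with columns k and W.
#' @export
elbow_curve <- function(features, k_range = 1:10, seed = 1L,
                        n_restarts = 25) {
  n_distinct <- nrow(unique(features))
  if (max(k_range) > n_distinct) {
    warning("k_range shrunk to the ", n_distinct, " distinct feature rows")
    k_range <- k_range[k_range <= n_distinct]
  }
  W <- vapply(k_range, function(k)
    .kmeans_w(features, k, seed + k, n_restarts)$tot.withinss, numeric(1))
  data.frame(k = k_range, W = W)
}

#' Choose k by the elbow method
#'
#' Picks the interior k maximizing the discrete second difference
#' W(k-1) - 2 W(k) + W(k+1) of the within-cluster sum-of-squares curve —
#' the sharpest bend of the curve. Degenerate inputs (all rows identical)
#' return 1. Deterministic given the seed.
#'
#' @inheritParams elbow_curve
#' @return list with `k` (the chosen value) and `curve` (the W(k) table).
#' @export
choose_k_elbow <- function(features, k_range = 1:10, seed = 1L,
                           n_restarts = 25) {
  if (nrow(unique(features)) == 1)
    return(list(k = 1L, curve = data.frame(k = 1L, W = 0)))
  curve <- elbow_curve(features, k_range, seed, n_restarts)
  if (nrow(curve) < 3) return(list(k = curve$k[which.min(curve$W)], curve = curve))
  d2 <- diff(curve$W, differences = 2)  # W(k-1) - 2W(k) + W(k+1), interior ks
  k <- curve$k[which.max(d2) + 1L]
  list(k = as.integer(k), curve = curve)
}

#' Cluster genes by dose-response features
#'
#' Standard Euclidean k-means on unscaled percent features, best of
#' `n_restarts` random starts by within-cluster sum of squares, seeded for
#' determinism.
#'
#' @param features numeric matrix with gene ids as rownames.
#' @param k number of clusters (1 <= k <= rows).
#' @param seed integer seed.
#' @param n_restarts restarts.
#' @param standardize z-score columns before clustering.
#' @return data frame gene_id, cluster_raw, plus one column per feature;
#'   attribute `kmeans` holds the full fit.
#' @export
cluster_genes <- function(features, k, seed = 1L, n_restarts = 25,
                          standardize = FALSE) {
  if (k < 1 || k > nrow(features))
    .fail("k must lie in 1..", nrow(features))
  fit_feats <- if (standardize) scale(features) else features
  fit <- .kmeans_w(fit_feats, k, seed, n_restarts)
  out <- data.frame(gene_id = rownames(features),
                    cluster_raw = as.integer(fit$cluster),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(features))
  rownames(out) <- NULL
  attr(out, "kmeans") <- fit
  out
}

#' Assign efficacy-ordered tiers
#'
#' Relabels raw k-means clusters into tiers ordered by potency: clusters
#' sorted by descending mean lethality averaged over all doses, ties broken
#' by descending mean at the lowest dose, then by smallest raw label.
#' Tier 1 is the most potent.
#'
#' @param assignments output of [cluster_genes()].
#' @param features the feature matrix used for clustering.
#' @return `assignments` with a `tier` column.
#' @export
assign_tiers <- function(assignments, features) {
  stopifnot(nrow(assignments) == nrow(features))
  raw <- sort(unique(assignments$cluster_raw))
  overall <- vapply(raw, function(cl)
    mean(features[assignments$cluster_raw == cl, , drop = FALSE]), numeric(1))
  low <- vapply(raw, function(cl)
    mean(features[assignments$cluster_raw == cl, 1]), numeric(1))
  ord <- order(-overall, -low, raw)
  tier_of <- integer(max(raw))
  tier_of[raw[ord]] <- seq_along(raw)
  assignments$tier <- tier_of[assignments$cluster_raw]
  assignments
}

#' The most-effective gene set
#'
#' Union of genes in the configured top efficacy tiers.
#'
#' @param assignments tiered assignment table from [assign_tiers()].
#' @param cfg a [pipeline_config()].
#' @return character vector of gene ids.
#' @export
define_most_effective <- function(assignments, cfg = pipeline_config()) {
  assignments$gene_id[assignments$tier %in% cfg$most_effective_tiers]
}

#' Cluster, choose k and tier in one call
#'
#' @param profiles clustering-eligible profile table.
#' @param cfg a [pipeline_config()]; `cfg$k_fixed` overrides the elbow.
#' @return list: `assignments` (tiered table), `k`, `elbow` (W(k) table or
#'   NULL when k was fixed).
#' @export
tier_profiles <- function(profiles, cfg = pipeline_config()) {
  features <- profile_features(profiles, cfg)
  if (!is.null(cfg$k_fixed)) {
    k <- min(cfg$k_fixed, nrow(unique(features)))
    if (k < cfg$k_fixed)
      warning("k_fixed shrunk to ", k, " distinct feature rows")
    elbow <- NULL
  } else {
    sel <- choose_k_elbow(features, cfg$k_range, cfg$seed, cfg$n_restarts)
    k <- sel$k
    elbow <- sel$curve
  }
  assignments <- cluster_genes(features, k, cfg$seed, cfg$n_restarts,
                               cfg$standardize_features)
  assignments <- assign_tiers(assignments, features)
  list(assignments = assignments, k = k, elbow = elbow)
}
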