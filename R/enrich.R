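# Gene-set over-representation with an enrichment-ratio statistic,
# cross-dataset term ranking, categorical directionality matrices, and a
# substrate-set z-score for kinase/phosphatase activity inference.

#' Over-representation of gene sets among significant genes
#'
#' For each term, counts the overlap `k` between the dataset's significant
#' genes and the term's members (both intersected with the dataset's
#' measured-gene universe) and computes the upper-tail hypergeometric
#' probability `P[X >= k]` for `X ~ Hypergeom(N, K, n_sig)`. The enrichment
#' ratio is `k / n_sig`: the number of differentially regulated hits
#' belonging to the term, normalised to the total number of significant
#' hits in the dataset (not a fold enrichment). A term is significant when
#' `-log10(p) >= log10_cut`.
#'
#' The default test is one-sided (upper tail), the natural direction for
#' over-representation; `alternative = "two.sided"` doubles the smaller
#' tail (capped at 1) for users who want a two-tailed reading of the
#' cutoff. Term p-values are unadjusted by default; `adjust` applies a
#' [stats::p.adjust()] method before the cutoff.
#'
#' @param sig_genes character vector of significant HGNC symbols (subset of
#'   `universe`).
#' @param universe character vector: genes measured in the dataset after
#'   harmonisation.
#' @param db named list of term member vectors (see [read_gmt()]) or the
#'   `db` element of [gen_gene_set_db()].
#' @param log10_cut significance cutoff on -log10(p); 2 for disease-
#'   ontology screens, 1.3 (p < 0.05) for pathway modules.
#' @param dataset_id optional id copied to the output.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param adjust p-adjustment method, default `"none"`.
#' @return data.frame, one row per term: `dataset_id`, `term_id`, `k`, `K`,
#'   `n_sig`, `N`, `p_value`, `enrichment_ratio`, `significant`, and
#'   `undefined_ratio` flagging the degenerate `n_sig = 0` case (ratio
#'   reported as 0).
#' @export
overrepresentation <- function(sig_genes, universe, db, log10_cut = 2,
                               dataset_id = NA_character_,
                               alternative = c("greater", "two.sided"),
                               adjust = "none") {
  alternative <- match.arg(alternative)
  stopifnot(log10_cut > 0)
  universe <- unique(universe)
  sig_genes <- unique(sig_genes)
  if (!all(sig_genes %in% universe)) {
    stop_panrenal("sig_genes must be a subset of the universe")
  }
  N <- length(universe)
  n_sig <- length(sig_genes)
  term_ids <- names(db)
  K <- integer(length(db))
  k <- integer(length(db))
  for (i in seq_along(db)) {
    members <- intersect(db[[i]], universe)
    K[i] <- length(members)
    k[i] <- sum(sig_genes %in% members)
  }
  if (n_sig == 0L) {
    p <- rep(1, length(db))
  } else {
    # P[X >= k], upper tail of Hypergeom(N, K, n_sig)
    p_up <- stats::phyper(k - 1L, K, N - K, n_sig, lower.tail = FALSE)
    if (alternative == "greater") {
      p <- p_up
    } else {
      p_lo <- stats::phyper(k, K, N - K, n_sig, lower.tail = TRUE)
      p <- pmin(1, 2 * pmin(p_up, p_lo))
    }
  }
  if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
  ratio <- if (n_sig > 0) k / n_sig else rep(0, length(db))
  out <- data.frame(
    dataset_id = dataset_id, term_id = term_ids, k = k, K = K,
    n_sig = n_sig, N = N, p_value = p, enrichment_ratio = ratio,
    significant = -log10(p) >= log10_cut,
    undefined_ratio = n_sig == 0L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Rank terms across datasets
#'
#' Orders terms by the cross-dataset replication rules: 1) number of
#' datasets in which the term is significant (descending); 2) most
#' significant (minimum) p-value across datasets (ascending); 3) greatest
#' enrichment ratio across datasets (descending); residual ties broken by
#' term id.
#'
#' @param results row-bound [overrepresentation()] results from one or more
#'   datasets.
#' @return data.frame, one row per term in display order: `term_id`,
#'   `n_datasets_significant`, `min_p`, `max_enrichment_ratio`.
#' @export
rank_terms <- function(results) {
  stopifnot(nrow(results) >= 1,
            all(c("term_id", "p_value", "enrichment_ratio",
                  "significant") %in% names(results)))
  terms <- unique(results$term_id)
  n_rep <- vapply(terms, function(t)
    sum(results$significant[results$term_id == t]), 0L)
  min_p <- vapply(terms, function(t)
    min(results$p_value[results$term_id == t]), 0)
  max_er <- vapply(terms, function(t)
    max(results$enrichment_ratio[results$term_id == t]), 0)
  ord <- order(-n_rep, min_p, -max_er, terms)
  out <- data.frame(term_id = terms[ord],
                    n_datasets_significant = as.integer(n_rep[ord]),
                    min_p = min_p[ord],
                    max_enrichment_ratio = max_er[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Categorical directionality matrix
#'
#' Classifies each (feature, dataset) pair as `up`, `down`,
#' `not-significant` or `not-observed` for categorical heatmaps of, e.g.,
#' differential abundance in faecal microbial taxa. A pair is `up`/`down`
#' iff its p-value is at most `10^-threshold_log10` with the corresponding
#' fold-change sign.
#'
#' @param records data.frame with `dataset_id`, an id column (`feature_id`
#'   or `hgnc_symbol`), `log2fc` and `p_value`; or gene-level calls with
#'   `direction`, `significant` and `best_p`.
#' @param threshold_log10 -log10(p) cutoff, default 1.3 (p <= 0.0501).
#' @param dataset_id dataset id used when `records` has no `dataset_id`
#'   column.
#' @return data.frame `id`, `dataset_id`, `state` covering the full id x
#'   dataset grid.
#' @export
directionality_matrix <- function(records, threshold_log10 = 1.3,
                                  dataset_id = "dataset") {
  id_col <- intersect(c("feature_id", "hgnc_symbol"), names(records))[1]
  if (is.na(id_col)) stop_panrenal("records need feature_id or hgnc_symbol")
  if (!"dataset_id" %in% names(records)) records$dataset_id <- dataset_id
  if (all(c("direction", "best_p") %in% names(records))) {
    p <- records$best_p
    sgn <- records$direction
  } else {
    p <- records$p_value
    sgn <- sign_int(records$log2fc)
  }
  cut <- 10^(-threshold_log10)
  state <- ifelse(p <= cut & sgn > 0, "up",
                  ifelse(p <= cut & sgn < 0, "down", "not-significant"))
  ids <- unique(records[[id_col]])
  ds <- unique(records$dataset_id)
  grid <- expand.grid(id = ids, dataset_id = ds, stringsAsFactors = FALSE)
  key <- paste(records[[id_col]], records$dataset_id, sep = "\r")
  hit <- match(paste(grid$id, grid$dataset_id, sep = "\r"), key)
  grid$state <- ifelse(is.na(hit), "not-observed", state[hit])
  grid
}

#' Kinase/phosphatase activity from substrate-site fold changes
#'
#' Substrate-set enrichment z-score: for an enzyme with `m` known substrate
#' sites, `z = (mean(substrate log2fc) - mean(all log2fc)) * sqrt(m) /
#' sd(all log2fc)`. Two-sided p-values from the standard normal, false
#' discovery controlled across enzymes by Benjamini-Hochberg; activity
#' calls at `q < 0.05` by convention.
#'
#' @param site_log2fcs named numeric vector: phosphosite -> log2 fold
#'   change (the background distribution).
#' @param enzyme_map named list: enzyme -> character vector of substrate
#'   site ids.
#' @param min_m minimum number of quantified substrate sites; enzymes below
#'   it are skipped (default 3).
#' @return data.frame per retained enzyme: `enzyme_id`, `m`, `z`,
#'   `p_value`, `q`, `significant`, ordered by `z`.
#' @export
ksea <- function(site_log2fcs, enzyme_map, min_m = 3L) {
  stopifnot(length(site_log2fcs) >= 2, !is.null(names(site_log2fcs)))
  mu <- mean(site_log2fcs)
  s <- stats::sd(site_log2fcs)
  if (s == 0) stop_panrenal("zero variance in the site background")
  rows <- lapply(names(enzyme_map), function(e) {
    sites <- intersect(enzyme_map[[e]], names(site_log2fcs))
    m <- length(sites)
    if (m < min_m) return(NULL)
    z <- (mean(site_log2fcs[sites]) - mu) * sqrt(m) / s
    data.frame(enzyme_id = e, m = m, z = z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(enzyme_id = character(), m = integer(), z = numeric(),
                      p_value = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out$p_value <- 2 * stats::pnorm(-abs(out$z))
  out$q <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q < 0.05
  out <- out[order(out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}
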