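# Multi-dataset consensus scoring of differentially regulated gene products
# (DRGPs). Each significant, directional observation of a gene in a
# kidney-specific core (proteome/transcriptome) dataset contributes +1 or
# -1; the sum S is multiplied by the number of core observations n to give
# the product score P = S * n. Genes pass the plotting filter when
# |P| >= 9 and |P| != 12, i.e. when the directional majority margin is at
# least three datasets.

#' Consensus product score across core datasets
#'
#' Computes, for every gene observed anywhere, the direction-score sum `S`
#' over core datasets (+1 per significant upregulation, -1 per significant
#' downregulation), the number of core observations `n` (significant,
#' directional calls only; tied direction-0 calls count toward neither),
#' the product score `P = S * n`, and the plotting flag
#' `|P| >= 9 & |P| != 12`. Calls from non-core datasets (epiproteome,
#' epigenome, plasma/exosome sources, metabolome) never feed the score but
#' are retained in the per-dataset direction matrix for display.
#'
#' @param calls gene-level calls (see [collapse_features()]).
#' @param descriptors dataset descriptors; every `dataset_id` in `calls`
#'   must be present, and `core_scoring` marks kidney-specific
#'   proteome/transcriptome datasets.
#' @return an object of class `drgp_consensus`: a data.frame with columns
#'   `hgnc_symbol`, `S`, `n`, `P`, `plotted`, carrying the full gene x
#'   dataset direction matrix in `attr(, "directions")` (entries +1/-1/0,
#'   `NA` = not observed) and the descriptors in `attr(, "descriptors")`.
#' @examples
#' calls <- data.frame(
#'   dataset_id = c("ds1", "ds2", "ds3"), hgnc_symbol = "TUBA1A",
#'   direction = 1L, significant = TRUE, best_p = 0.01,
#'   n_features_collapsed = 1L
#' )
#' descr <- data.frame(
#'   dataset_id = c("ds1", "ds2", "ds3"), mission = "M", species = "mouse",
#'   tissue = "kidney", modality = "proteome", kidney_specific = TRUE,
#'   core_scoring = TRUE
#' )
#' score_drgp(calls, descr) # S = 3, n = 3, P = 9, plotted
#' @export
score_drgp <- function(calls, descriptors) {
  validate_descriptors(descriptors)
  need <- c("dataset_id", "hgnc_symbol", "direction", "significant")
  stopifnot(all(need %in% names(calls)))
  unknown <- setdiff(calls$dataset_id, descriptors$dataset_id)
  if (length(unknown)) {
    stop_panrenal("calls reference datasets without descriptors: ",
                  paste(unknown, collapse = ", "))
  }
  genes <- sort(unique(calls$hgnc_symbol))
  ds <- descriptors$dataset_id
  dirs <- matrix(NA_integer_, length(genes), length(ds),
                 dimnames = list(genes, ds))
  if (nrow(calls)) {
    shown <- ifelse(calls$significant, calls$direction, 0L)
    dirs[cbind(match(calls$hgnc_symbol, genes),
               match(calls$dataset_id, ds))] <- shown
  }
  core <- descriptors$core_scoring
  core_dirs <- dirs[, core, drop = FALSE]
  contributes <- !is.na(core_dirs) & core_dirs != 0L
  S <- as.integer(rowSums(core_dirs * contributes, na.rm = TRUE))
  n <- as.integer(rowSums(contributes))
  P <- S * n
  out <- data.frame(hgnc_symbol = genes, S = S, n = n, P = P,
                    plotted = abs(P) >= 9L & abs(P) != 12L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "directions") <- dirs
  attr(out, "descriptors") <- descriptors
  class(out) <- c("drgp_consensus", "data.frame")
  out
}

#' Split plotted consensus scores into ranked up/down lists
#'
#' Genes passing the plotting filter are split by the sign of `P` and each
#' list is sorted by `|P|` descending, ties broken by `n` descending then
#' gene symbol; `P = 0` is never plotted.
#'
#' @param scores a `drgp_consensus` object or its data.frame.
#' @return list with `up` and `down` data.frames in display order.
#' @export
filter_and_rank <- function(scores) {
  df <- as.data.frame(scores)
  keep <- df[df$plotted & df$P != 0L, , drop = FALSE]
  ord <- function(x) {
    x[order(-abs(x$P), -x$n, x$hgnc_symbol), , drop = FALSE]
  }
  up <- ord(keep[keep$P > 0L, , drop = FALSE])
  down <- ord(keep[keep$P < 0L, , drop = FALSE])
  rownames(up) <- rownames(down) <- NULL
  list(up = up, down = down)
}

#' Achievable product scores
#'
#' The set of values `S * n` reachable with `0 <= n <= n_max` core
#' observations, `|S| <= n` and `S` congruent to `n` modulo 2 (each
#' observation contributes exactly +1 or -1). Useful to see which filter
#' thresholds are attainable: with six core datasets, 10 and 11 are not
#' achievable and 12 only as |S| = 2, n = 6 — the configuration the
#' plotting filter excludes for having a directional margin below three.
#'
#' @param n_max maximum number of core observations.
#' @return sorted integer vector of achievable products.
#' @export
achievable_products <- function(n_max) {
  stopifnot(n_max >= 0)
  prods <- 0L
  for (n in seq_len(n_max)) {
    S <- seq(-n, n, by = 2L)
    prods <- c(prods, S * n)
  }
  sort(unique(as.integer(prods)))
}

#' @export
print.drgp_consensus <- function(x, ...) {
  df <- as.data.frame(x)
  descr <- attr(x, "descriptors")
  cat("DRGP consensus scores\n")
  cat(sprintf("  %d genes over %d datasets (%d core)\n", nrow(df),
              nrow(descr), sum(descr$core_scoring)))
  cat(sprintf("  %d genes pass the plotting filter (|P| >= 9, |P| != 12)\n",
              sum(df$plotted)))
  top <- df[df$plotted, , drop = FALSE]
  top <- top[order(-abs(top$P)), , drop = FALSE]
  if (nrow(top)) {
    cat("  strongest consensus:\n")
    print(utils::head(top, 10), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.drgp_consensus <- function(object, ...) {
  df <- as.data.frame(object)
  ranked <- filter_and_rank(object)
  structure(list(n_genes = nrow(df),
                 n_plotted = sum(df$plotted),
                 n_up = nrow(ranked$up), n_down = nrow(ranked$down),
                 product_range = range(df$P),
                 up = ranked$up, down = ranked$down),
            class = "summary.drgp_consensus")
}

#' @export
print.summary.drgp_consensus <- function(x, ...) {
  cat(sprintf(
    "DRGP consensus: %d genes, %d plotted (%d up, %d down), P in [%d, %d]\n",
    x$n_genes, x$n_plotted, x$n_up, x$n_down,
    x$product_range[1], x$product_range[2]))
  if (x$n_up) {
    cat("upregulated:\n")
    print(x$up, row.names = FALSE)
  }
  if (x$n_down) {
    cat("downregulated:\n")
    print(x$down, row.names = FALSE)
  }
  invisible(x)
}

#' Categorical direction heatmap of a consensus result
#'
#' Displays the per-dataset direction matrix (up / down / not significant /
#' not observed) for the genes passing the plotting filter, core datasets
#' first — the display the ranking rules were designed for.
#'
#' @param x a `drgp_consensus` object.
#' @param max_genes cap on displayed genes (strongest |P| first).
#' @param ... ignored.
#' @export
plot.drgp_consensus <- function(x, max_genes = 40L, ...) {
  dirs <- attr(x, "directions")
  descr <- attr(x, "descriptors")
  df <- as.data.frame(x)
  keep <- df[df$plotted, , drop = FALSE]
  keep <- keep[order(-keep$P), , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop_panrenal("no genes pass the plotting filter")
  }
  keep <- utils::head(keep, max_genes)
  ds_order <- order(-descr$core_scoring)
  m <- dirs[keep$hgnc_symbol, ds_order, drop = FALSE]
  z <- m
  z[is.na(z)] <- -2L # not observed
  cols <- c("white", "grey85", "#2166AC", "#B2182B") # NA, 0, down, up
  lev <- c(-2L, 0L, -1L, 1L)
  zi <- matrix(match(z, lev), nrow(z), ncol(z))
  op <- par(mar = c(6, 7, 2, 1))
  on.exit(par(op))
  image(seq_len(ncol(m)), seq_len(nrow(m)), t(zi[rev(seq_len(nrow(zi))), ,
                                                 drop = FALSE]),
        col = cols, zlim = c(1, 4), axes = FALSE, xlab = "", ylab = "",
        main = "DRGP direction by dataset")
  axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Tidy a consensus result for export
#'
#' @param x a `drgp_consensus` object.
#' @param row.names,optional,... standard [as.data.frame()] arguments.
#' @param long if `TRUE`, return the long per-(gene, dataset) direction
#'   table (columns `hgnc_symbol`, `dataset_id`, `direction`,
#'   `core_scoring`) instead of the per-gene score table.
#' @export
as.data.frame.drgp_consensus <- function(x, row.names = NULL,
                                         optional = FALSE, long = FALSE,
                                         ...) {
  if (long) {
    dirs <- attr(x, "directions")
    descr <- attr(x, "descriptors")
    out <- data.frame(
      hgnc_symbol = rep(rownames(dirs), ncol(dirs)),
      dataset_id = rep(colnames(dirs), each = nrow(dirs)),
      direction = as.integer(dirs),
      stringsAsFactors = FALSE
    )
    out <- out[!is.na(out$direction), , drop = FALSE]
    out$core_scoring <- descr$core_scoring[match(out$dataset_id,
                                                 descr$dataset_id)]
    rownames(out) <- NULL
    return(out)
  }
  cls <- class(x)
  attr(x, "directions") <- NULL
  attr(x, "descriptors") <- NULL
  class(x) <- "data.frame"
  x
}
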