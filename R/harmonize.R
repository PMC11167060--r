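# Harmonisation: re-key heterogeneous differential features to HGNC gene
# symbols through an ortholog map, then collapse multiple features per gene
# (phosphosites, isoforms, CpG sites) to one direction/significance call per
# (dataset, gene).

#' Map differential-feature records to HGNC symbols
#'
#' Human records keep their symbol (HGNC maps to itself); non-human records
#' are looked up in the ortholog map by (species, native symbol). Unmapped
#' symbols are dropped and counted. One-to-many orthologs are handled by
#' `policy`: `"drop_ambiguous"` (default; avoids double-counting a native
#' symbol in the downstream consensus), `"expand_all"` (one output record
#' per target), or `"first_alphabetical"`.
#'
#' @param records data.frame of differential feature records (columns as in
#'   [read_dataset_table()]). Taxon records carry no symbol and are dropped
#'   with a count.
#' @param map ortholog map data.frame (`species`, `native_symbol`,
#'   `hgnc_symbol`).
#' @param policy ambiguity policy, see above.
#' @return the mapped records with an `hgnc_symbol` column, and an attribute
#'   `report`: counts of `mapped`, `unmapped`, `ambiguous_dropped` and
#'   `taxon_skipped` records (`mapped` counts input records, so
#'   features_in = mapped + unmapped + ambiguous_dropped + taxon_skipped).
#' @export
map_to_hgnc <- function(records, map,
                        policy = c("drop_ambiguous", "expand_all",
                                   "first_alphabetical")) {
  policy <- match.arg(policy)
  stopifnot(all(DATASET_COLUMNS %in% names(records)))
  is_taxon <- records$feature_class == "taxon"
  taxon_skipped <- sum(is_taxon)
  records <- records[!is_taxon, , drop = FALSE]
  if (nrow(records) == 0L) {
    out <- cbind(records, hgnc_symbol = character(0))
    attr(out, "report") <- list(mapped = 0L, unmapped = 0L,
                                ambiguous_dropped = 0L,
                                taxon_skipped = taxon_skipped)
    return(out)
  }
  unknown <- setdiff(records$species, c("human", map$species))
  if (length(unknown)) {
    stop_panrenal("species not in ortholog map: ",
                  paste(unknown, collapse = ", "))
  }
  is_human <- records$species == "human"
  key <- paste(records$species, records$symbol, sep = "\r")
  map_key <- paste(map$species, map$native_symbol, sep = "\r")
  targets <- split(map$hgnc_symbol, map_key)
  n_targets <- lengths(targets)[key]
  n_targets[is.na(n_targets)] <- 0L
  n_targets[is_human] <- 1L

  unmapped <- !is_human & n_targets == 0L
  ambiguous <- !is_human & n_targets > 1L
  ambiguous_dropped <- 0L

  pieces <- list()
  simple <- records[!unmapped & !ambiguous, , drop = FALSE]
  simple_key <- key[!unmapped & !ambiguous]
  hgnc <- simple$symbol # human records map to themselves
  nonhuman <- simple$species != "human"
  if (any(nonhuman)) {
    hgnc[nonhuman] <- vapply(targets[simple_key[nonhuman]], `[`, "", 1L)
  }
  simple$hgnc_symbol <- unname(hgnc)
  pieces$simple <- simple

  if (any(ambiguous)) {
    amb <- records[ambiguous, , drop = FALSE]
    amb_targets <- targets[key[ambiguous]]
    if (policy == "drop_ambiguous") {
      ambiguous_dropped <- nrow(amb)
    } else if (policy == "first_alphabetical") {
      amb$hgnc_symbol <- vapply(amb_targets, function(t) sort(t)[1], "")
      pieces$amb <- amb
    } else { # expand_all
      reps <- lengths(amb_targets)
      amb <- amb[rep(seq_len(nrow(amb)), reps), , drop = FALSE]
      amb$hgnc_symbol <- unlist(amb_targets, use.names = FALSE)
      pieces$amb <- amb
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "report") <- list(
    mapped = sum(!unmapped & !ambiguous) + if (policy == "drop_ambiguous")
      0L else sum(ambiguous),
    unmapped = sum(unmapped),
    ambiguous_dropped = ambiguous_dropped,
    taxon_skipped = taxon_skipped
  )
  out
}

#' Collapse mapped features to one call per (dataset, gene)
#'
#' A gene is significant in a dataset iff at least one of its features has
#' p below `alpha`. The direction is the sign of the sum of signs of the
#' log2 fold changes over the significant features (majority vote; a tie, or
#' no significant feature, gives direction 0, and tied genes are excluded
#' from consensus scoring downstream). `best_p` is the minimum p over
#' significant features, or over all features when none is significant.
#' A log2 fold change of exactly 0 contributes sign 0.
#'
#' Collapsing is idempotent and invariant to record order.
#'
#' @param records mapped records carrying `hgnc_symbol` (see
#'   [map_to_hgnc()]); may span several datasets if a `dataset_id` column is
#'   present, otherwise `dataset_id` must name the single dataset.
#' @param alpha per-feature significance threshold in (0,1); default 0.05 on
#'   unadjusted p-values.
#' @param dataset_id dataset id used when `records` has no `dataset_id`
#'   column.
#' @param adjust optional p-adjustment method applied across the dataset's
#'   features before thresholding (`"none"` default; any
#'   [stats::p.adjust()] method).
#' @return data.frame of gene-level calls: `dataset_id`, `hgnc_symbol`,
#'   `direction` (+1/-1/0), `significant`, `best_p`,
#'   `n_features_collapsed`.
#' @export
collapse_features <- function(records, alpha = 0.05, dataset_id = NULL,
                              adjust = "none") {
  stopifnot(alpha > 0, alpha < 1)
  if (!"dataset_id" %in% names(records) && nrow(records) > 0L) {
    if (is.null(dataset_id)) {
      stop_panrenal("records lack dataset_id; supply dataset_id=")
    }
    records$dataset_id <- dataset_id
  }
  if (nrow(records) == 0L) {
    return(data.frame(dataset_id = character(), hgnc_symbol = character(),
                      direction = integer(), significant = logical(),
                      best_p = numeric(), n_features_collapsed = integer(),
                      stringsAsFactors = FALSE))
  }
  stopifnot("hgnc_symbol" %in% names(records))
  p <- records$p_value
  if (adjust != "none") {
    for (ds in unique(records$dataset_id)) {
      i <- records$dataset_id == ds
      p[i] <- stats::p.adjust(p[i], method = adjust)
    }
  }
  sig <- p < alpha
  key <- interaction(records$dataset_id, records$hgnc_symbol, drop = TRUE)
  sgn <- sign_int(records$log2fc)
  dir_sum <- tapply(ifelse(sig, sgn, 0L), key, sum)
  any_sig <- tapply(sig, key, any)
  best_p_sig <- tapply(ifelse(sig, p, Inf), key, min)
  best_p_all <- tapply(p, key, min)
  n_feat <- tapply(sig, key, length)
  first <- !duplicated(key)
  ord <- levels(key)
  lookup <- match(ord, key[first])
  out <- data.frame(
    dataset_id = records$dataset_id[first][lookup],
    hgnc_symbol = records$hgnc_symbol[first][lookup],
    direction = sign_int(as.numeric(dir_sum[ord])),
    significant = as.logical(any_sig[ord]),
    best_p = ifelse(as.logical(any_sig[ord]),
                    as.numeric(best_p_sig[ord]),
                    as.numeric(best_p_all[ord])),
    n_features_collapsed = as.integer(n_feat[ord]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$dataset_id, out$hgnc_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonise a set of dataset tables end to end
#'
#' Maps every table to HGNC and collapses to gene-level calls, returning the
#' combined call table plus a per-dataset harmonisation report.
#'
#' @param tables named list of differential-feature tables (names are
#'   dataset ids).
#' @param map ortholog map.
#' @param alpha,policy,adjust passed to [map_to_hgnc()] and
#'   [collapse_features()].
#' @return list with `calls` (combined gene-level calls) and `report`
#'   (per-dataset mapping counts, JSON-serialisable).
#' @export
harmonize_datasets <- function(tables, map, alpha = 0.05,
                               policy = "drop_ambiguous", adjust = "none") {
  stopifnot(is.list(tables), !is.null(names(tables)))
  calls <- list()
  report <- list()
  for (id in names(tables)) {
    mapped <- map_to_hgnc(tables[[id]], map, policy = policy)
    report[[id]] <- attr(mapped, "report")
    calls[[id]] <- collapse_features(mapped, alpha = alpha,
                                     dataset_id = id, adjust = adjust)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  list(calls = out, report = report)
}
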