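# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops, exhaustive enumeration) and never call the code paths
# they check.

# Small, fast config for module tests; the defaults (the study-scale
# conditions) are exercised in the acceptance suite.
small_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, n_genes = 400L, n_planted_consensus = 6L,
                    n_terms = 20L, term_size_range = c(8L, 40L),
                    chem_n_subjects = 8L, ...)
}

make_descriptors <- function(ids, core = rep(TRUE, length(ids))) {
  data.frame(
    dataset_id = ids, mission = "M", species = "mouse",
    tissue = ifelse(core, "kidney", "plasma"),
    modality = ifelse(core, "proteome", "plasma"),
    kidney_specific = core, core_scoring = core,
    stringsAsFactors = FALSE
  )
}

make_calls <- function(gene, dataset_id, direction, significant = TRUE,
                       best_p = 0.01) {
  data.frame(
    dataset_id = dataset_id, hgnc_symbol = gene,
    direction = as.integer(direction), significant = significant,
    best_p = best_p, n_features_collapsed = 1L, stringsAsFactors = FALSE
  )
}

# Brute-force consensus scorer: explicit per-gene, per-dataset loop.
oracle_score <- function(calls, descriptors) {
  genes <- sort(unique(calls$hgnc_symbol))
  out <- data.frame(hgnc_symbol = genes, S = 0L, n = 0L, P = 0L,
                    plotted = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    S <- 0L
    n <- 0L
    for (j in seq_len(nrow(calls))) {
      if (calls$hgnc_symbol[j] != genes[i]) next
      ds <- which(descriptors$dataset_id == calls$dataset_id[j])
      if (!descriptors$core_scoring[ds]) next
      if (!calls$significant[j]) next
      if (calls$direction[j] == 0L) next
      S <- S + calls$direction[j]
      n <- n + 1L
    }
    out$S[i] <- S
    out$n[i] <- n
    out$P[i] <- S * n
    out$plotted[i] <- abs(S * n) >= 9L && abs(S * n) != 12L
  }
  out
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every possible
# draw of n_sig genes from N and count overlaps >= k.
oracle_hyper <- function(k, K, N, n_sig) {
  draws <- utils::combn(N, n_sig)
  hits <- colSums(draws <= K) # genes 1..K are the term members
  mean(hits >= k)
}

# Pairwise comparator for the term-ranking rules, used with a naive
# selection sort.
oracle_rank <- function(results) {
  terms <- unique(results$term_id)
  stat <- lapply(terms, function(t) {
    r <- results[results$term_id == t, ]
    list(rep = sum(r$significant), minp = min(r$p_value),
         er = max(r$enrichment_ratio), id = t)
  })
  before <- function(a, b) {
    if (a$rep != b$rep) return(a$rep > b$rep)
    if (a$minp != b$minp) return(a$minp < b$minp)
    if (a$er != b$er) return(a$er > b$er)
    a$id < b$id
  }
  ord <- integer(0)
  left <- seq_along(stat)
  while (length(left)) {
    best <- left[1]
    for (i in left[-1]) if (before(stat[[i]], stat[[best]])) best <- i
    ord <- c(ord, best)
    left <- setdiff(left, best)
  }
  vapply(stat[ord], function(s) s$id, "")
}

# Connected components through igraph on the pixel-adjacency graph.
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  idx <- which(mask != 0)
  if (length(idx) == 0) return(0L)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  offs <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  pos <- paste(r, c)
  edges <- character(0)
  for (j in seq_len(nrow(offs))) {
    nbr <- paste(r + offs$dr[j], c + offs$dc[j])
    hit <- nbr %in% pos
    edges <- c(edges, rbind(pos[hit], nbr[hit]))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)]),
    directed = FALSE, vertices = data.frame(name = pos)
  )
  igraph::count_components(g)
}
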