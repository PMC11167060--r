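# Over-representation, term ranking, directionality states and the
# substrate-set activity z-score.

test_that("hypergeometric p matches closed cases and the quoted ratio definition", {
  universe <- paste0("g", 1:20)
  db <- list(T1 = paste0("g", 1:5))
  # all 5 significant genes inside a 5-member term: p = 1 / C(20,5)
  r <- overrepresentation(paste0("g", 1:5), universe, db, log10_cut = 2)
  expect_equal(r$p_value, 1 / choose(20, 5))
  expect_true(r$significant)
  expect_equal(r$enrichment_ratio, 1)
  # zero overlap: P[X >= 0] = 1
  r0 <- overrepresentation(paste0("g", 6:10), universe,
                           list(T1 = paste0("g", 1:5)), log10_cut = 2)
  expect_equal(r0$k, 0L)
  expect_equal(r0$p_value, 1)
  # ratio is overlap / significant count
  r4 <- overrepresentation(paste0("g", 1:10), universe,
                           list(T1 = paste0("g", c(1:4, 15))), 2)
  expect_equal(r4$k, 4L)
  expect_equal(r4$enrichment_ratio, 0.4)
})

test_that("hypergeometric p matches exhaustive enumeration for N <= 25", {
  set.seed(2024)
  grid <- expand.grid(N = c(6, 10, 15, 20, 25), n_sig = c(2, 3, 5))
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]
    n_sig <- grid$n_sig[i]
    if (choose(N, n_sig) > 60000) next
    K <- sample(1:(N - 1), 1)
    universe <- paste0("g", 1:N)
    sig <- paste0("g", sample(N, n_sig))
    db <- list(T = paste0("g", 1:K))
    got <- overrepresentation(sig, universe, db, log10_cut = 2)
    want <- oracle_hyper(got$k, K, N, n_sig)
    expect_equal(got$p_value, want, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are flagged, not guessed", {
  universe <- paste0("g", 1:10)
  r <- overrepresentation(character(0), universe, list(T = universe[1:3]), 2)
  expect_equal(r$p_value, 1)
  expect_equal(r$enrichment_ratio, 0)
  expect_true(r$undefined_ratio)
  expect_error(overrepresentation("zzz", universe, list(T = universe[1:3]), 2),
               "subset")
})

test_that("enrichment ratios over a disjoint cover of significant genes sum to 1", {
  universe <- paste0("g", 1:30)
  sig <- paste0("g", c(2, 5, 9, 12, 20, 28))
  db <- list(A = paste0("g", 1:10), B = paste0("g", 11:20),
             C = paste0("g", 21:30))
  r <- overrepresentation(sig, universe, db, 2)
  expect_equal(sum(r$enrichment_ratio), 1)
})

test_that("term ranking follows replication, then p, then enrichment", {
  mk <- function(term, ds, p, er, sig) {
    data.frame(dataset_id = ds, term_id = term, k = 1L, K = 5L, n_sig = 10L,
               N = 100L, p_value = p, enrichment_ratio = er,
               significant = sig, undefined_ratio = FALSE,
               stringsAsFactors = FALSE)
  }
  res <- rbind(
    mk("A", c("d1", "d2", "d3"), 1e-3, 0.1, TRUE),
    mk("B", c("d1", "d2"), 1e-8, 0.5, TRUE),
    mk("C", c("d1", "d2"), 1e-5, 0.5, TRUE)
  )
  r <- rank_terms(res)
  expect_equal(r$term_id, c("A", "B", "C"))
})

test_that("ranking agrees with a pairwise-comparison oracle on random inputs", {
  set.seed(11)
  for (rep in 1:50) {
    n_terms <- sample(3:12, 1)
    n_ds <- sample(1:5, 1)
    res <- expand.grid(term_id = paste0("T", seq_len(n_terms)),
                       dataset_id = paste0("d", seq_len(n_ds)),
                       stringsAsFactors = FALSE)
    res$p_value <- signif(runif(nrow(res)), 2)
    res$enrichment_ratio <- signif(runif(nrow(res)), 1)
    res$significant <- res$p_value < 0.3
    got <- rank_terms(res)$term_id
    expect_equal(got, oracle_rank(res))
  }
})

test_that("directionality states follow the -log10 cutoff", {
  recs <- data.frame(
    feature_id = c("Oxalobacter", "Lactobacillus", "Bifidobacterium"),
    dataset_id = "fecal1",
    log2fc = c(1.2, -0.8, 0.5), p_value = c(0.04, 0.02, 0.06),
    stringsAsFactors = FALSE
  )
  dm <- directionality_matrix(recs, threshold_log10 = 1.3)
  states <- setNames(dm$state, dm$id)
  expect_equal(states[["Oxalobacter"]], "up")      # 0.04 < 10^-1.3
  expect_equal(states[["Lactobacillus"]], "down")
  expect_equal(states[["Bifidobacterium"]], "not-significant")
  # a taxon absent from a second dataset is not-observed there
  recs2 <- rbind(recs,
                 data.frame(feature_id = "Oxalobacter", dataset_id = "fecal2",
                            log2fc = 1, p_value = 0.01))
  dm2 <- directionality_matrix(recs2, 1.3)
  expect_equal(dm2$state[dm2$id == "Lactobacillus" &
                           dm2$dataset_id == "fecal2"], "not-observed")
})

test_that("ksea computes the substrate-set z-score", {
  # engineered background: global mean 1, sd exactly 1, substrate mean 2,
  # m = 4  =>  z = (2 - 1) * sqrt(4) / 1 = 2
  d <- sqrt(29) / 6
  bg <- rep(2 / 3, 12) + rep(c(d, -d), 6)
  sites <- setNames(c(rep(2, 4), bg), paste0("s", 1:16))
  expect_equal(mean(sites), 1)
  expect_equal(sd(sites), 1)
  r <- ksea(sites, list(K1 = paste0("s", 1:4)), min_m = 3)
  expect_equal(r$z, 2, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pnorm(-2))

  # substrate mean equal to the global mean gives z = 0
  sites0 <- setNames(c(1, -1, 2, -2, 0, 0), paste0("s", 1:6))
  r0 <- ksea(sites0, list(K = paste0("s", 5:6)), min_m = 2)
  expect_equal(r0$z, 0)

  # enzymes under min_m are skipped; zero-variance background errors
  expect_equal(nrow(ksea(sites, list(K = "s1"), min_m = 3)), 0L)
  expect_error(ksea(setNames(rep(1, 5), paste0("s", 1:5)),
                    list(K = c("s1", "s2", "s3"))), "variance")
})

test_that("negating every fold change negates every z", {
  set.seed(5)
  sites <- setNames(rnorm(200), paste0("s", 1:200))
  emap <- list(K1 = paste0("s", 1:10), K2 = paste0("s", 50:70),
               K3 = paste0("s", 100:104))
  a <- ksea(sites, emap)
  b <- ksea(-sites, emap)
  b <- b[match(a$enzyme_id, b$enzyme_id), ]
  expect_equal(a$z, -b$z)
})
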