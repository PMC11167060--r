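# Consensus product score: worked examples, brute-force equivalence,
# symmetry, monotonicity and planted-gene recovery.

test_that("worked product-score examples", {
  d3 <- make_descriptors(c("a", "b", "c"))
  s3 <- score_drgp(make_calls("G1", c("a", "b", "c"), 1L), d3)
  expect_equal(as.data.frame(s3)[, c("S", "n", "P", "plotted")],
               data.frame(S = 3L, n = 3L, P = 9L, plotted = TRUE))

  d6 <- make_descriptors(letters[1:6])
  s6 <- score_drgp(make_calls("G1", letters[1:6],
                              c(1L, 1L, 1L, 1L, -1L, -1L)), d6)
  expect_equal(as.data.frame(s6)[, c("S", "n", "P", "plotted")],
               data.frame(S = 2L, n = 6L, P = 12L, plotted = FALSE))

  s2 <- score_drgp(make_calls("G1", c("a", "b"), c(1L, -1L)), d6)
  expect_equal(as.data.frame(s2)[, c("S", "n", "P", "plotted")],
               data.frame(S = 0L, n = 2L, P = 0L, plotted = FALSE))
})

test_that("non-core observations are displayed but never scored", {
  descr <- make_descriptors(c("core1", "core2", "core3", "plasma1"),
                            core = c(TRUE, TRUE, TRUE, FALSE))
  calls <- make_calls("G1", c("core1", "core2", "core3", "plasma1"), 1L)
  s <- score_drgp(calls, descr)
  expect_equal(as.data.frame(s)$n, 3L)
  expect_equal(as.data.frame(s)$P, 9L)
  dirs <- attr(s, "directions")
  expect_equal(dirs["G1", "plasma1"], 1L)
  # a gene seen only outside the core is retained with n = 0
  s2 <- score_drgp(make_calls("G2", "plasma1", -1L), descr)
  expect_equal(as.data.frame(s2)[, c("S", "n", "P", "plotted")],
               data.frame(S = 0L, n = 0L, P = 0L, plotted = FALSE))
})

test_that("calls against unknown datasets are rejected", {
  expect_error(score_drgp(make_calls("G1", "nowhere", 1L),
                          make_descriptors("a")), "nowhere")
})

test_that("scorer agrees with brute-force enumeration on 1000 random instances", {
  set.seed(20260924)
  for (rep in 1:1000) {
    n_ds <- sample(1:6, 1)
    ids <- paste0("d", seq_len(n_ds))
    descr <- make_descriptors(ids, core = sample(c(TRUE, FALSE), n_ds,
                                                 replace = TRUE, prob = c(0.7, 0.3)))
    n_calls <- sample(1:30, 1)
    calls <- make_calls(
      gene = paste0("G", sample(1:20, n_calls, replace = TRUE)),
      dataset_id = sample(ids, n_calls, replace = TRUE),
      direction = sample(c(-1L, 0L, 1L), n_calls, replace = TRUE),
      significant = sample(c(TRUE, FALSE), n_calls, replace = TRUE,
                           prob = c(0.8, 0.2))
    )
    # one call per (dataset, gene)
    calls <- calls[!duplicated(calls[c("dataset_id", "hgnc_symbol")]), ]
    got <- as.data.frame(score_drgp(calls, descr))
    want <- oracle_score(calls, descr)
    expect_equal(got[, c("hgnc_symbol", "S", "n", "P", "plotted")], want)
  }
})

test_that("negating every direction flips S and P and swaps the lists", {
  set.seed(99)
  ids <- paste0("d", 1:6)
  descr <- make_descriptors(ids)
  calls <- make_calls(paste0("G", sample(1:15, 40, replace = TRUE)),
                      sample(ids, 40, replace = TRUE),
                      sample(c(-1L, 1L), 40, replace = TRUE))
  calls <- calls[!duplicated(calls[c("dataset_id", "hgnc_symbol")]), ]
  flipped <- calls
  flipped$direction <- -flipped$direction
  a <- score_drgp(calls, descr)
  b <- score_drgp(flipped, descr)
  expect_equal(as.data.frame(a)$S, -as.data.frame(b)$S)
  expect_equal(as.data.frame(a)$P, -as.data.frame(b)$P)
  ra <- filter_and_rank(a)
  rb <- filter_and_rank(b)
  expect_equal(ra$up$hgnc_symbol, rb$down$hgnc_symbol)
  expect_equal(ra$down$hgnc_symbol, rb$up$hgnc_symbol)
})

test_that("adding a concordant core observation never decreases |P|", {
  set.seed(7)
  ids <- paste0("d", 1:6)
  descr <- make_descriptors(ids)
  for (rep in 1:50) {
    k <- sample(1:5, 1)
    used <- sample(ids, k)
    dir <- sample(c(-1L, 1L), k, replace = TRUE)
    calls <- make_calls("G1", used, dir)
    p0 <- abs(as.data.frame(score_drgp(calls, descr))$P)
    s <- as.integer(sign(sum(dir)))
    extra <- make_calls("G1", setdiff(ids, used)[1],
                        if (s == 0L) 1L else s)
    p1 <- abs(as.data.frame(score_drgp(rbind(calls, extra), descr))$P)
    expect_gte(p1, p0)
  }
})

test_that("ranking splits by sign, orders by |P| then n then symbol", {
  descr <- make_descriptors(paste0("d", 1:9))
  calls <- rbind(
    make_calls("BIG", paste0("d", 1:4), 1L),          # P = 16
    make_calls("NID1", paste0("d", 1:3), 1L),         # P = 9
    make_calls("PODXL", paste0("d", 1:3), 1L),        # P = 9
    make_calls("DOWN", paste0("d", 1:3), -1L)         # P = -9
  )
  r <- filter_and_rank(score_drgp(calls, descr))
  expect_equal(r$up$hgnc_symbol, c("BIG", "NID1", "PODXL"))
  expect_equal(r$down$hgnc_symbol, "DOWN")
  empty <- filter_and_rank(score_drgp(
    make_calls("G", "d1", 1L), descr))
  expect_equal(nrow(empty$up) + nrow(empty$down), 0L)
})

test_that("achievable products: parity constraint, 12 only from 2 x 6", {
  p6 <- achievable_products(6)
  expect_false(any(c(10, 11) %in% p6))
  expect_true(12 %in% p6)
  # enumerate achieving pairs independently
  pairs <- expand.grid(S = -6:6, n = 0:6)
  pairs <- pairs[abs(pairs$S) <= pairs$n &
                   (pairs$S %% 2) == (pairs$n %% 2), ]
  expect_equal(sort(unique(pairs$S * pairs$n)), p6)
  ach12 <- pairs[pairs$S * pairs$n == 12, ]
  expect_true(all(abs(ach12$S) == 2 & ach12$n == 6))
  expect_equal(achievable_products(0), 0L)
  expect_equal(p6, sort(-p6)) # symmetric under negation
})

test_that("planted k-concordant genes recover P = k^2 and discordant genes are excluded", {
  cfg <- small_config(seed = 31L)
  om <- gen_multiomic_datasets(cfg)
  h <- harmonize_datasets(om$tables, om$ground_truth$ortholog_map)
  cs <- as.data.frame(score_drgp(h$calls, om$descriptors))
  gt <- om$ground_truth$planted_genes
  m <- merge(gt, cs, by = "hgnc_symbol")
  expect_equal(m$P, m$direction * m$k^2)
  expect_true(all(m$plotted[m$k %in% c(3, 4, 5)]))
  # a constructed 4-up/2-down gene is excluded by the |P| = 12 rule
  descr <- make_descriptors(paste0("d", 1:6))
  disc <- score_drgp(make_calls("G", paste0("d", 1:6),
                                c(1L, 1L, 1L, 1L, -1L, -1L)), descr)
  expect_false(as.data.frame(disc)$plotted)
})
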