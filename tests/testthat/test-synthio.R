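# Generators: determinism, construction guarantees, and ground-truth
# sufficiency.

test_that("a fixed seed fully determines every artefact", {
  cfg <- small_config(seed = 42L)
  a <- gen_multiomic_datasets(cfg)
  b <- gen_multiomic_datasets(cfg)
  expect_identical(a, b)
  expect_identical(gen_gene_set_db(cfg), gen_gene_set_db(cfg))
  expect_identical(gen_chemistry_panel(cfg), gen_chemistry_panel(cfg))
  m1 <- gen_kidney_mask(cfg)
  m2 <- gen_kidney_mask(cfg)
  expect_identical(m1, m2)
  expect_identical(gen_dot_field(cfg, m1$raster),
                   gen_dot_field(cfg, m2$raster))
  # and written tables are byte-identical
  f1 <- tempfile()
  f2 <- tempfile()
  write_dataset_table(a$tables[[1]], f1)
  write_dataset_table(b$tables[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted genes are significant with the planted sign in their core datasets", {
  cfg <- small_config(seed = 5L)
  om <- gen_multiomic_datasets(cfg)
  gt <- om$ground_truth$planted_genes
  omap <- om$ground_truth$ortholog_map
  for (i in seq_len(nrow(gt))) {
    ds_ids <- strsplit(gt$core_datasets[i], ",")[[1]]
    for (ds in ds_ids) {
      tab <- om$tables[[ds]]
      sp <- om$descriptors$species[om$descriptors$dataset_id == ds]
      sym <- if (sp == "human") gt$hgnc_symbol[i] else {
        omap$native_symbol[omap$hgnc_symbol == gt$hgnc_symbol[i] &
                             omap$species == sp][1]
      }
      rows <- tab[tab$symbol == sym, ]
      expect_gt(nrow(rows), 0)
      expect_true(all(rows$p_value < cfg$alpha))
      expect_true(all(sign(rows$log2fc) == gt$direction[i]))
    }
  }
})

test_that("over-planting is rejected", {
  expect_error(
    gen_multiomic_datasets(simulation_config(n_genes = 10L,
                                             n_planted_consensus = 11L)),
    "exceeds"
  )
})

test_that("chance never mimics a planted consensus under the null", {
  # Frozen from a 20-seed Monte-Carlo calibration at the default study
  # conditions: the largest direction-consistent significant core count a
  # gene reaches without planted effects is 3 (so product scores never
  # exceed the |P| = 9 filter floor by more than chance-level singles).
  for (s in 1:5) {
    cfg <- simulation_config(seed = s, n_planted_consensus = 0L)
    om <- gen_multiomic_datasets(cfg)
    h <- harmonize_datasets(om$tables, om$ground_truth$ortholog_map)
    core <- om$descriptors$dataset_id[om$descriptors$core_scoring]
    d <- h$calls[h$calls$dataset_id %in% core & h$calls$significant &
                   h$calls$direction != 0, ]
    up <- table(d$hgnc_symbol[d$direction == 1])
    dn <- table(d$hgnc_symbol[d$direction == -1])
    expect_lte(max(c(0, up, dn)), 3)
  }
})

test_that("ortholog map honours the unmapped and ambiguous fractions", {
  cfg <- simulation_config(seed = 2L, n_genes = 1000L,
                           n_planted_consensus = 0L,
                           fraction_unmapped = 0.1, fraction_ambiguous = 0)
  omap <- gen_ortholog_map(cfg)
  expect_length(attr(omap, "unmapped"), 100L)
  # with no ambiguity the per-species map is a bijection
  for (sp in unique(omap$species)) {
    sub <- omap[omap$species == sp, ]
    expect_false(anyDuplicated(sub$native_symbol) > 0)
    expect_false(anyDuplicated(sub$hgnc_symbol) > 0)
  }
  cfg2 <- small_config(seed = 3L, fraction_ambiguous = 0.05)
  omap2 <- gen_ortholog_map(cfg2)
  amb <- attr(omap2, "ambiguous")
  expect_gt(length(amb), 0)
  sub <- omap2[omap2$species == omap2$species[1], ]
  counts <- table(sub$native_symbol)
  expect_true(all(counts[panrenal:::native_symbol(amb)] == 2L))
  # round-trip through the TSV representation is the identity
  f <- tempfile(fileext = ".tsv")
  write_ortholog_map(omap2, f)
  back <- read_ortholog_map(f)
  expect_equal(back, as.data.frame(omap2)[names(back)],
               ignore_attr = TRUE)
})

test_that("gene-set generator respects sizes, planted overlap and GMT round-trip", {
  cfg <- small_config(seed = 9L)
  gs <- gen_gene_set_db(cfg)
  sizes <- lengths(gs$db)
  expect_true(all(sizes >= cfg$term_size_range[1] &
                    sizes <= cfg$term_size_range[2]))
  planted_genes <- panrenal:::planted_truth(cfg)$hgnc_symbol
  for (t in gs$ground_truth$planted_term_ids) {
    overlap <- length(intersect(gs$db[[t]], planted_genes))
    expect_gte(overlap, min(cfg$planted_term_overlap, length(planted_genes),
                            min(sizes)))
  }
  f <- tempfile(fileext = ".gmt")
  write_gmt(gs$db, f)
  back <- read_gmt(f)
  expect_identical(unname(lapply(back, identity)),
                   unname(lapply(gs$db, identity)))
  expect_identical(names(back), names(gs$db))
})

test_that("chemistry panels are positive, complete and shifted as planted", {
  cfg <- small_config(seed = 4L)
  g <- gen_chemistry_panel(cfg)
  expect_true(all(g$panel$value > 0))
  expect_equal(nrow(unique(g$panel[c("subject_id", "timepoint")])),
               cfg$chem_n_subjects * length(cfg$chem_timepoints))
  # planted x3 in-flight shift visible in the group means
  ca <- g$panel[g$panel$compartment == "urine" & g$panel$analyte == "calcium", ]
  m <- tapply(ca$value, ca$timepoint, mean)
  expect_gt(m[["FD30"]] / m[["Pre"]], 2)
  expect_lt(m[["R+30"]] / m[["Pre"]], 1.5)
  gg <- gen_chemistry_panel(cfg, design = "groups")
  expect_true(all(c("exposed", "control") %in% gg$panel$group))
  expect_true(all(gg$panel$value > 0))
})

test_that("kidney mask partitions tissue and places disjoint tubules", {
  cfg <- small_config(seed = 6L)
  mk <- gen_kidney_mask(cfg)
  gt <- mk$ground_truth
  expect_equal(gt$n_tubules, cfg$mask_geometry$n_tubules)
  # object labels are 1..n with the recorded pixel counts, pairwise
  # disjoint by construction of a single-label raster
  counts <- tabulate(mk$raster$objects[mk$raster$objects > 0])
  expect_equal(counts, gt$tubule_areas_px)
  # region codes partition the tissue
  expect_equal(sum(gt$region_areas_px),
               sum(mk$raster$regions > 0))
  # every tubule pixel lies in the cortex
  expect_true(all(mk$raster$regions[mk$raster$objects > 0] ==
                    mk$raster$region_legend[["cortex"]]))
})

test_that("mask generation fails cleanly when tubules cannot be placed", {
  cfg <- small_config(seed = 1L)
  cfg$mask_geometry$n_tubules <- 5000L
  expect_error(gen_kidney_mask(cfg), "10\\^4 attempts")
})

test_that("dot fields follow the per-region intensities", {
  cfg <- small_config(seed = 8L,
                      dot_intensities = c(cortex = 0, OSOM = 600,
                                          ISOM = 2000, IM = 400))
  mk <- gen_kidney_mask(cfg)
  df <- gen_dot_field(cfg, mk$raster)
  expect_equal(sum(df$dots$region == "cortex"), 0L)
  # every dot falls inside its own region
  px <- mk$raster$pixel_size_um
  rr <- floor(df$dots$y_um / px) + 1L
  cc <- floor(df$dots$x_um / px) + 1L
  codes <- mk$raster$regions[cbind(rr, cc)]
  expect_equal(unname(mk$raster$region_legend[df$dots$region]),
               codes)
  # realised counts recorded in the ground truth
  expect_equal(unname(table(factor(df$dots$region,
                                   levels = df$ground_truth$region))),
               array(df$ground_truth$count))
})
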