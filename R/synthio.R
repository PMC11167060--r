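# Seeded generators emulating the result-level structure of the study
# inputs: per-dataset differential-feature tables across modalities/species,
# ortholog maps, gene-set databases, pre/in/post-flight chemistry panels,
# kidney label masks and ISH-style dot fields. Every generator draws from its
# own RNG stream derived from (seed, artefact name) and exports ground truth
# for parameter-recovery tests.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' emulate a multi-mission integration study: 12 datasets (6 kidney-specific
#' core transcriptome/proteome, plus phosphoproteome, methylome, plasma
#' metabolome/transcriptome/exosome and faecal metagenome), a 2,000-gene
#' universe, planted consensus genes concordantly significant in 3-5 core
#' datasets, gene-set databases with planted enriched terms, a 20-subject
#' astronaut-style chemistry panel with an in-flight urinary calcium shift,
#' and a cortex/OSOM/ISOM/IM annular kidney mask at 1 um/pixel with
#' non-overlapping elliptical tubules.
#'
#' @param seed integer; fully determines every generated artefact.
#' @param n_datasets number of differential datasets (the first
#'   `n_core` entries of `modalities` that are transcriptome/proteome are
#'   kidney-specific core datasets).
#' @param modalities character vector of length `n_datasets`; defaults to a
#'   mixed plan of the eight supported modalities.
#' @param species_mix named fractions (must sum to 1) used to allocate
#'   species across kidney datasets; plasma-derived datasets are human.
#' @param n_genes size of the HGNC gene universe.
#' @param measured_fraction fraction of the universe measured per dataset.
#' @param n_planted_consensus number of planted consensus genes.
#' @param planted_k core-dataset counts for planted genes (recycled).
#' @param planted_direction signs for planted genes (recycled).
#' @param effect_size_mean,effect_size_sd absolute log2 fold-change
#'   distribution for significant planted features.
#' @param alpha significance threshold the generators guarantee planted
#'   features to beat (and null appearances of planted genes to miss).
#' @param sig_p_shape1,sig_p_shape2 Beta parameters of the alternative
#'   p-value distribution (default Beta(0.5, 20), truncated below `alpha`).
#' @param fraction_unmapped,fraction_ambiguous fractions of non-planted
#'   native symbols left out of, or mapped one-to-many in, the ortholog map.
#' @param n_terms,term_size_range,n_planted_terms,planted_term_overlap
#'   gene-set database shape: number of terms, member-count range, number of
#'   planted enriched terms and minimum planted-gene overlap per planted term.
#' @param n_taxa,taxon_sig_fraction metagenome dataset shape.
#' @param chem_n_subjects,chem_timepoints chemistry panel shape (timepoints
#'   design); the first timepoint is baseline.
#' @param chemistry_effect_table named list `"compartment.analyte"` ->
#'   named vector timepoint -> multiplicative shift (timepoints design).
#' @param chemistry_group_effects named vector `"compartment.analyte"` ->
#'   multiplicative shift applied to the exposed group (groups design).
#' @param chem_sdlog,chem_subject_sdlog log-normal noise and between-subject
#'   scatter (log scale).
#' @param mask_geometry list: `pixel_size_um`, annulus radii (um)
#'   `outer_radius_um` > `cortex_inner_um` > `osom_inner_um` >
#'   `isom_inner_um`, `n_tubules`, `tubule_area_range_um2`,
#'   `interstitial_fraction`.
#' @param dot_intensities named dots/mm^2 per anatomical region.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_datasets = 12L,
                              modalities = NULL,
                              species_mix = c(mouse = 0.6, human = 0.25, rat = 0.15),
                              n_genes = 2000L,
                              measured_fraction = 0.7,
                              n_planted_consensus = 12L,
                              planted_k = c(3L, 4L, 5L),
                              planted_direction = c(1L, -1L),
                              effect_size_mean = 1.5,
                              effect_size_sd = 0.4,
                              alpha = 0.05,
                              sig_p_shape1 = 0.5,
                              sig_p_shape2 = 20,
                              fraction_unmapped = 0.05,
                              fraction_ambiguous = 0.03,
                              n_terms = 50L,
                              term_size_range = c(10L, 80L),
                              n_planted_terms = 3L,
                              planted_term_overlap = 8L,
                              n_taxa = 40L,
                              taxon_sig_fraction = 0.2,
                              chem_n_subjects = 20L,
                              chem_timepoints = c("Pre", "FD30", "FD60", "R+0", "R+30"),
                              chemistry_effect_table = list(
                                "urine.calcium" = c(FD30 = 3, FD60 = 3)
                              ),
                              chemistry_group_effects = c("urine.protein" = 1.6),
                              chem_sdlog = 0.2,
                              chem_subject_sdlog = 0.1,
                              mask_geometry = list(
                                pixel_size_um = 1,
                                outer_radius_um = 260,
                                cortex_inner_um = 170,
                                osom_inner_um = 120,
                                isom_inner_um = 70,
                                n_tubules = 12L,
                                tubule_area_range_um2 = c(200, 900),
                                interstitial_fraction = 0.06
                              ),
                              dot_intensities = c(cortex = 800, OSOM = 600,
                                                  ISOM = 2000, IM = 400)) {
  if (is.null(modalities)) {
    modalities <- c("transcriptome", "transcriptome", "transcriptome",
                    "proteome", "proteome", "proteome",
                    "epiproteome", "epigenome", "metabolome",
                    "plasma", "exosome", "metagenome")
    modalities <- rep_len(modalities, n_datasets)
  }
  cfg <- list(seed = as.integer(seed), n_datasets = as.integer(n_datasets),
              modalities = modalities, species_mix = species_mix,
              n_genes = as.integer(n_genes),
              measured_fraction = measured_fraction,
              n_planted_consensus = as.integer(n_planted_consensus),
              planted_k = as.integer(planted_k),
              planted_direction = as.integer(planted_direction),
              effect_size_mean = effect_size_mean,
              effect_size_sd = effect_size_sd, alpha = alpha,
              sig_p_shape1 = sig_p_shape1, sig_p_shape2 = sig_p_shape2,
              fraction_unmapped = fraction_unmapped,
              fraction_ambiguous = fraction_ambiguous,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              n_planted_terms = as.integer(n_planted_terms),
              planted_term_overlap = as.integer(planted_term_overlap),
              n_taxa = as.integer(n_taxa),
              taxon_sig_fraction = taxon_sig_fraction,
              chem_n_subjects = as.integer(chem_n_subjects),
              chem_timepoints = chem_timepoints,
              chemistry_effect_table = chemistry_effect_table,
              chemistry_group_effects = chemistry_group_effects,
              chem_sdlog = chem_sdlog,
              chem_subject_sdlog = chem_subject_sdlog,
              mask_geometry = mask_geometry,
              dot_intensities = dot_intensities)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  counts <- c(cfg$n_datasets, cfg$n_genes, cfg$n_planted_consensus,
              cfg$n_terms, cfg$n_planted_terms, cfg$n_taxa,
              cfg$chem_n_subjects, cfg$mask_geometry$n_tubules)
  if (any(counts < 0)) stop_panrenal("all counts must be >= 0")
  if (abs(sum(cfg$species_mix) - 1) > 1e-8) {
    stop_panrenal("species_mix fractions must sum to 1")
  }
  if (cfg$term_size_range[1] > cfg$term_size_range[2]) {
    stop_panrenal("term_size_range must be (min, max) with min <= max")
  }
  if (cfg$n_planted_consensus > cfg$n_genes) {
    stop_panrenal("n_planted_consensus exceeds n_genes")
  }
  if (length(cfg$modalities) != cfg$n_datasets) {
    stop_panrenal("modalities must have one entry per dataset")
  }
  if (!all(cfg$modalities %in% MODALITIES)) {
    stop_panrenal("unknown modality label")
  }
  g <- cfg$mask_geometry
  if (!(g$outer_radius_um > g$cortex_inner_um &&
        g$cortex_inner_um > g$osom_inner_um &&
        g$osom_inner_um > g$isom_inner_um && g$isom_inner_um > 0)) {
    stop_panrenal("mask radii must be strictly decreasing and positive")
  }
  cfg
}

gene_universe <- function(cfg) sprintf("GENE%04d", seq_len(cfg$n_genes))

# Native (non-human) symbol for an HGNC symbol: rodent nomenclature style,
# first letter capitalised, rest lower-case.
native_symbol <- function(hgnc) {
  paste0(substr(hgnc, 1, 1), tolower(substring(hgnc, 2)))
}

# Planted consensus genes and their core-dataset assignments; shared (via
# its own stream) by the dataset and gene-set generators.
planted_truth <- function(cfg) {
  descr <- dataset_plan(cfg)
  core_ids <- descr$dataset_id[descr$core_scoring]
  with_stream(cfg$seed, "planted", {
    universe <- gene_universe(cfg)
    n <- cfg$n_planted_consensus
    if (n == 0L) {
      return(data.frame(hgnc_symbol = character(), direction = integer(),
                        k = integer(), core_datasets = character(),
                        stringsAsFactors = FALSE))
    }
    genes <- sample(universe, n)
    k <- rep_len(cfg$planted_k, n)
    if (any(k > length(core_ids))) {
      stop_panrenal("planted_k exceeds the number of core datasets")
    }
    direction <- rep_len(cfg$planted_direction, n)
    ds <- vapply(k, function(ki) paste(sample(core_ids, ki), collapse = ","),
                 "")
    data.frame(hgnc_symbol = genes, direction = direction, k = k,
               core_datasets = ds, stringsAsFactors = FALSE)
  })
}

# Deterministic dataset descriptor plan derived from the config.
dataset_plan <- function(cfg) {
  n <- cfg$n_datasets
  modality <- cfg$modalities
  tissue <- ifelse(modality %in% c("transcriptome", "proteome",
                                   "epiproteome", "epigenome"),
                   "kidney",
                   ifelse(modality == "metagenome", "faecal", "plasma"))
  # Allocate species over kidney datasets by the configured mix; plasma and
  # faecal datasets are human and mouse respectively (matching the study
  # design: astronaut fluids, rodent stools).
  species <- character(n)
  kidney_idx <- which(tissue == "kidney")
  if (length(kidney_idx)) {
    mix <- sort(cfg$species_mix, decreasing = TRUE)
    counts <- floor(mix * length(kidney_idx))
    while (sum(counts) < length(kidney_idx)) {
      counts[which.max(mix * length(kidney_idx) - counts)] <-
        counts[which.max(mix * length(kidney_idx) - counts)] + 1
    }
    species[kidney_idx] <- rep(names(counts), counts)[seq_along(kidney_idx)]
  }
  species[tissue == "plasma"] <- "human"
  species[tissue == "faecal"] <- "mouse"
  kidney_specific <- tissue == "kidney"
  core <- kidney_specific & modality %in% c("proteome", "transcriptome")
  data.frame(
    dataset_id = sprintf("ds%02d", seq_len(n)),
    mission = sprintf("MISSION-%02d", seq_len(n)),
    species = species, tissue = tissue, modality = modality,
    kidney_specific = kidney_specific, core_scoring = core,
    stringsAsFactors = FALSE
  )
}

# Truncated Beta draw guaranteed below `upper` (inverse-CDF method).
rbeta_below <- function(n, shape1, shape2, upper) {
  u <- runif(n, 0, stats::pbeta(upper, shape1, shape2))
  stats::qbeta(u, shape1, shape2)
}

#' Generate synthetic multi-omic differential datasets
#'
#' Emulates the result-level structure of a multi-mission integration study:
#' one tab-separatable differential-feature table per dataset, spanning the
#' configured modalities and species. Planted consensus genes are
#' significant (p below `cfg$alpha`) with their planted sign in their
#' assigned core (kidney proteome/transcriptome) datasets and deliberately
#' non-significant anywhere else, so downstream recovery can be stated
#' exactly against the ground truth. Phosphoproteome and methylome datasets
#' carry several features per gene; non-human datasets use native symbols
#' resolvable through [gen_ortholog_map()]; the metagenome dataset carries
#' taxa without gene symbols.
#'
#' @param cfg a [simulation_config()].
#' @return list with `tables` (named list of data.frames, one per dataset),
#'   `descriptors` (dataset descriptor data.frame) and `ground_truth`
#'   (planted genes with directions and core-dataset memberships, plus the
#'   per-dataset measured-gene lists).
#' @export
gen_multiomic_datasets <- function(cfg) {
  cfg <- validate_simulation_config(cfg)
  descr <- dataset_plan(cfg)
  planted <- planted_truth(cfg)
  omap <- gen_ortholog_map(cfg)
  universe <- gene_universe(cfg)
  planted_ds <- strsplit(planted$core_datasets, ",", fixed = TRUE)
  names(planted_ds) <- planted$hgnc_symbol

  with_stream(cfg$seed, "datasets", {
    tables <- vector("list", nrow(descr))
    names(tables) <- descr$dataset_id
    measured_by_ds <- list()
    for (i in seq_len(nrow(descr))) {
      d <- descr[i, ]
      if (d$modality == "metagenome") {
        tables[[i]] <- gen_taxon_table(cfg)
        next
      }
      n_meas <- round(cfg$measured_fraction * cfg$n_genes)
      measured <- sample(universe, n_meas)
      # planted genes must be measured in the datasets they are planted into
      must <- planted$hgnc_symbol[vapply(planted_ds, function(s)
        d$dataset_id %in% s, NA)]
      measured <- union(measured, must)
      measured_by_ds[[d$dataset_id]] <- measured

      fclass <- switch(d$modality,
                       transcriptome = "transcript",
                       proteome = "protein",
                       epiproteome = "phosphosite",
                       epigenome = "cpg",
                       metabolome = "metabolite-gene-link",
                       plasma = "transcript",
                       exosome = "protein")
      nfeat <- switch(fclass,
                      phosphosite = sample(1:4, length(measured), replace = TRUE),
                      cpg = sample(1:3, length(measured), replace = TRUE),
                      rep(1L, length(measured)))
      gene <- rep(measured, nfeat)
      site <- unlist(lapply(nfeat, seq_len))
      feature_id <- switch(fclass,
        phosphosite = sprintf("%s_S%d", gene, site * 7),
        cpg = sprintf("cg_%s_%d", gene, site),
        transcript = paste0("tx_", gene),
        protein = paste0("pr_", gene),
        `metabolite-gene-link` = paste0("met_", gene))

      m <- length(gene)
      log2fc <- rnorm(m, 0, 0.4)
      p <- runif(m)
      is_planted_here <- gene %in% must
      planted_elsewhere <- gene %in% planted$hgnc_symbol & !is_planted_here
      # planted features in their core datasets: truncated-Beta p and a
      # directional effect size
      if (any(is_planted_here)) {
        idx <- which(is_planted_here)
        dir <- planted$direction[match(gene[idx], planted$hgnc_symbol)]
        p[idx] <- rbeta_below(length(idx), cfg$sig_p_shape1,
                              cfg$sig_p_shape2, cfg$alpha)
        log2fc[idx] <- dir * abs(rnorm(length(idx), cfg$effect_size_mean,
                                       cfg$effect_size_sd))
      }
      # planted genes stay clean of stray significance elsewhere
      if (any(planted_elsewhere)) {
        idx <- which(planted_elsewhere)
        p[idx] <- runif(length(idx), cfg$alpha, 1)
      }
      symbol <- if (d$species == "human") gene else native_symbol(gene)
      tables[[i]] <- data.frame(
        feature_id = feature_id, feature_class = fclass, symbol = symbol,
        species = d$species, log2fc = log2fc, p_value = p,
        stringsAsFactors = FALSE
      )
    }
    list(tables = tables, descriptors = descr,
         ground_truth = list(planted_genes = planted,
                             measured = measured_by_ds,
                             ortholog_map = omap))
  })
}

gen_taxon_table <- function(cfg) {
  taxa <- sprintf("Taxon_%02d", seq_len(cfg$n_taxa))
  m <- length(taxa)
  p <- runif(m)
  log2fc <- rnorm(m, 0, 0.6)
  n_sig <- round(cfg$taxon_sig_fraction * m)
  if (n_sig > 0) {
    idx <- sample(m, n_sig)
    p[idx] <- rbeta_below(n_sig, cfg$sig_p_shape1, cfg$sig_p_shape2,
                          cfg$alpha)
    log2fc[idx] <- sample(c(-1, 1), n_sig, replace = TRUE) *
      abs(rnorm(n_sig, cfg$effect_size_mean, cfg$effect_size_sd))
  }
  data.frame(feature_id = taxa, feature_class = "taxon", symbol = "",
             species = "mouse", log2fc = log2fc, p_value = p,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic ortholog map
#'
#' Maps native rodent symbols to HGNC symbols. A configured fraction of
#' non-planted symbols is omitted (unmapped) and another fraction maps
#' one-to-many, to exercise the harmonisation policies. Planted consensus
#' genes are always mapped one-to-one so parameter-recovery statements stay
#' exact. Human symbols are their own HGNC symbols and need no entries.
#'
#' @param cfg a [simulation_config()].
#' @return data.frame with columns `species`, `native_symbol`,
#'   `hgnc_symbol`; attributes `unmapped` and `ambiguous` list the affected
#'   HGNC symbols.
#' @export
gen_ortholog_map <- function(cfg) {
  cfg <- validate_simulation_config(cfg)
  planted <- planted_truth(cfg)
  with_stream(cfg$seed, "orthologs", {
    universe <- gene_universe(cfg)
    pool <- setdiff(universe, planted$hgnc_symbol)
    n_unm <- round(cfg$fraction_unmapped * cfg$n_genes)
    n_amb <- round(cfg$fraction_ambiguous * cfg$n_genes)
    pick <- sample(pool, min(n_unm + n_amb, length(pool)))
    unmapped <- pick[seq_len(min(n_unm, length(pick)))]
    ambiguous <- setdiff(pick, unmapped)
    species <- setdiff(names(cfg$species_mix), "human")
    rows <- list()
    for (sp in species) {
      keep <- setdiff(universe, unmapped)
      rows[[sp]] <- data.frame(
        species = sp, native_symbol = native_symbol(keep), hgnc_symbol = keep,
        stringsAsFactors = FALSE
      )
      if (length(ambiguous)) {
        extra <- sample(setdiff(universe, ambiguous), length(ambiguous))
        rows[[paste0(sp, "_amb")]] <- data.frame(
          species = sp, native_symbol = native_symbol(ambiguous),
          hgnc_symbol = extra, stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "unmapped") <- unmapped
    attr(out, "ambiguous") <- ambiguous
    out
  })
}

#' Generate a synthetic gene-set database
#'
#' Random terms over the gene universe with sizes uniform in
#' `term_size_range`. Planted terms receive at least
#' `planted_term_overlap` planted consensus genes each, creating a real
#' over-representation signal among significant genes; remaining terms are
#' uniform draws.
#'
#' @param cfg a [simulation_config()].
#' @return list with `db` (named list of member-symbol vectors, GMT
#'   serialisable via [write_gmt()]) and `ground_truth` (planted term ids).
#' @export
gen_gene_set_db <- function(cfg) {
  cfg <- validate_simulation_config(cfg)
  planted <- planted_truth(cfg)
  with_stream(cfg$seed, "genesets", {
    universe <- gene_universe(cfg)
    sizes <- sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]),
                    cfg$n_terms, replace = TRUE)
    ids <- sprintf("TERM%04d", seq_len(cfg$n_terms))
    planted_ids <- if (cfg$n_planted_terms > 0) {
      ids[seq_len(min(cfg$n_planted_terms, cfg$n_terms))]
    } else {
      character()
    }
    db <- vector("list", cfg$n_terms)
    names(db) <- ids
    for (i in seq_len(cfg$n_terms)) {
      if (ids[i] %in% planted_ids && nrow(planted) > 0) {
        n_overlap <- min(cfg$planted_term_overlap, nrow(planted), sizes[i])
        core <- sample(planted$hgnc_symbol, n_overlap)
        fill <- sample(setdiff(universe, core),
                       max(sizes[i] - n_overlap, 0))
        db[[i]] <- sort(c(core, fill))
      } else {
        db[[i]] <- sort(sample(universe, sizes[i]))
      }
    }
    attr(db, "description") <- ifelse(ids %in% planted_ids,
                                      "planted synthetic term",
                                      "background synthetic term")
    list(db = db, ground_truth = list(planted_term_ids = planted_ids))
  })
}

#' Generate a synthetic clinical chemistry panel
#'
#' Log-normal measurements around physiological baselines for urine and
#' plasma analytes. In the `"timepoints"` design (astronaut-style), every
#' subject is measured at pre-, in- and post-flight timepoints and
#' `chemistry_effect_table` applies multiplicative in-flight shifts that
#' return to baseline afterwards; between-subject scatter is shared across a
#' subject's timepoints, giving the repeated-measures correlation. In the
#' `"groups"` design (rodent-style), exposed and control groups of both
#' sexes are measured once and `chemistry_group_effects` shifts the exposed
#' group.
#'
#' @param cfg a [simulation_config()].
#' @param design `"timepoints"` or `"groups"`.
#' @return list with `panel` (long data.frame, see
#'   [read_chemistry_panel()]) and `ground_truth` (baselines and planted
#'   shifts).
#' @export
gen_chemistry_panel <- function(cfg, design = c("timepoints", "groups")) {
  cfg <- validate_simulation_config(cfg)
  design <- match.arg(design)
  base <- chem_baselines()
  stream <- paste0("chemistry_", design)
  with_stream(cfg$seed, stream, {
    if (design == "timepoints") {
      subjects <- sprintf("AST%02d", seq_len(cfg$chem_n_subjects))
      tps <- cfg$chem_timepoints
      grid <- expand.grid(subject_id = subjects, timepoint = tps,
                          key = base$key, stringsAsFactors = FALSE)
      grid <- merge(grid, base, by = "key", sort = FALSE)
      subj_eff <- rnorm(length(subjects) * nrow(base), 0,
                        cfg$chem_subject_sdlog)
      names(subj_eff) <- paste(rep(subjects, each = nrow(base)),
                               rep(base$key, length(subjects)))
      shift <- rep(1, nrow(grid))
      for (key in names(cfg$chemistry_effect_table)) {
        eff <- cfg$chemistry_effect_table[[key]]
        for (tp in names(eff)) {
          hit <- grid$key == key & grid$timepoint == tp
          shift[hit] <- eff[[tp]]
        }
      }
      value <- grid$baseline * shift *
        exp(subj_eff[paste(grid$subject_id, grid$key)]) *
        exp(rnorm(nrow(grid), 0, cfg$chem_sdlog))
      panel <- data.frame(
        subject_id = grid$subject_id, group = "exposed", sex = "F",
        timepoint = grid$timepoint, compartment = grid$compartment,
        analyte = grid$analyte, value = value, unit = grid$unit,
        stringsAsFactors = FALSE
      )
      truth <- list(baselines = base, shifts = cfg$chemistry_effect_table)
    } else {
      n_per <- cfg$chem_n_subjects
      plan <- expand.grid(sex = c("F", "M"), group = c("exposed", "control"),
                          idx = seq_len(n_per), stringsAsFactors = FALSE)
      plan$subject_id <- sprintf("MUS%03d", seq_len(nrow(plan)))
      grid <- merge(plan, base, by = NULL)
      shift <- rep(1, nrow(grid))
      for (key in names(cfg$chemistry_group_effects)) {
        hit <- grid$key == key & grid$group == "exposed"
        shift[hit] <- cfg$chemistry_group_effects[[key]]
      }
      value <- grid$baseline * shift *
        exp(rnorm(nrow(grid), 0, cfg$chem_sdlog))
      panel <- data.frame(
        subject_id = grid$subject_id, group = grid$group, sex = grid$sex,
        timepoint = "terminal", compartment = grid$compartment,
        analyte = grid$analyte, value = value, unit = grid$unit,
        stringsAsFactors = FALSE
      )
      truth <- list(baselines = base, shifts = cfg$chemistry_group_effects)
    }
    validate_panel(panel)
    list(panel = panel, ground_truth = truth)
  })
}

# Physiological baselines. Creatinine is kept in mmol/l in both
# compartments so fractional excretions are unit-consistent out of the box.
chem_baselines <- function() {
  u <- data.frame(
    compartment = "urine",
    analyte = c("creatinine", "calcium", "phosphate", "sodium", "potassium",
                "chloride", "magnesium", "osmolality", "volume", "protein",
                "glucose"),
    baseline = c(10, 2.5, 15, 120, 50, 110, 4, 600, 1.6, 0.08, 0.3),
    unit = c("mmol/l", "mmol/l", "mmol/l", "mmol/l", "mmol/l", "mmol/l",
             "mmol/l", "mosm/kg", "l/day", "g/l", "mmol/l"),
    stringsAsFactors = FALSE
  )
  p <- data.frame(
    compartment = "plasma",
    analyte = c("creatinine", "calcium", "phosphate", "sodium", "potassium",
                "chloride", "magnesium", "osmolality", "albumin",
                "aldosterone", "renin", "glucose"),
    baseline = c(0.08, 2.4, 1.1, 140, 4.2, 104, 0.85, 290, 42, 300, 20, 5),
    unit = c("mmol/l", "mmol/l", "mmol/l", "mmol/l", "mmol/l", "mmol/l",
             "mmol/l", "mosm/kg", "g/l", "pmol/l", "mu/l", "mmol/l"),
    stringsAsFactors = FALSE
  )
  out <- rbind(u, p)
  out$key <- paste(out$compartment, out$analyte, sep = ".")
  out
}

#' Generate a synthetic kidney label mask
#'
#' Concentric annuli for cortex, outer/inner stripes of the outer medulla
#' (OSOM/ISOM) and inner medulla (IM) around the raster centre, with
#' non-overlapping elliptical "tubule" objects placed inside the cortex by
#' rejection sampling (axis ratio uniform on (1,3), area uniform over the
#' configured range, at least one background pixel between objects so
#' 8-connected components never merge). Optionally a random interstitial
#' pixel channel covering a fixed fraction of the tissue.
#'
#' @param cfg a [simulation_config()].
#' @return list with `raster` (a [label_raster]) and `ground_truth` (exact
#'   per-tubule pixel areas, per-region pixel areas, interstitial pixel
#'   count).
#' @export
gen_kidney_mask <- function(cfg) {
  cfg <- validate_simulation_config(cfg)
  g <- cfg$mask_geometry
  px <- g$pixel_size_um
  half <- ceiling(g$outer_radius_um / px) + 2L
  n <- 2L * half + 1L
  cx <- half + 1L
  coords_r <- matrix(rep(seq_len(n), n), nrow = n)
  coords_c <- t(coords_r)
  r_um <- sqrt((coords_r - cx)^2 + (coords_c - cx)^2) * px
  regions <- matrix(0L, n, n)
  regions[r_um <= g$outer_radius_um] <- 1L  # cortex
  regions[r_um <= g$cortex_inner_um] <- 2L  # OSOM
  regions[r_um <= g$osom_inner_um] <- 3L    # ISOM
  regions[r_um <= g$isom_inner_um] <- 4L    # IM
  legend <- c(background = 0L, cortex = 1L, OSOM = 2L, ISOM = 3L, IM = 4L)

  objects <- matrix(0L, n, n)
  areas_px <- integer(0)
  with_stream(cfg$seed, "mask", {
    attempts <- 0L
    placed <- 0L
    while (placed < g$n_tubules) {
      attempts <- attempts + 1L
      if (attempts > 1e4L) {
        stop_panrenal("could not place ", g$n_tubules,
                      " non-overlapping tubules in 10^4 attempts")
      }
      area <- runif(1, g$tubule_area_range_um2[1], g$tubule_area_range_um2[2])
      ratio <- runif(1, 1, 3)
      a <- sqrt(area * ratio / pi) / px
      b <- sqrt(area / (ratio * pi)) / px
      theta <- runif(1, 0, pi)
      rad <- runif(1, g$cortex_inner_um, g$outer_radius_um)
      phi <- runif(1, 0, 2 * pi)
      ec <- cx + (rad / px) * cos(phi)
      er <- cx + (rad / px) * sin(phi)
      bb <- ceiling(max(a, b)) + 1L
      rows <- max(1L, floor(er - bb)):min(n, ceiling(er + bb))
      cols <- max(1L, floor(ec - bb)):min(n, ceiling(ec + bb))
      dr <- rep(rows, times = length(cols)) - er
      dc <- rep(cols, each = length(rows)) - ec
      u <- (dc * cos(theta) + dr * sin(theta)) / a
      v <- (-dc * sin(theta) + dr * cos(theta)) / b
      inside <- u^2 + v^2 <= 1
      if (!any(inside)) next
      pr <- rep(rows, times = length(cols))[inside]
      pc <- rep(cols, each = length(rows))[inside]
      # whole ellipse must sit in cortex, clear of other tubules by >= 1 px
      if (any(regions[cbind(pr, pc)] != 1L)) next
      nbr <- expand.grid(dr = -1:1, dc = -1:1)
      clear <- TRUE
      for (j in seq_len(nrow(nbr))) {
        rr <- pmin(pmax(pr + nbr$dr[j], 1L), n)
        cc <- pmin(pmax(pc + nbr$dc[j], 1L), n)
        if (any(objects[cbind(rr, cc)] != 0L)) {
          clear <- FALSE
          break
        }
      }
      if (!clear) next
      placed <- placed + 1L
      objects[cbind(pr, pc)] <- placed
      areas_px[placed] <- length(pr)
    }
    interstitium <- NULL
    inter_px <- 0L
    if (!is.null(g$interstitial_fraction) && g$interstitial_fraction > 0) {
      tissue_idx <- which(regions > 0L)
      inter_px <- round(g$interstitial_fraction * length(tissue_idx))
      interstitium <- matrix(0L, n, n)
      interstitium[sample(tissue_idx, inter_px)] <- 1L
    }
    raster <- label_raster(regions = regions, objects = objects,
                           pixel_size_um = px, region_legend = legend,
                           interstitium = interstitium)
    region_areas_px <- vapply(legend[-1], function(code)
      sum(regions == code), 0L)
    list(raster = raster,
         ground_truth = list(n_tubules = g$n_tubules,
                             tubule_areas_px = areas_px,
                             tubule_areas_um2 = areas_px * px^2,
                             region_areas_px = region_areas_px,
                             interstitial_px = inter_px))
  })
}

#' Generate a synthetic ISH-style dot field over a label mask
#'
#' Homogeneous Poisson point process per anatomical region with the
#' configured intensities (dots per square millimetre): the dot count in a
#' region is Poisson with mean intensity times physical region area, and
#' positions are uniform over the region's pixels (with sub-pixel jitter).
#'
#' @param cfg a [simulation_config()].
#' @param raster a [label_raster] supplying regions and pixel size.
#' @return list with `dots` (data.frame `x_um`, `y_um`, `region`) and
#'   `ground_truth` (per-region intensity, realised count, area in mm^2).
#' @export
gen_dot_field <- function(cfg, raster) {
  cfg <- validate_simulation_config(cfg)
  stopifnot(inherits(raster, "label_raster"))
  px <- raster$pixel_size_um
  legend <- raster$region_legend
  legend <- legend[names(legend) != "background"]
  with_stream(cfg$seed, "dots", {
    out <- list()
    truth <- data.frame(region = names(legend), intensity_per_mm2 = NA_real_,
                        area_mm2 = NA_real_, count = NA_integer_,
                        stringsAsFactors = FALSE)
    for (i in seq_along(legend)) {
      nm <- names(legend)[i]
      idx <- which(raster$regions == legend[[i]])
      area_mm2 <- length(idx) * px^2 / 1e6
      lambda <- cfg$dot_intensities[[nm]] %||% 0
      count <- if (lambda > 0) rpois(1, lambda * area_mm2) else 0L
      truth$intensity_per_mm2[i] <- lambda
      truth$area_mm2[i] <- area_mm2
      truth$count[i] <- count
      if (count > 0) {
        pick <- sample(idx, count, replace = TRUE)
        rr <- ((pick - 1L) %% nrow(raster$regions)) + 1L
        cc <- ((pick - 1L) %/% nrow(raster$regions)) + 1L
        out[[nm]] <- data.frame(
          x_um = (cc - 1 + runif(count)) * px,
          y_um = (rr - 1 + runif(count)) * px,
          region = nm, stringsAsFactors = FALSE
        )
      }
    }
    dots <- if (length(out)) do.call(rbind, out) else
      data.frame(x_um = numeric(), y_um = numeric(), region = character())
    rownames(dots) <- NULL
    list(dots = dots, ground_truth = truth)
  })
}

#' Run every generator and optionally write the artefacts to disk
#'
#' Convenience wrapper producing the full synthetic study: differential
#' tables with descriptors and ortholog map, gene-set database, astronaut-
#' and rodent-style chemistry panels, kidney mask and dot field, with all
#' ground truths.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir if non-NULL, artefacts are written there (tab-separated
#'   tables, GMT, TIFF + JSON sidecar).
#' @return invisible list of all generated artefacts.
#' @export
simulate_study <- function(cfg, out_dir = NULL) {
  cfg <- validate_simulation_config(cfg)
  omics <- gen_multiomic_datasets(cfg)
  gsets <- gen_gene_set_db(cfg)
  chem_tp <- gen_chemistry_panel(cfg, "timepoints")
  chem_gr <- gen_chemistry_panel(cfg, "groups")
  mask <- gen_kidney_mask(cfg)
  dots <- gen_dot_field(cfg, mask$raster)
  res <- list(config = cfg, omics = omics, gene_sets = gsets,
              chemistry_timepoints = chem_tp, chemistry_groups = chem_gr,
              mask = mask, dots = dots)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "datasets"), recursive = TRUE,
               showWarnings = FALSE)
    for (id in names(omics$tables)) {
      write_dataset_table(omics$tables[[id]],
                          file.path(out_dir, "datasets", paste0(id, ".tsv")))
    }
    write_descriptors(omics$descriptors,
                      file.path(out_dir, "descriptors.tsv"))
    write_ortholog_map(omics$ground_truth$ortholog_map,
                       file.path(out_dir, "orthologs.tsv"))
    write_gmt(gsets$db, file.path(out_dir, "gene_sets.gmt"))
    write_chemistry_panel(chem_tp$panel,
                          file.path(out_dir, "chemistry_timepoints.tsv"))
    write_chemistry_panel(chem_gr$panel,
                          file.path(out_dir, "chemistry_groups.tsv"))
    write_label_raster(mask$raster, file.path(out_dir, "kidney_mask"))
    utils::write.table(dots$dots, file.path(out_dir, "dots.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}
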