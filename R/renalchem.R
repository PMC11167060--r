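# Derived renal physiology indices from urine/plasma chemistry panels, and
# the comparison/normalisation conventions used with them: repeated-measures
# contrasts against a pre-exposure baseline, two-factor group comparisons,
# and fold-of-control normalisation.

#' Fractional excretion of an analyte
#'
#' `FE_x = 100 * (U_x * P_cr) / (P_x * U_cr)` — the percentage of the
#' filtered load of analyte x excreted in urine, computed from spot urine
#' and plasma concentrations of the analyte and creatinine. Units must be
#' consistent within each analyte pair (the index is invariant to
#' rescaling a pair by a common factor). In the absence of plasma calcium
#' abnormalities FE of calcium is below 1%.
#'
#' @param Ux,Px urine and plasma analyte concentrations.
#' @param Ucr,Pcr urine and plasma creatinine concentrations.
#' @param analyte name used in error messages.
#' @return fractional excretion in percent.
#' @export
fractional_excretion <- function(Ux, Px, Ucr, Pcr, analyte = "analyte") {
  if (any(Px == 0, na.rm = TRUE) || any(Ucr == 0, na.rm = TRUE)) {
    stop_panrenal("zero denominator computing fractional excretion of ",
                  analyte, " (plasma ", analyte, " or urine creatinine)")
  }
  100 * (Ux * Pcr) / (Px * Ucr)
}

#' Albumin-corrected fractional excretion of magnesium
#'
#' Only the ultrafilterable fraction of plasma magnesium (the part not
#' bound to albumin) is filtered, so the plasma concentration entering the
#' fractional excretion is `uf_fraction * P_Mg`; the conventional
#' ultrafilterable fraction is 0.7.
#'
#' @param U_Mg,P_Mg urine and plasma total magnesium.
#' @param Ucr,Pcr urine and plasma creatinine.
#' @param uf_fraction ultrafilterable fraction of plasma magnesium in
#'   (0, 1].
#' @return corrected fractional excretion in percent.
#' @export
fe_mg_corrected <- function(U_Mg, P_Mg, Ucr, Pcr, uf_fraction = 0.7) {
  if (any(uf_fraction <= 0)) {
    stop_panrenal("uf_fraction must be positive")
  }
  fractional_excretion(U_Mg, uf_fraction * P_Mg, Ucr, Pcr,
                       analyte = "magnesium")
}

#' Tubular maximum phosphate reabsorption per unit GFR (TmP/GFR)
#'
#' Walton-Bijvoet approximation from the tubular reabsorption of phosphate
#' `TRP = 1 - FE_PO4/100` and plasma phosphate: `TRP * P_phos` when
#' `TRP <= 0.86`, otherwise `0.3 * TRP / (1 - 0.8 * TRP) * P_phos`. The
#' result carries the units of plasma phosphate. The piecewise form has a
#' small documented discontinuity (about `0.03 * P_phos`) at the 0.86
#' junction and is monotone increasing in plasma phosphate.
#'
#' @param TRP tubular reabsorption of phosphate, in `[0, 1]`.
#' @param P_phos plasma phosphate (> 0).
#' @return TmP/GFR in the units of `P_phos`.
#' @export
tmp_gfr <- function(TRP, P_phos) {
  if (any(TRP < 0 | TRP > 1, na.rm = TRUE)) {
    stop_panrenal("TRP must lie in [0, 1]")
  }
  if (any(P_phos <= 0, na.rm = TRUE)) {
    stop_panrenal("plasma phosphate must be positive")
  }
  ifelse(TRP <= 0.86, TRP * P_phos, 0.3 * TRP / (1 - 0.8 * TRP) * P_phos)
}

#' Transtubular potassium gradient (TTKG)
#'
#' `(U_K / P_K) / (U_osm / P_osm)` — the urine-to-plasma potassium ratio
#' corrected for water abstraction in the collecting duct via the
#' osmolality ratio; dimensionless.
#'
#' @param Uk,Pk urine and plasma potassium.
#' @param Uosm,Posm urine and plasma osmolality.
#' @export
ttkg <- function(Uk, Pk, Uosm, Posm) {
  if (any(c(Uk, Pk, Uosm, Posm) <= 0, na.rm = TRUE)) {
    stop_panrenal("all TTKG inputs must be positive")
  }
  (Uk / Pk) / (Uosm / Posm)
}

#' Estimated GFR (CKD-EPI 2021 creatinine equation)
#'
#' Race-free 2021 refit: `142 * min(Scr/kappa, 1)^alpha *
#' max(Scr/kappa, 1)^-1.200 * 0.9938^age * 1.012[female]` with
#' `kappa = 0.7 (F) / 0.9 (M)` and `alpha = -0.241 (F) / -0.302 (M)`.
#' Valid for human adults; rodent panels should report creatinine
#' clearance instead (no validated rodent eGFR equation exists).
#'
#' @param scr_mg_dl serum/plasma creatinine in mg/dL.
#' @param age_years age in years.
#' @param sex `"F"` or `"M"` (recycled).
#' @return eGFR in mL/min/1.73 m^2; strictly decreasing in creatinine.
#' @export
egfr_ckdepi <- function(scr_mg_dl, age_years, sex) {
  stopifnot(all(sex %in% c("F", "M")))
  if (any(scr_mg_dl <= 0, na.rm = TRUE)) {
    stop_panrenal("creatinine must be positive")
  }
  kappa <- ifelse(sex == "F", 0.7, 0.9)
  alpha <- ifelse(sex == "F", -0.241, -0.302)
  fem <- ifelse(sex == "F", 1.012, 1)
  r <- scr_mg_dl / kappa
  142 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.2) * 0.9938^age_years * fem
}

#' Derived renal index table from a chemistry panel
#'
#' Computes, per subject and timepoint: fractional excretions for every
#' analyte measured in both urine and plasma (with the albumin-corrected
#' magnesium variant), TmP/GFR, TTKG, the aldosterone:renin ratio (only
#' when both analytes share the sample time), urinary analyte:creatinine
#' ratios, and eGFR when subject ages are supplied (human panels; rodent
#' panels get `NA` with a note). Missing analytes propagate as missing,
#' never zero.
#'
#' @param panel long chemistry panel (see [read_chemistry_panel()]).
#' @param ages optional named vector subject_id -> age in years, enabling
#'   eGFR.
#' @param uf_fraction ultrafilterable magnesium fraction for the corrected
#'   FE.
#' @return long data.frame `subject_id`, `timepoint`, `index`, `value`.
#' @export
derive_renal_indices <- function(panel, ages = NULL, uf_fraction = 0.7) {
  validate_panel(panel)
  get1 <- function(sub, tp, comp, an) {
    v <- panel$value[panel$subject_id == sub & panel$timepoint == tp &
                       panel$compartment == comp & panel$analyte == an]
    if (length(v) == 1) v else NA_real_
  }
  unit1 <- function(comp, an) {
    u <- unique(panel$unit[panel$compartment == comp & panel$analyte == an])
    if (length(u) == 1) u else NA_character_
  }
  combos <- unique(panel[c("subject_id", "timepoint")])
  fe_analytes <- intersect(
    unique(panel$analyte[panel$compartment == "urine"]),
    unique(panel$analyte[panel$compartment == "plasma"])
  )
  fe_analytes <- setdiff(fe_analytes, c("creatinine", "osmolality"))
  rows <- list()
  add <- function(sub, tp, index, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = sub, timepoint = tp, index = index, value = value,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(combos))) {
    sub <- combos$subject_id[i]
    tp <- combos$timepoint[i]
    ucr <- get1(sub, tp, "urine", "creatinine")
    pcr <- get1(sub, tp, "plasma", "creatinine")
    for (an in fe_analytes) {
      ux <- get1(sub, tp, "urine", an)
      px <- get1(sub, tp, "plasma", an)
      fe <- if (anyNA(c(ux, px, ucr, pcr))) NA_real_ else
        fractional_excretion(ux, px, ucr, pcr, analyte = an)
      add(sub, tp, paste0("FE_", an), fe)
      if (an == "magnesium" && !anyNA(c(ux, px, ucr, pcr))) {
        add(sub, tp, "FE_magnesium_corr",
            fe_mg_corrected(ux, px, ucr, pcr, uf_fraction))
      }
      if (an == "phosphate" && !anyNA(c(ux, px, ucr, pcr))) {
        fe_po4 <- fractional_excretion(ux, px, ucr, pcr, "phosphate")
        trp <- max(min(1 - fe_po4 / 100, 1), 0)
        add(sub, tp, "TmP_GFR", tmp_gfr(trp, px))
      }
    }
    uk <- get1(sub, tp, "urine", "potassium")
    pk <- get1(sub, tp, "plasma", "potassium")
    uo <- get1(sub, tp, "urine", "osmolality")
    po <- get1(sub, tp, "plasma", "osmolality")
    add(sub, tp, "TTKG",
        if (anyNA(c(uk, pk, uo, po))) NA_real_ else ttkg(uk, pk, uo, po))
    aldo <- get1(sub, tp, "plasma", "aldosterone")
    renin <- get1(sub, tp, "plasma", "renin")
    add(sub, tp, "aldosterone_renin_ratio",
        if (anyNA(c(aldo, renin)) || renin == 0) NA_real_ else aldo / renin)
    for (an in setdiff(unique(panel$analyte[panel$compartment == "urine"]),
                       c("creatinine", "osmolality", "volume"))) {
      ux <- get1(sub, tp, "urine", an)
      add(sub, tp, paste0(an, "_creatinine_ratio"),
          if (anyNA(c(ux, ucr)) || ucr == 0) NA_real_ else ux / ucr)
    }
    if (!is.null(ages) && sub %in% names(ages) && !is.na(pcr)) {
      u <- unit1("plasma", "creatinine")
      scr <- switch(u,
                    "mg/dl" = pcr,
                    "mmol/l" = pcr * 11.312,
                    "umol/l" = pcr / 88.42,
                    NA_real_)
      sex <- panel$sex[match(sub, panel$subject_id)]
      add(sub, tp, "eGFR",
          if (is.na(scr)) NA_real_ else egfr_ckdepi(scr, ages[[sub]], sex))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalise measurements to the control-group mean
#'
#' Divides each value by the mean of the control group for the same
#' compartment, analyte and sex ("fold of control"). A zero or missing
#' control mean yields `NA` (flagged), never infinity. By construction the
#' control group's own folds have mean 1 per analyte.
#'
#' @param panel long chemistry panel with a `group` column.
#' @param control label of the control group.
#' @return the panel with columns `fold_of_control` and `control_missing`.
#' @export
normalize_to_control <- function(panel, control = "control") {
  validate_panel(panel)
  if (!control %in% panel$group) {
    stop_panrenal("no rows with control group '", control, "'")
  }
  key <- paste(panel$compartment, panel$analyte, panel$sex, sep = "\r")
  ctrl <- panel$group == control
  means <- tapply(panel$value[ctrl], key[ctrl], mean)
  m <- as.numeric(means[key])
  bad <- is.na(m) | m == 0
  panel$fold_of_control <- ifelse(bad, NA_real_, panel$value / m)
  panel$control_missing <- bad
  panel
}

#' Repeated-measures comparison of timepoints against baseline
#'
#' Per (compartment, analyte): a repeated-measures one-way ANOVA across
#' timepoints (subject as error stratum) plus paired contrasts of every
#' post-baseline timepoint against baseline, Bonferroni-corrected with
#' family size equal to the number of post-baseline timepoints. Subjects
#' missing any timepoint are dropped from that analyte's comparison.
#'
#' @param panel long chemistry panel.
#' @param baseline baseline timepoint label (default first in the data).
#' @param family Bonferroni family size; defaults to the number of
#'   post-baseline timepoints.
#' @return data.frame per analyte and contrast: `compartment`, `analyte`,
#'   `anova_p`, `timepoint`, `p_raw`, `p_bonferroni`.
#' @export
compare_timepoints <- function(panel, baseline = NULL, family = NULL) {
  validate_panel(panel)
  tps <- unique(panel$timepoint)
  if (length(tps) < 2) stop_panrenal("need at least 2 timepoints")
  baseline <- baseline %||% tps[1]
  if (!baseline %in% tps) stop_panrenal("baseline timepoint not in panel")
  post <- setdiff(tps, baseline)
  fam <- family %||% length(post)
  keys <- unique(panel[c("compartment", "analyte")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- panel$compartment == keys$compartment[i] &
      panel$analyte == keys$analyte[i]
    d <- panel[sel, c("subject_id", "timepoint", "value")]
    wide <- tapply(d$value, list(d$subject_id, d$timepoint), mean)
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 2) next
    long <- data.frame(
      subject_id = factor(rep(rownames(wide), ncol(wide))),
      timepoint = factor(rep(colnames(wide), each = nrow(wide))),
      value = as.numeric(wide)
    )
    if (stats::sd(long$value) == 0) {
      anova_p <- 1 # constant response: nothing to test
    } else {
      fit <- stats::aov(value ~ timepoint + Error(subject_id), data = long)
      tab <- summary(fit)[["Error: Within"]][[1]]
      anova_p <- tab[["Pr(>F)"]][1]
      if (is.na(anova_p) || is.nan(anova_p)) anova_p <- 1
    }
    for (tp in post) {
      diffs <- wide[, tp] - wide[, baseline]
      p_raw <- if (stats::sd(diffs) == 0) 1 else
        stats::t.test(diffs)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = keys$compartment[i], analyte = keys$analyte[i],
        anova_p = anova_p, timepoint = tp, p_raw = p_raw,
        p_bonferroni = min(1, p_raw * fam), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-factor group comparison of a chemistry panel
#'
#' Per (compartment, analyte): two-way ANOVA `value ~ group * sex`,
#' reporting the treatment-group factor p-value (the boxed statistic of
#' sham-normalised panel displays) alongside the sex and interaction
#' p-values.
#'
#' @param panel long chemistry panel with `group` and `sex` columns and at
#'   least two subjects per group.
#' @return data.frame `compartment`, `analyte`, `p_group`, `p_sex`,
#'   `p_interaction`.
#' @export
compare_groups <- function(panel) {
  validate_panel(panel)
  if (length(unique(panel$group)) < 2) {
    stop_panrenal("need at least 2 groups")
  }
  keys <- unique(panel[c("compartment", "analyte")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- panel$compartment == keys$compartment[i] &
      panel$analyte == keys$analyte[i]
    d <- panel[sel, ]
    d$group <- factor(d$group)
    d$sex <- factor(d$sex)
    two_sex <- nlevels(d$sex) > 1
    form <- if (two_sex) value ~ group * sex else value ~ group
    tab <- summary(stats::aov(form, data = d))[[1]]
    p <- tab[["Pr(>F)"]]
    rows[[length(rows) + 1L]] <- data.frame(
      compartment = keys$compartment[i], analyte = keys$analyte[i],
      p_group = p[1],
      p_sex = if (two_sex) p[2] else NA_real_,
      p_interaction = if (two_sex) p[3] else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
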