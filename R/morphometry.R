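# Quantitative anatomy from integer label rasters: discrete tubule metrics
# within the cortex, dot densities per anatomical region, fractional areas,
# and normalised organ weights. Physical units always come from the raster
# metadata, never from the pixel grid.

#' Construct a label raster
#'
#' An integer-valued 2D raster with anatomical region codes, an object
#' channel of discrete tubule labels (or a binary tubule mask), a physical
#' pixel size in micrometres and a region-code legend. Region codes
#' partition the tissue; code 0 is background.
#'
#' @param regions integer matrix of region codes.
#' @param objects integer matrix of the same shape: 0 outside tubules,
#'   a positive label (or 1 for a binary mask) inside.
#' @param pixel_size_um physical pixel edge length in micrometres (> 0).
#' @param region_legend named integer vector, region name -> code; must
#'   include `background = 0`.
#' @param interstitium optional binary matrix marking interstitial pixels.
#' @return an object of class `label_raster`.
#' @export
label_raster <- function(regions, objects = NULL, pixel_size_um = 1,
                         region_legend = c(background = 0L, cortex = 1L,
                                           OSOM = 2L, ISOM = 3L, IM = 4L),
                         interstitium = NULL) {
  stopifnot(is.matrix(regions), pixel_size_um > 0)
  regions <- matrix(as.integer(regions), nrow(regions))
  if (is.null(objects)) objects <- matrix(0L, nrow(regions), ncol(regions))
  objects <- matrix(as.integer(objects), nrow(objects))
  stopifnot(identical(dim(regions), dim(objects)))
  if (!all(unique(as.integer(regions)) %in% region_legend)) {
    stop_panrenal("raster contains region codes missing from the legend")
  }
  structure(list(regions = regions, objects = objects,
                 pixel_size_um = pixel_size_um,
                 region_legend = region_legend,
                 interstitium = interstitium),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  cat(sprintf("label_raster %d x %d px at %g um/px\n",
              nrow(x$regions), ncol(x$regions), x$pixel_size_um))
  for (nm in names(x$region_legend)) {
    npx <- sum(x$regions == x$region_legend[[nm]])
    cat(sprintf("  %-10s code %d: %d px (%.4f mm^2)\n", nm,
                x$region_legend[[nm]], npx,
                npx * x$pixel_size_um^2 / 1e6))
  }
  cat(sprintf("  objects: %d labelled px\n", sum(x$objects != 0L)))
  invisible(x)
}

#' Connected-component labelling of a binary mask
#'
#' Flood-fill labelling with 8- or 4-connectivity. Written in-package so
#' the neighbourhood rule stays configurable and reportable (whether
#' touching tubule profiles merge depends on it).
#'
#' @param mask logical or 0/1 integer matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- mask != 0
  labels <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  todo <- which(fg)
  next_label <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    frontier <- start
    labels[start] <- next_label
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nbr_r <- rep(r, each = nrow(offs)) + offs[, "dr"]
      nbr_c <- rep(c, each = nrow(offs)) + offs[, "dc"]
      ok <- nbr_r >= 1 & nbr_r <= nr & nbr_c >= 1 & nbr_c <= nc
      idx <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      idx <- unique(idx[fg[idx] & labels[idx] == 0L])
      labels[idx] <- next_label
      frontier <- idx
    }
  }
  labels
}

#' Tubule morphometry within the cortex
#'
#' Finds discrete tubules by connected-component labelling of the object
#' channel restricted to the cortex (components clipped by the cortex
#' border count with their in-cortex area only), discards components below
#' `min_area_um2`, and reports the three display quantities: mean area per
#' tubule (um^2), tubule density per mm^2 of cortex, and total tubule area
#' as a percentage of cortex area. These satisfy the identity
#' `percent_of_cortex = density_per_mm2 * mean_area_um2 * 1e-4`.
#'
#' @param raster a [label_raster] with a cortex region.
#' @param min_area_um2 minimum component area kept (default 100 um^2,
#'   rejecting single-pixel noise at typical resolutions).
#' @param connectivity component connectivity, 8 (default) or 4.
#' @return list of class `tubule_morphometry`: `n_tubules`, `areas_um2`,
#'   `mean_area_um2`, `density_per_mm2`, `percent_of_cortex`,
#'   `cortex_area_mm2`.
#' @export
tubule_morphometry <- function(raster, min_area_um2 = 100,
                               connectivity = 8) {
  stopifnot(inherits(raster, "label_raster"))
  code <- raster$region_legend[["cortex"]]
  if (is.null(code)) stop_panrenal("raster legend lacks a cortex region")
  in_cortex <- raster$regions == code
  cortex_px <- sum(in_cortex)
  if (cortex_px == 0L) stop_panrenal("zero cortex area")
  px2 <- raster$pixel_size_um^2
  cortex_area_mm2 <- cortex_px * px2 / 1e6
  comp <- label_components(raster$objects != 0L & in_cortex, connectivity)
  areas_px <- tabulate(comp[comp > 0L])
  areas_um2 <- areas_px * px2
  areas_um2 <- areas_um2[areas_um2 >= min_area_um2]
  n <- length(areas_um2)
  mean_area <- if (n) mean(areas_um2) else 0
  density <- n / cortex_area_mm2
  percent <- sum(areas_um2) / (cortex_area_mm2 * 1e6) * 100
  structure(list(n_tubules = n, areas_um2 = areas_um2,
                 mean_area_um2 = mean_area, density_per_mm2 = density,
                 percent_of_cortex = percent,
                 cortex_area_mm2 = cortex_area_mm2),
            class = "tubule_morphometry")
}

#' @export
print.tubule_morphometry <- function(x, ...) {
  cat(sprintf(paste0("%d tubules; mean area %.1f um^2; density %.1f /mm^2",
                     " of cortex; %.2f%% of cortex area\n"),
              x$n_tubules, x$mean_area_um2, x$density_per_mm2,
              x$percent_of_cortex))
  invisible(x)
}

#' Dot density per anatomical region
#'
#' Counts pre-detected dots (e.g. ISH probe signals) per region of a label
#' raster and divides by the physical region area. The summary `Average`
#' is the simple arithmetic mean of the four anatomical region densities
#' (cortex, OSOM, ISOM, IM), not an area-weighted mean. Dots falling on
#' background are counted separately and excluded from densities.
#'
#' @param dots data.frame with `x_um`, `y_um` physical coordinates (origin
#'   at the raster corner).
#' @param raster a [label_raster].
#' @return data.frame per region: `region`, `count`, `area_mm2`,
#'   `density_per_mm2` (NA-flagged for zero-area regions), with the
#'   four-region mean in `attr(, "region_average")` and out-of-tissue dots
#'   in `attr(, "n_background")`.
#' @export
dot_density <- function(dots, raster) {
  stopifnot(inherits(raster, "label_raster"),
            all(c("x_um", "y_um") %in% names(dots)))
  px <- raster$pixel_size_um
  nr <- nrow(raster$regions)
  nc <- ncol(raster$regions)
  cc <- pmin(pmax(floor(dots$x_um / px) + 1L, 1L), nc)
  rr <- pmin(pmax(floor(dots$y_um / px) + 1L, 1L), nr)
  codes <- raster$regions[cbind(rr, cc)]
  legend <- raster$region_legend
  regions <- setdiff(names(legend), "background")
  out <- data.frame(region = regions, count = NA_integer_,
                    area_mm2 = NA_real_, density_per_mm2 = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    code <- legend[[regions[i]]]
    npx <- sum(raster$regions == code)
    out$count[i] <- sum(codes == code)
    out$area_mm2[i] <- npx * px^2 / 1e6
    out$density_per_mm2[i] <- if (npx == 0L) NA_real_ else
      out$count[i] / out$area_mm2[i]
  }
  anatomical <- intersect(c("cortex", "OSOM", "ISOM", "IM"), out$region)
  attr(out, "region_average") <-
    mean(out$density_per_mm2[out$region %in% anatomical])
  attr(out, "n_background") <- sum(codes == legend[["background"]])
  out
}

#' Fractional area of a target mask within a reference mask
#'
#' `100 * |target AND reference| / |reference|` in pixels — e.g. the
#' fractional interstitial area within the tissue of a PAS-stained
#' section.
#'
#' @param target,reference binary (or logical) matrices of equal shape.
#' @return percentage.
#' @export
fractional_area <- function(target, reference) {
  stopifnot(identical(dim(target), dim(reference)))
  ref_px <- sum(reference != 0)
  if (ref_px == 0L) stop_panrenal("empty reference mask")
  100 * sum(target != 0 & reference != 0) / ref_px
}

#' Normalised kidney weight
#'
#' Mean of the available kidney wet weights (mg), normalised to the
#' animal's body weight and expressed as a percentage:
#' `mean(kidney mg) / (bodyweight g * 1000) * 100`. If only one kidney
#' weight is recorded, that kidney is used without averaging.
#'
#' @param left_mg,right_mg kidney wet weights in milligrams (`NA` if not
#'   recorded).
#' @param bodyweight_g body weight in grams (> 0).
#' @return kidney weight as percent of body weight.
#' @export
normalized_kidney_weight <- function(left_mg, right_mg, bodyweight_g) {
  if (any(bodyweight_g <= 0, na.rm = TRUE)) {
    stop_panrenal("bodyweight must be positive")
  }
  both_missing <- is.na(left_mg) & is.na(right_mg)
  if (any(both_missing)) {
    stop_panrenal("at least one kidney weight must be present")
  }
  mean_kidney <- rowMeans(cbind(left_mg, right_mg), na.rm = TRUE)
  if (any(mean_kidney == 0, na.rm = TRUE)) {
    warning("kidney weight of 0 mg recorded", call. = FALSE)
  }
  mean_kidney / (bodyweight_g * 1000) * 100
}

#' Multi-group comparison of morphometric endpoints
#'
#' One-way ANOVA with Dunnett many-to-one contrasts against the control
#' group (several exposure groups), or a two-sample Student t-test when
#' only two groups are present. Raw and adjusted p-values are reported;
#' the Dunnett adjustment never reports an adjusted p below the raw p.
#'
#' @param values numeric endpoint per animal.
#' @param group group label per animal.
#' @param control label of the reference group (default `"control"`).
#' @return data.frame per non-control group: `group`, `estimate` (mean
#'   difference vs control), `p_raw`, `p_adjusted`, plus the overall
#'   `anova_p` as an attribute.
#' @export
group_compare <- function(values, group, control = "control") {
  group <- as.character(group)
  stopifnot(length(values) == length(group))
  if (!control %in% group) stop_panrenal("control group absent")
  others <- setdiff(unique(group), control)
  if (length(others) == 0L) stop_panrenal("need at least two groups")
  d <- data.frame(values = values,
                  group = factor(group, levels = c(control, others)))
  if (stats::sd(values) == 0) {
    # identical endpoints across all animals: no group effect to test
    out <- data.frame(group = others, estimate = 0, p_raw = 1,
                      p_adjusted = 1, stringsAsFactors = FALSE)
    attr(out, "anova_p") <- 1
    return(out)
  }
  if (length(others) == 1L) {
    tt <- stats::t.test(values ~ group, data = d, var.equal = TRUE)
    out <- data.frame(group = others,
                      estimate = diff(rev(tt$estimate))[[1]] * -1,
                      p_raw = tt$p.value, p_adjusted = tt$p.value,
                      stringsAsFactors = FALSE)
    attr(out, "anova_p") <- tt$p.value
    rownames(out) <- NULL
    return(out)
  }
  fit <- stats::aov(values ~ group, data = d)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  dn <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(dn, test = multcomp::adjusted("single-step"))
  raw <- summary(dn, test = multcomp::adjusted("none"))
  out <- data.frame(group = others,
                    estimate = as.numeric(sm$test$coefficients),
                    p_raw = as.numeric(raw$test$pvalues),
                    p_adjusted = pmax(as.numeric(sm$test$pvalues),
                                      as.numeric(raw$test$pvalues)),
                    stringsAsFactors = FALSE)
  attr(out, "anova_p") <- anova_p
  rownames(out) <- NULL
  out
}

#' Incidence as a percentage
#'
#' `100 * affected / total` — e.g. the fraction of animals in a group with
#' a histopathological finding such as thrombotic microangiopathy.
#'
#' @param affected number of affected individuals.
#' @param total group size (> 0).
#' @return percentage.
#' @export
incidence_rate <- function(affected, total) {
  stopifnot(all(total > 0), all(affected >= 0), all(affected <= total))
  100 * affected / total
}
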