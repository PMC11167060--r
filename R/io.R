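# Readers/writers for the plain-text interchange formats used throughout:
# tab-separated tables for differential features, dataset descriptors,
# ortholog maps and chemistry panels; GMT for gene sets; 16-bit TIFF plus a
# JSON sidecar for label masks.

DATASET_COLUMNS <- c("feature_id", "feature_class", "symbol", "species",
                     "log2fc", "p_value")
FEATURE_CLASSES <- c("transcript", "protein", "phosphosite", "cpg",
                     "metabolite-gene-link", "taxon")
MODALITIES <- c("epigenome", "transcriptome", "proteome", "epiproteome",
                "metabolome", "metagenome", "plasma", "exosome")

#' Read or write a differential-feature table
#'
#' Tables are tab-separated UTF-8 with a header row and columns
#' `feature_id`, `feature_class`, `symbol`, `species`, `log2fc`, `p_value`.
#' One row is one measured biomolecule's differential result in one dataset.
#'
#' @param path file path.
#' @return `read_dataset_table()` returns a data.frame with the columns
#'   above; `write_dataset_table()` returns `path` invisibly.
#' @export
read_dataset_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(DATASET_COLUMNS, names(x))
  if (length(missing)) {
    stop_panrenal("dataset table ", path, " lacks columns: ",
                  paste(missing, collapse = ", "))
  }
  x[DATASET_COLUMNS]
}

#' @rdname read_dataset_table
#' @param x data.frame of differential feature records.
#' @export
write_dataset_table <- function(x, path) {
  stopifnot(all(DATASET_COLUMNS %in% names(x)))
  utils::write.table(x[DATASET_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write dataset descriptors
#'
#' One row per dataset: `dataset_id`, `mission`, `species`, `tissue`,
#' `modality`, `kidney_specific`, `core_scoring`. A dataset is core-scoring
#' iff it is a kidney-specific proteome or transcriptome dataset; only core
#' datasets feed the consensus product score.
#'
#' @param path file path.
#' @export
read_descriptors <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$kidney_specific <- as.logical(x$kidney_specific)
  x$core_scoring <- as.logical(x$core_scoring)
  validate_descriptors(x)
  x
}

#' @rdname read_descriptors
#' @param x descriptor data.frame.
#' @export
write_descriptors <- function(x, path) {
  validate_descriptors(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_descriptors <- function(x) {
  need <- c("dataset_id", "mission", "species", "tissue", "modality",
            "kidney_specific", "core_scoring")
  stopifnot(all(need %in% names(x)))
  if (anyDuplicated(x$dataset_id)) {
    stop_panrenal("duplicate dataset_id in descriptors")
  }
  bad <- x$core_scoring &
    !(x$kidney_specific & x$modality %in% c("proteome", "transcriptome"))
  if (any(bad)) {
    stop_panrenal("core_scoring requires a kidney-specific proteome or ",
                  "transcriptome dataset: ",
                  paste(x$dataset_id[bad], collapse = ", "))
  }
  invisible(x)
}

#' Read or write an ortholog map
#'
#' Tab-separated with columns `species`, `native_symbol`, `hgnc_symbol`; a
#' native symbol mapping to several HGNC symbols occupies several rows.
#'
#' @param path file path.
#' @export
read_ortholog_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "native_symbol", "hgnc_symbol") %in% names(x)))
  x
}

#' @rdname read_ortholog_map
#' @param x ortholog map data.frame.
#' @export
write_ortholog_map <- function(x, path) {
  stopifnot(all(c("species", "native_symbol", "hgnc_symbol") %in% names(x)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write gene sets in GMT format
#'
#' GMT is one term per line: term id, description, then tab-separated member
#' symbols. `read_gmt()` returns a named list of character vectors with the
#' descriptions in `attr(, "description")`.
#'
#' @param path file path.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  # fgsea drops the description column; recover it for round-tripping.
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  names(desc) <- vapply(parts, `[`, "", 1L)
  attr(sets, "description") <- desc[names(sets)]
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors (member HGNC symbols).
#' @param description optional character vector of term descriptions,
#'   recycled; defaults to the `description` attribute or `"na"`.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  desc <- description %||% attr(sets, "description") %||% rep("na", length(sets))
  desc <- rep_len(desc, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a clinical chemistry panel
#'
#' Long-format tab-separated table with columns `subject_id`, `group`,
#' `sex`, `timepoint`, `compartment` (`urine` or `plasma`), `analyte`,
#' `value`, `unit`. Each (subject, timepoint, compartment, analyte) is
#' unique.
#'
#' @param path file path.
#' @export
read_chemistry_panel <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character",
                                        group = "character",
                                        sex = "character",
                                        timepoint = "character",
                                        compartment = "character",
                                        analyte = "character",
                                        value = "numeric",
                                        unit = "character"))
  validate_panel(x)
  x
}

#' @rdname read_chemistry_panel
#' @param x panel data.frame.
#' @export
write_chemistry_panel <- function(x, path) {
  validate_panel(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_panel <- function(x) {
  need <- c("subject_id", "group", "sex", "timepoint", "compartment",
            "analyte", "value", "unit")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop_panrenal("chemistry panel lacks columns: ",
                  paste(missing, collapse = ", "))
  }
  key <- paste(x$subject_id, x$timepoint, x$compartment, x$analyte)
  if (anyDuplicated(key)) {
    stop_panrenal("duplicate (subject, timepoint, compartment, analyte) rows")
  }
  if (any(x$value < 0, na.rm = TRUE)) {
    stop_panrenal("negative concentrations in panel")
  }
  invisible(x)
}

#' Write or read a label raster with its JSON sidecar
#'
#' The region and object channels are stored as single-channel 16-bit TIFFs
#' (`<prefix>_regions.tif`, `<prefix>_objects.tif`, and
#' `<prefix>_interstitium.tif` when present); pixel size in micrometres and
#' the region-code legend go to `<prefix>_meta.json`. Physical units are
#' carried in the sidecar, never implied by raster resolution.
#'
#' @param raster a [label_raster] object.
#' @param prefix path prefix for the output files.
#' @return `write_label_raster()` returns the prefix invisibly;
#'   `read_label_raster()` returns a [label_raster].
#' @export
write_label_raster <- function(raster, prefix) {
  stopifnot(inherits(raster, "label_raster"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_panrenal("the 'tiff' package is required for raster i/o")
  }
  write1 <- function(m, path) {
    stopifnot(max(m) < 65536)
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  }
  write1(raster$regions, paste0(prefix, "_regions.tif"))
  write1(raster$objects, paste0(prefix, "_objects.tif"))
  if (!is.null(raster$interstitium)) {
    write1(raster$interstitium, paste0(prefix, "_interstitium.tif"))
  }
  meta <- list(pixel_size_um = raster$pixel_size_um,
               region_legend = as.list(raster$region_legend))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(prefix) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_panrenal("the 'tiff' package is required for raster i/o")
  }
  read1 <- function(path) {
    m <- tiff::readTIFF(path)
    matrix(as.integer(round(m * 65535)), nrow = nrow(m))
  }
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  inter_path <- paste0(prefix, "_interstitium.tif")
  label_raster(
    regions = read1(paste0(prefix, "_regions.tif")),
    objects = read1(paste0(prefix, "_objects.tif")),
    pixel_size_um = meta$pixel_size_um,
    region_legend = unlist(meta$region_legend),
    interstitium = if (file.exists(inter_path)) read1(inter_path) else NULL
  )
}
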