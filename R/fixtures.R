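# Packaged study fixtures: the 21-gene x 18-structure expression Z-score
# table (transcribed cell-for-cell from the published table, including its
# typographic en-dash minus signs, the gene names as printed, and two
# genuinely missing cells in the MAAD row), the 20 AD-predictive AAL
# regions, and the default structure <-> region mapping.

# Allen Human Brain Atlas style top-level structure codes, in table column
# order: frontal lobe, insula, cingulate gyrus, hippocampal formation,
# parahippocampal gyrus, occipital lobe, parietal lobe, temporal lobe,
# amygdala, basal forebrain, globus pallidus, striatum, claustrum,
# epithalamus, hypothalamus, subthalamus, dorsal thalamus, ventral thalamus.
TABLE_STRUCTURES <- c("FL", "Ins", "CgG", "HP", "PHG", "OL", "PL", "TL",
                      "Amy", "BF", "GP", "Str", "Cla", "ET", "HT", "ST",
                      "DT", "VT")

# Gene names as printed ("MART" and "MAAD" are kept verbatim); values are
# space-separated in column order, "NA" marking a missing cell.
.TABLE_Z_RAW <- c(
  MART    = "1.5 1.5 1.3 0.29 0.14 1.2 1.4 1.5 -0.48 0.18 -0.67 -1.3 0.11 -2.2 -0.36 -0.45 -0.09 -0.85",
  APOE    = "-0.87 -0.63 -0.57 -1.2 -0.03 -0.48 -0.79 -0.58 1 1.4 2.4 1.2 -0.48 0.34 0.71 0.38 1 0.8",
  PICALM  = "-1 -1.3 -0.94 -0.39 -0.76 -0.75 -0.9 -1 0.04 0.74 0.97 -0.33 0.4 -0.75 -0.61 0 -0.06 2",
  BIN1    = "-0.55 -0.6 -0.39 0.53 -0.67 -0.42 -0.51 -0.47 -0.06 0.65 0.88 -0.55 0.2 -2.1 -1.3 0.45 0.32 1.4",
  CLU     = "0.61 0.76 0.73 0.76 0.48 0.51 0.55 0.73 0.55 0.86 0.25 2.4 0.13 -1.2 -0.13 -0.29 0.02 -0.57",
  CR1     = "-0.24 -0.25 -0.12 -1.1 0.19 -0.68 -0.04 0.39 -0.25 -1.1 -0.62 -0.38 -0.43 -0.87 -0.96 0.4 -0.55 1.4",
  ABCA7   = "-0.7 -1 -0.55 1 -1.6 -0.24 -0.8 -0.94 0.93 1.6 -1.5 -1.8 0.84 -0.49 -0.48 1.4 0.11 0.73",
  SORL1   = "0.31 -0.38 -0.07 0.31 -0.6 0.93 0.56 -0.08 -1.6 -1.1 0.79 -2.4 -0.12 0.73 -0.95 0.8 -0.31 0.85",
  PLEKHC1 = "-0.97 -0.84 -0.47 -0.85 0.04 -0.94 -0.83 -0.79 1.6 1.1 1.8 0.26 0.79 -0.19 0.15 0.48 0.34 1.2",
  CD2AP   = "-1 -1.5 -1.3 -0.59 -0.67 -0.01 -0.59 -0.83 0.08 -1.3 0.62 0.4 -1.1 1.1 0.17 -0.12 0.52 -0.1",
  CD33    = "-0.86 -0.85 -1.2 -0.76 -0.31 -1.4 -0.95 -0.65 0.54 -0.41 0.86 -0.79 0.57 0.36 -0.49 1.2 -0.32 1.3",
  APP     = "-0.29 -0.43 -0.12 0.42 0.16 0.09 -0.05 -0.2 0.7 0.01 0.47 -0.36 2 -1.1 -1.1 -0.29 0.11 1.3",
  PSEN1   = "-0.56 -0.82 -0.56 -1.1 -0.98 -0.75 -0.68 -0.66 -1 0.66 1.1 -0.34 -0.59 -0.61 -1.1 0.41 -0 1.3",
  PSEN2   = "-0.86 -0.79 -0.77 -0.43 -0.75 -1.3 -0.98 -0.85 -0.23 0.8 -0.5 -0.68 1.8 -0.93 0.59 1.5 0.83 0.77",
  CASS    = "-0.36 -0.28 -1.1 -0.88 -0.37 -0.64 -0.75 0.41 0.14 1.2 1.8 0.97 -0.77 -1.7 0.89 -0.51 0.83 0.77",
  EPHA1   = "-0.21 -0.31 -0.29 -0.48 0.05 -0.53 0.29 0.03 -0.05 -0.6 -0.9 -0.49 0.4 -0.72 -0.86 0.07 -0.32 0.78",
  PTK2B   = "0.58 0.35 0.36 2.2 -0.21 0.4 0.54 0.34 1.6 0.54 -1.6 -0.51 0.73 -1.8 -1.5 -0.75 0.89 0.73",
  INPP5D  = "-0.89 -0.82 -1.1 -1.2 -1.1 0.43 -0.68 -0.77 -0.43 0.21 1.5 0.43 -0.49 1.7 0.04 1.1 -0.12 0.47",
  MEF2C   = "1.3 1.4 1.3 -0.21 1.1 1.4 1.4 1.4 0.64 -0.35 -0.73 -0.66 1.5 -0.81 -0.8 -0.73 -0.74 -0.4",
  CUGBP1  = "0.34 0.18 0.48 1.7 0.76 0.93 0.61 0.42 1.6 0.84 -0.64 0.55 1.8 -0.52 -0.48 -1.1 0.82 -0.46",
  MAAD    = "-0.37 -0.41 0.27 1.6 NA NA 0.04 -0.15 2.3 0.48 -0.98 0.3 2.1 -0.96 -0.59 -0.01 -0.72 1.3"
)

# printed gene symbol -> canonical symbol, for reporting only
GENE_ALIASES <- c(MART = "MAPT")

# character matrix of cells exactly as transcribed: en-dash minus signs,
# empty string for missing cells
.table_z_cells <- function() {
  rows <- strsplit(.TABLE_Z_RAW, " ", fixed = TRUE)
  cells <- do.call(rbind, rows)
  stopifnot(ncol(cells) == length(TABLE_STRUCTURES))
  cells[cells == "NA"] <- ""
  cells <- sub("^-", "\u2013", cells)
  dimnames(cells) <- list(names(.TABLE_Z_RAW), TABLE_STRUCTURES)
  cells
}

# The 20 AD-predictive AAL regions (left/right suffixed AAL-style names).
AD_PREDICTIVE_REGIONS <- c(
  "Amygdala_L", "Caudate_L", "Hippocampus_L", "Hippocampus_R",
  "Frontal_Inf_Oper_L", "Parietal_Inf_R", "Insula_L", "Putamen_L",
  "Cingulum_Mid_R", "Frontal_Mid_L", "Frontal_Mid_R", "Pallidum_L",
  "Pallidum_R", "Paracentral_Lobule_L", "ParaHippocampal_L",
  "ParaHippocampal_R", "Precentral_L", "Precuneus_L", "Precuneus_R",
  "Parietal_Sup_R")

# Default many-to-many mapping of top-level structures to the AAL regions
# they contain spatially; every AD-predictive region appears exactly once
# here (no region straddles two structures in this set).
.DEFAULT_MAPPING <- list(
  FL  = c("Frontal_Inf_Oper_L", "Frontal_Mid_L", "Frontal_Mid_R", "Precentral_L"),
  Ins = "Insula_L",
  CgG = "Cingulum_Mid_R",
  HP  = c("Hippocampus_L", "Hippocampus_R"),
  PHG = c("ParaHippocampal_L", "ParaHippocampal_R"),
  PL  = c("Parietal_Inf_R", "Parietal_Sup_R", "Precuneus_L", "Precuneus_R",
          "Paracentral_Lobule_L"),
  Amy = "Amygdala_L",
  GP  = c("Pallidum_L", "Pallidum_R"),
  Str = c("Caudate_L", "Putamen_L")
)

#' Write the packaged study fixtures to a directory
#'
#' Writes three byte-stable, tab-delimited UTF-8 files: the 21 x 18
#' gene-by-structure Z-score table (`gene_structure_zscores.tsv`,
#' transcribed with its typographic minus signs and two empty cells), the
#' list of 20 AD-predictive AAL regions (`ad_predictive_regions.tsv`), and
#' the default structure-to-region mapping
#' (`structure_region_mapping.tsv`).
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- .table_z_cells()
  zdf <- data.frame(gene = rownames(cells), cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  zpath <- file.path(dir, "gene_structure_zscores.tsv")
  write_tsv(zdf, zpath)
  rpath <- file.path(dir, "ad_predictive_regions.tsv")
  write_tsv(data.frame(region_name = AD_PREDICTIVE_REGIONS), rpath)
  mdf <- data.frame(
    structure = rep(names(.DEFAULT_MAPPING), lengths(.DEFAULT_MAPPING)),
    region_name = unlist(.DEFAULT_MAPPING, use.names = FALSE))
  mpath <- file.path(dir, "structure_region_mapping.tsv")
  write_tsv(mdf, mpath)
  invisible(list(zscores = zpath, regions = rpath, mapping = mpath))
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "swiron")
  if (p == "") {
    # fall back to regenerating in a session temp dir (e.g. during development)
    p <- file.path(tempdir(), "swiron-extdata", file)
    if (!file.exists(p)) write_fixtures(dirname(p))
  }
  p
}

# normalise typographic minus signs (en dash U+2013, minus U+2212, hyphen)
.parse_signed <- function(s) {
  s <- gsub("[\u2013\u2212]", "-", trimws(s))
  s[s == ""] <- NA
  suppressWarnings(as.numeric(s))
}

#' Load a gene-by-structure Z-score table
#'
#' Reads a tab-delimited table whose first column holds gene names and whose
#' remaining columns hold per-structure normalized Z-scores. Both ASCII
#' hyphen-minus and typographic en-dash/minus signs are accepted; empty
#' cells become `NA`. Defaults to the packaged 21-gene table.
#'
#' @param path TSV path; `NULL` for the packaged fixture.
#' @return Numeric matrix (genes x structures) of class `expression_table`.
#' @export
load_zscore_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("gene_structure_zscores.tsv")
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  z <- apply(df[, -1, drop = FALSE], 2, .parse_signed)
  rownames(z) <- df[[1]]
  structure(z, class = c("expression_table", class(z)))
}

#' Load the packaged AD-predictive region list
#'
#' @param path TSV with a `region_name` column; `NULL` for the packaged
#'   20-region fixture.
#' @return Character vector of region names.
#' @export
load_region_list <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("ad_predictive_regions.tsv")
  read.delim(path, sep = "\t", fileEncoding = "UTF-8")$region_name
}

#' Load a structure-to-region mapping table
#'
#' @param path TSV with columns `structure` and `region_name` (many-to-many,
#'   one pair per row); `NULL` for the packaged default mapping.
#' @return Data frame with columns `structure` and `region_name`.
#' @export
load_structure_mapping <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("structure_region_mapping.tsv")
  read.delim(path, sep = "\t", fileEncoding = "UTF-8")
}
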