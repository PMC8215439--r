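# Regional iron feature extraction: per-region mean phase and conversion to
# the iron content score X = -b * pi / 4096 (radians).

#' Convert raw phase to the iron content score
#'
#' Maps a raw SWI phase value \eqn{b \in [-4096, 4095]} to
#' \eqn{X = -b\pi/4096}, a score in radians within \eqn{[-\pi, \pi]} that
#' increases with iron content (iron lowers the phase).
#'
#' @param b_mean Numeric vector of raw phase values (typically regional
#'   means); `NA` is passed through.
#' @return Numeric vector of iron scores in radians.
#' @examples
#' phase_to_iron(c(-4096, 0, 2048))  # pi, 0, -pi/2
#' @export
phase_to_iron <- function(b_mean) {
  ok <- is.na(b_mean) | (b_mean >= PHASE_MIN & b_mean <= PHASE_MAX)
  if (!all(ok))
    stop(sprintf("phase values outside [%d, %d]: e.g. %g",
                 PHASE_MIN, PHASE_MAX, b_mean[!ok][1]))
  -b_mean * pi / 4096
}

#' Per-region mean phase of one subject
#'
#' Entry `k` is the arithmetic mean (computed in floating point) of the phase
#' values of all voxels carrying atlas label `k`; background (label 0) is
#' excluded. A region with no voxels yields `NA` with a warning.
#'
#' @param volume A [phase_volume()].
#' @param atlas An [atlas_volume()] on the same voxel grid.
#' @return Named numeric vector, one mean per region in `region_table` order.
#' @export
region_mean_phase <- function(volume, atlas) {
  stopifnot(inherits(volume, "phase_volume"), inherits(atlas, "atlas_volume"))
  if (!identical(dim(volume$voxels), dim(atlas$labels)))
    stop(sprintf("volume grid %s does not match atlas grid %s",
                 paste(dim(volume$voxels), collapse = "x"),
                 paste(dim(atlas$labels), collapse = "x")))
  lab <- as.vector(atlas$labels)
  vox <- as.numeric(volume$voxels)
  keep <- lab > 0L
  means_by_label <- tapply(vox[keep], lab[keep], mean)
  ids <- atlas$region_table$region_id
  out <- setNames(as.numeric(means_by_label[as.character(ids)]), ids)
  if (anyNA(out))
    warning(sprintf("subject %s: region(s) %s have no voxels; returning NA",
                    volume$subject_id,
                    paste(ids[is.na(out)], collapse = ", ")))
  out
}

#' Build the subjects x regions iron feature matrix
#'
#' Composes [region_mean_phase()] and [phase_to_iron()] for every subject:
#' row `i`, column `k` holds \eqn{X_{ik} = -\bar b_{ik}\pi/4096}, the iron
#' content score of subject `i` in atlas region `k`.
#'
#' @param volumes List of [phase_volume()] objects sharing the atlas grid.
#' @param atlas An [atlas_volume()].
#' @param atlas_name Provenance tag stored with the matrix.
#' @return A numeric matrix of class `region_feature_matrix` with subject IDs
#'   as row names and region IDs as column names; attribute `region_names`
#'   carries the region names, `atlas_name` the provenance tag.
#' @export
build_feature_matrix <- function(volumes, atlas, atlas_name = "synthetic") {
  stopifnot(inherits(atlas, "atlas_volume"))
  rows <- lapply(volumes, region_mean_phase, atlas = atlas)
  b <- do.call(rbind, rows)
  rownames(b) <- vapply(volumes, `[[`, character(1), "subject_id")
  x <- phase_to_iron(b)
  structure(x,
            region_names = atlas$region_table$region_name,
            atlas_name = atlas_name,
            class = c("region_feature_matrix", class(x)))
}

#' @export
print.region_feature_matrix <- function(x, ...) {
  cat(sprintf("Regional iron feature matrix: %d subjects x %d regions (atlas: %s)\n",
              nrow(x), ncol(x), attr(x, "atlas_name")))
  print(head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE], 4), ...)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Write / read a feature matrix as TSV
#'
#' Rows are subjects (first column `subject_id`), remaining columns one per
#' region ID; tab-delimited with a header row.
#'
#' @param x A `region_feature_matrix` (or plain matrix with dimnames).
#' @param path Output file.
#' @return `path` (write) or a `region_feature_matrix` (read), invisibly for
#'   the writer.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(subject_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  structure(m, class = c("region_feature_matrix", class(m)))
}
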