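# Synthetic SWI cohort generation: block-tiled atlas + per-subject integer
# phase volumes with class-dependent mean shifts in designated effect regions.

PHASE_MIN <- -4096L
PHASE_MAX <- 4095L
CLASS_LEVELS <- c("NC", "MCI", "AD")

#' Specification of a synthetic SWI cohort
#'
#' Bundles the parameters of the synthetic cohort generator: class sizes,
#' volume geometry, parcellation size, which regions carry a disease effect,
#' and the per-class mean phase shifts in those regions. Defaults emulate a
#' 69-subject cohort (24 NC / 21 MCI / 24 AD) with three effect regions in a
#' 16-region parcellation.
#'
#' Phase values are raw integer SWI phase units in \[-4096, 4095\]; more
#' negative phase corresponds to higher iron content after the conversion
#' \eqn{X = -b\pi/4096}. Effect shifts are therefore negative for
#' iron-accumulating classes, growing in magnitude from NC (0) through MCI to
#' AD, mirroring progressive iron deposition.
#'
#' @param n_nc,n_mci,n_ad Number of subjects per diagnostic class.
#' @param volume_shape Integer vector of length 3: voxel grid dimensions.
#' @param n_regions Number of atlas regions `R`; regions are axis-aligned
#'   blocks tiling the volume.
#' @param effect_regions Integer region IDs (in `1..n_regions`) carrying a
#'   class-dependent mean shift.
#' @param effect_sizes Numeric matrix with one row per effect region and
#'   columns `NC`, `MCI`, `AD`: the mean phase shift (raw phase units) added
#'   to every voxel of that region for subjects of that class. Default: 0 for
#'   NC, -150 for MCI, -300 for AD in every effect region.
#' @param noise_sd Standard deviation of the additive Gaussian voxel noise,
#'   raw phase units.
#' @param seed Integer seed; one global seed derives an independent
#'   per-subject stream.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [cohort_spec_from_yaml()]
#' @export
cohort_spec <- function(n_nc = 24, n_mci = 21, n_ad = 24,
                        volume_shape = c(24, 24, 24),
                        n_regions = 16,
                        effect_regions = c(2L, 7L, 11L),
                        effect_sizes = NULL,
                        noise_sd = 200,
                        seed = 1) {
  n_nc <- as.integer(n_nc); n_mci <- as.integer(n_mci); n_ad <- as.integer(n_ad)
  if (any(c(n_nc, n_mci, n_ad) < 0) || n_nc + n_mci + n_ad <= 0)
    stop("class counts must be non-negative with total > 0")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 1))
    stop("volume_shape must be three positive integers")
  n_regions <- as.integer(n_regions)
  if (n_regions < 1) stop("n_regions must be >= 1")
  effect_regions <- as.integer(effect_regions)
  if (length(effect_regions) &&
      (any(effect_regions < 1) || any(effect_regions > n_regions)))
    stop("every effect region ID must lie in 1..n_regions")
  if (anyDuplicated(effect_regions)) stop("duplicate effect region IDs")
  if (is.null(effect_sizes)) {
    effect_sizes <- matrix(rep(c(0, -150, -300), each = length(effect_regions)),
                           nrow = length(effect_regions),
                           dimnames = list(NULL, CLASS_LEVELS))
  }
  effect_sizes <- as.matrix(effect_sizes)
  if (nrow(effect_sizes) != length(effect_regions) || ncol(effect_sizes) != 3)
    stop("effect_sizes must be a length(effect_regions) x 3 matrix (NC, MCI, AD)")
  colnames(effect_sizes) <- CLASS_LEVELS
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_nc = n_nc, n_mci = n_mci, n_ad = n_ad,
                 volume_shape = volume_shape, n_regions = n_regions,
                 effect_regions = effect_regions, effect_sizes = effect_sizes,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Read a cohort specification from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [cohort_spec()]; `effect_sizes` may be given as a list of three-element
#'   `[NC, MCI, AD]` rows.
#' @return A `cohort_spec`.
#' @export
cohort_spec_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$effect_sizes))
    y$effect_sizes <- do.call(rbind, y$effect_sizes)
  do.call(cohort_spec, y)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic SWI cohort spec: %d subjects (NC %d / MCI %d / AD %d)\n",
              x$n_nc + x$n_mci + x$n_ad, x$n_nc, x$n_mci, x$n_ad))
  cat(sprintf("  volume %s, %d regions, effect regions {%s}, noise sd %g\n",
              paste(x$volume_shape, collapse = "x"), x$n_regions,
              paste(x$effect_regions, collapse = ", "), x$noise_sd))
  invisible(x)
}

#' A single subject's phase volume
#'
#' @param voxels 3D integer array of raw phase values in \[-4096, 4095\].
#' @param subject_id Subject identifier.
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(voxels, subject_id) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  rng <- range(voxels)
  if (rng[1] < PHASE_MIN || rng[2] > PHASE_MAX)
    stop(sprintf("phase values must lie in [%d, %d]; observed [%g, %g]",
                 PHASE_MIN, PHASE_MAX, rng[1], rng[2]))
  dm <- dim(voxels)
  voxels <- as.integer(voxels)  # drops any reader-specific attributes
  dim(voxels) <- dm
  structure(list(voxels = voxels, subject_id = as.character(subject_id)),
            class = "phase_volume")
}

#' An atlas label volume with its region table
#'
#' @param labels 3D integer array of region labels; 0 is background, regions
#'   are labelled `1..R`.
#' @param region_table Data frame with columns `region_id` and `region_name`;
#'   defaults to generic names for the labels present.
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, region_table = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3) stop("labels must be a 3D array")
  dm <- dim(labels)
  labels <- as.integer(labels)  # drops any reader-specific attributes
  dim(labels) <- dm
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids > 0]
  if (is.null(region_table)) {
    region_table <- data.frame(region_id = ids,
                               region_name = sprintf("region_%02d", ids))
  }
  if (!all(c("region_id", "region_name") %in% names(region_table)))
    stop("region_table needs columns region_id, region_name")
  extra <- setdiff(ids, region_table$region_id)
  if (length(extra))
    stop("labels contain region IDs missing from region_table: ",
         paste(extra, collapse = ", "))
  structure(list(labels = labels, region_table = region_table),
            class = "atlas_volume")
}

# Nearly-cubic block grid (a,b,c) with a*b*c >= R blocks.
.block_grid <- function(n_regions) {
  a <- max(1L, as.integer(ceiling(n_regions^(1 / 3))))
  b <- max(1L, as.integer(ceiling(sqrt(n_regions / a))))
  c <- as.integer(ceiling(n_regions / (a * b)))
  c(a, b, c)
}

# Split axis length n into k nearly equal contiguous runs of labels 1..k.
.axis_bins <- function(n, k) {
  if (n < k) stop(sprintf("volume too small: axis of %d voxels cannot host %d blocks", n, k))
  rep(seq_len(k), times = diff(round(seq(0, n, length.out = k + 1))))
}

# Label array tiling the volume with axis-aligned blocks 1..R (excess blocks
# become background 0).
.tile_atlas <- function(volume_shape, n_regions) {
  g <- .block_grid(n_regions)
  bx <- .axis_bins(volume_shape[1], g[1])
  by <- .axis_bins(volume_shape[2], g[2])
  bz <- .axis_bins(volume_shape[3], g[3])
  block <- array(0L, volume_shape)
  # block index in column-major block order
  block[] <- (bx[slice.index(block, 1)] - 1L) +
    g[1] * (by[slice.index(block, 2)] - 1L) +
    g[1] * g[2] * (bz[slice.index(block, 3)] - 1L) + 1L
  block[block > n_regions] <- 0L
  block
}

#' Generate a synthetic SWI cohort
#'
#' Builds a block-tiled atlas and one integer phase volume per subject. Each
#' voxel value is the class- and region-dependent mean shift plus Gaussian
#' noise, rounded and clipped to the raw phase range \[-4096, 4095\]. One
#' global seed derives an independent per-subject noise stream, so output is
#' bit-identical across calls with the same spec.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `atlas` (an [atlas_volume()]), `volumes`
#'   (list of [phase_volume()]), and `labels` (data frame with `subject_id`
#'   and `class`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lab <- .tile_atlas(spec$volume_shape, spec$n_regions)
  atlas <- atlas_volume(lab)
  classes <- rep(CLASS_LEVELS, times = c(spec$n_nc, spec$n_mci, spec$n_ad))
  n <- length(classes)
  subject_ids <- sprintf("sub-%03d", seq_len(n))

  # per-class mean shift map (shared across subjects of a class)
  shift_maps <- lapply(CLASS_LEVELS, function(cl) {
    m <- array(0, spec$volume_shape)
    for (i in seq_along(spec$effect_regions))
      m[lab == spec$effect_regions[i]] <- spec$effect_sizes[i, cl]
    m
  })
  names(shift_maps) <- CLASS_LEVELS

  set.seed(spec$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_clipped <- 0L
  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    v <- shift_maps[[classes[i]]]
    if (spec$noise_sd > 0)
      v <- v + rnorm(length(v), sd = spec$noise_sd)
    v <- round(v)
    clip <- v < PHASE_MIN | v > PHASE_MAX
    n_clipped <- n_clipped + sum(clip)
    v[v < PHASE_MIN] <- PHASE_MIN
    v[v > PHASE_MAX] <- PHASE_MAX
    dim(v) <- spec$volume_shape
    volumes[[i]] <- phase_volume(v, subject_ids[i])
  }
  if (n_clipped > 0)
    message(sprintf("generate_cohort: clipped %d voxel(s) to the phase range", n_clipped))
  list(atlas = atlas, volumes = volumes,
       labels = data.frame(subject_id = subject_ids,
                           class = factor(classes, levels = CLASS_LEVELS)))
}

#' Write a cohort to disk (NIfTI volumes + TSV label table)
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(cohort$atlas$labels, atlas_path)
  region_path <- file.path(dir, "regions.tsv")
  write_tsv(cohort$atlas$region_table, region_path)
  phase_paths <- vapply(cohort$volumes, function(v) {
    p <- file.path(dir, paste0(v$subject_id, "_phase.nii.gz"))
    RNifti::writeNifti(v$voxels, p)
    p
  }, character(1))
  labels_path <- file.path(dir, "labels.tsv")
  write_tsv(cohort$labels, labels_path)
  invisible(list(atlas = atlas_path, regions = region_path,
                 volumes = phase_paths, labels = labels_path))
}

#' Read a phase volume from a NIfTI file
#'
#' @param path NIfTI file with integer phase data.
#' @param subject_id Optional subject identifier; defaults to the file name
#'   stripped of extensions.
#' @return A [phase_volume()].
#' @export
read_phase_volume <- function(path, subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("(_phase)?\\.nii(\\.gz)?$", "", basename(path))
  v <- RNifti::readNifti(path)
  phase_volume(round(as.array(v)), subject_id)
}

#' Read an atlas from a NIfTI label file
#'
#' @param path NIfTI file with integer labels (0 = background).
#' @param region_table Optional region table (see [atlas_volume()]), or a
#'   path to a TSV with columns `region_id` and `region_name`.
#' @return An [atlas_volume()].
#' @export
read_atlas <- function(path, region_table = NULL) {
  if (is.character(region_table) && length(region_table) == 1)
    region_table <- read.delim(region_table, sep = "\t")
  lab <- round(as.array(RNifti::readNifti(path)))
  atlas_volume(lab, region_table)
}

# tab-delimited with header, UTF-8, no quoting; byte-stable
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df)) {
    rows <- do.call(paste, c(lapply(df, function(col) {
      s <- as.character(col)
      s[is.na(col)] <- ""
      s
    }), sep = "\t"))
    writeLines(enc2utf8(rows), con, useBytes = TRUE)
  }
  invisible(path)
}
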