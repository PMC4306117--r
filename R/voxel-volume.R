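#' Voxel volume container
#'
#' A 3D grey-value grid with isotropic voxel spacing, the working data model
#' for reconstructed micro-CT scans.  Grey values are conventionally on a
#' 16-bit scale (0--65535) for raw reconstructions; a calibrated volume
#' (e.g. rescaled towards Hounsfield-like units) may hold arbitrary numeric
#' values.
#'
#' @param grid 3D numeric or integer array of grey values.
#' @param voxel_size Isotropic voxel edge length in micrometres (µm).
#'   The study scans this package models were reconstructed at 15.5 µm.
#' @return An object of class `voxel_volume`: a list with elements `grid`
#'   and `voxel_size` (µm).
#' @examples
#' v <- voxel_volume(array(100L, c(4, 4, 4)), voxel_size = 15.5)
#' dim(v$grid)
#' @export
voxel_volume <- function(grid, voxel_size = 15.5) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array")
  if (length(grid) == 0L) stop("`grid` must be non-empty")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (µm)")
  if (anyNA(grid)) stop("`grid` contains missing values")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %.3g µm (%.3g mm³ field of view)\n",
              d[1], d[2], d[3], x$voxel_size,
              prod(d) * (x$voxel_size / 1000)^3))
  cat(sprintf("  grey values: [%.4g, %.4g]\n",
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Grey-value threshold configuration
#'
#' Fixed threshold bands separating background, plaque tissue and
#' calcification in a reconstructed 16-bit volume.  Defaults follow the
#' fixed bands used for density-calibrated carotid plaque scans: tissue
#' 324--1249 GV and calcification at or above 1250 GV.  A grey value of
#' exactly 1250 is assigned to calcification so that the tissue and
#' calcification bands are contiguous.
#'
#' @param tissue_low,tissue_high Inclusive grey-value band for plaque tissue.
#' @param calc_low Lowest grey value counted as calcification
#'   (rule: `GV >= calc_low`).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(tissue_low = 324, tissue_high = 1249,
                             calc_low = 1250) {
  stopifnot(is.numeric(tissue_low), is.numeric(tissue_high), is.numeric(calc_low))
  if (!(tissue_low < tissue_high))
    stop("tissue_low must be < tissue_high")
  if (!(calc_low > tissue_high))
    stop("calc_low must be > tissue_high")
  structure(list(tissue_low = tissue_low, tissue_high = tissue_high,
                 calc_low = calc_low),
            class = "threshold_config")
}

#' Linear grey-value calibration from reference materials
#'
#' Rescales a volume by the least-squares linear map from measured grey
#' values of reference materials (e.g. air, water, hydroxyapatite phantom)
#' to their target values on the calibrated scale.  With exactly two
#' distinct reference points the map interpolates both exactly; with more,
#' it is the ordinary least-squares line.
#'
#' @param volume A [voxel_volume()].
#' @param reference_points Data frame with columns `material`, `measured`
#'   (grey value in the volume) and `target` (value on the calibrated
#'   scale), at least two rows with distinct `measured` values.
#' @return A [voxel_volume()] on the calibrated scale (numeric grid; not
#'   clipped to 16-bit).  The fitted intercept/slope and residuals are
#'   attached as attribute `"calibration"`.
#' @examples
#' v <- voxel_volume(array(c(100, 600, 600, 1100), c(2, 2, 1)))
#' refs <- data.frame(material = c("air", "water"),
#'                    measured = c(100, 600), target = c(-1000, 0))
#' calibrate_grey_values(v, refs)$grid[2, 1, 1]  # water voxel -> 0
#' @export
calibrate_grey_values <- function(volume, reference_points) {
  stopifnot(inherits(volume, "voxel_volume"))
  rp <- as.data.frame(reference_points)
  if (!all(c("measured", "target") %in% names(rp)))
    stop("reference_points needs `measured` and `target` columns")
  if (nrow(rp) < 2L)
    stop("at least two reference points are required")
  if (anyDuplicated(rp$measured))
    stop("duplicate measured grey values make the linear fit singular")
  fit <- lm(target ~ measured, data = rp)
  cf <- coef(fit)
  grid <- cf[[1]] + cf[[2]] * as.numeric(volume$grid)
  dim(grid) <- dim(volume$grid)
  out <- voxel_volume(grid, volume$voxel_size)
  attr(out, "calibration") <- list(intercept = unname(cf[[1]]),
                                   slope = unname(cf[[2]]),
                                   residuals = unname(stats::residuals(fit)))
  out
}

#' Segment a volume into tissue and calcification masks
#'
#' Applies the fixed threshold bands of a [threshold_config()]: plaque
#' tissue is `tissue_low <= GV <= tissue_high`, calcification is
#' `GV >= calc_low`.  Voxels below `tissue_low` are background and belong
#' to neither mask; the two masks are disjoint by construction.
#'
#' @param volume A [voxel_volume()].
#' @param thresholds A [threshold_config()].
#' @return List with logical 3D arrays `tissue` and `calc`.
#' @export
segment_volume <- function(volume, thresholds = threshold_config()) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(thresholds, "threshold_config"))
  g <- volume$grid
  tissue <- g >= thresholds$tissue_low & g <= thresholds$tissue_high
  calc <- g >= thresholds$calc_low
  list(tissue = tissue, calc = calc)
}

#' Label connected components of a binary mask
#'
#' Partitions the foreground of a 3D binary mask into maximal connected
#' components.  The default 26-neighbour connectivity treats voxels sharing
#' a face, edge or corner as connected (the inclusive convention for
#' agglomerated calcification); 6-neighbour (faces only) and 18-neighbour
#' conventions are available.  Component labels 1..K are assigned in scan
#' order of each component's first voxel, so labelling is deterministic.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer 3D array of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  mask <- mask != 0
  lab <- .cc_label_3d(as.logical(mask), as.integer(dim(mask)),
                      as.integer(connectivity))
  dim(lab) <- dim(mask)
  lab
}
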