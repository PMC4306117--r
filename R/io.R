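#' Write and read a voxel volume as a TIFF slice series
#'
#' `write_volume_tiff()` stores one 16-bit TIFF per z slice
#' (`slice_0001.tif`, ...) plus a `volume.json` sidecar holding the voxel
#' size (µm) and grid shape.  `read_volume_tiff()` reverses it.
#'
#' @param volume A [voxel_volume()] with grey values in 0--65535.
#' @param dir Directory for the series (created if needed).
#' @param prefix Slice file-name prefix.
#' @return `write_volume_tiff()`: the directory, invisibly.
#'   `read_volume_tiff()`: a [voxel_volume()].
#' @export
write_volume_tiff <- function(volume, dir, prefix = "slice") {
  stopifnot(inherits(volume, "voxel_volume"))
  g <- volume$grid
  if (min(g) < 0 || max(g) > 65535)
    stop("grey values outside the 16-bit range; calibrated volumes cannot be written as TIFF")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nz <- dim(g)[3]
  for (k in seq_len(nz)) {
    tiff::writeTIFF(g[, , k] / 65535,
                    file.path(dir, sprintf("%s_%04d.tif", prefix, k)),
                    bits.per.sample = 16L, compression = "none")
  }
  jsonlite::write_json(list(voxel_size_um = volume$voxel_size,
                            grid_shape = dim(g), n_slices = nz,
                            prefix = prefix),
                       file.path(dir, "volume.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "volume.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = sprintf("^%s_\\d+\\.tif$", meta$prefix),
                           full.names = TRUE))
  if (length(files) != meta$n_slices)
    stop("slice count does not match the sidecar metadata")
  slices <- lapply(files, function(f) round(tiff::readTIFF(f) * 65535))
  g <- array(0L, meta$grid_shape)
  for (k in seq_along(slices)) g[, , k] <- as.integer(slices[[k]])
  voxel_volume(g, meta$voxel_size_um)
}

#' Write and read a spectrum as two-column text
#'
#' Plain whitespace-separated text with a one-line header,
#' `wavenumber_cm-1 absorbance`, rows in the spectrum's grid order
#' (conventionally descending wavenumber).
#'
#' @param spectrum An [ftir_spectrum()].
#' @param path File path.
#' @return `read_spectrum()`: an [ftir_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  utils::write.table(data.frame(`wavenumber_cm-1` = spectrum$wavenumber,
                                absorbance = spectrum$absorbance,
                                check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  tb <- utils::read.table(path, header = TRUE, check.names = FALSE)
  ftir_spectrum(tb[[1]], tb[[2]])
}

#' Write and read a uniaxial test record as CSV
#'
#' Two-column CSV (`displacement_mm`, `force_N`) preceded by comment
#' header lines carrying the gauge length and reference cross-section:
#' `# gauge_length_mm: 10` and `# cross_section_mm2: 10`.
#'
#' @param record A [test_record()].
#' @param path File path.
#' @return `read_mech_record()`: a [test_record()].
#' @export
write_mech_record <- function(record, path) {
  stopifnot(inherits(record, "test_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# gauge_length_mm: %.10g", record$gauge_length),
               sprintf("# cross_section_mm2: %.10g", record$cross_section)),
             con)
  utils::write.table(data.frame(displacement_mm = record$displacement,
                                force_N = record$force),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mech_record
#' @export
read_mech_record <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  grab <- function(key) {
    ln <- grep(key, hdr, value = TRUE, fixed = TRUE)
    if (length(ln) != 1L) stop(sprintf("header line '%s' missing", key))
    as.numeric(sub(".*:", "", ln))
  }
  tb <- read.csv(path, comment.char = "#")
  test_record(tb$displacement_mm, tb$force_N,
              gauge_length = grab("gauge_length_mm"),
              cross_section = grab("cross_section_mm2"))
}
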