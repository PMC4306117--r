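#' Packaged per-specimen study tables
#'
#' Loads the per-specimen summary tables packaged with the study this
#' package models: `load_table1()` returns the joined
#' mechanical/biochemical/structural record (initial stiffness, peak
#' Cauchy stress and stretch, Calc:Col and Lip:Col ratios, calcification
#' volume fraction, total calcification surface area), `load_table2()` the
#' structural census (CVF plus counts of spherical, sheet and irregular
#' inclusions).  In the census, `-` means the geometry was absent from the
#' section and is read as `NA`; counting helpers treat it as 0.
#'
#' @param path Optional path to an equivalent CSV; defaults to the
#'   packaged fixture.
#' @return A data frame, one row per specimen.
#' @export
load_table1 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1.csv", package = "plaquemorph",
                        mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname load_table1
#' @export
load_table2 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table2.csv", package = "plaquemorph",
                        mustWork = TRUE)
  tb <- read.csv(path, stringsAsFactors = FALSE, na.strings = "-")
  for (cl in c("spherical", "sheet", "irregular"))
    tb[[cl]] <- as.integer(tb[[cl]])
  tb
}

#' Per-group mean and standard deviation of a field
#'
#' Summarises one numeric column of a specimen table by stiffness group.
#' The standard deviation is the sample SD (n - 1 denominator); groups of
#' size 1 report SD 0 and are flagged.
#'
#' @param table Data frame with a `group` column.
#' @param field Name of the numeric column to summarise.
#' @return Data frame with columns `group`, `mean`, `sd`, `n`,
#'   `sd_flagged`; empty groups are omitted.
#' @export
group_summary <- function(table, field) {
  stopifnot("group" %in% names(table), field %in% names(table))
  groups <- intersect(c("LS", "MS", "HS"), unique(table$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- table[[field]][table$group == g]
    data.frame(group = g, mean = mean(x),
               sd = if (length(x) > 1) sd(x) else 0,
               n = length(x), sd_flagged = length(x) == 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Overall peak-strength summary
#'
#' Mean and sample SD of peak Cauchy stress and stretch at peak over all
#' specimens.
#'
#' @param table Data frame with columns `cauchy_stress_mpa` and
#'   `stretch_ratio`.
#' @return List with elements `peak_stress` and `stretch_at_peak`, each
#'   `c(mean, sd)`.
#' @export
overall_strength_summary <- function(table) {
  stopifnot(all(c("cauchy_stress_mpa", "stretch_ratio") %in% names(table)))
  if (nrow(table) < 2L) stop("at least two specimens are required")
  list(peak_stress = c(mean = mean(table$cauchy_stress_mpa),
                       sd = sd(table$cauchy_stress_mpa)),
       stretch_at_peak = c(mean = mean(table$stretch_ratio),
                           sd = sd(table$stretch_ratio)))
}

#' Total inclusion counts per geometry class
#'
#' Column sums of the structural census; missing entries (absent
#' geometry, printed `-` in the source table) count as 0.
#'
#' @param table Data frame with columns `spherical`, `sheet`,
#'   `irregular`.
#' @return Named integer vector of totals.
#' @export
count_totals <- function(table) {
  cols <- c("spherical", "sheet", "irregular")
  stopifnot(all(cols %in% names(table)))
  vals <- table[cols]
  if (any(vals < 0, na.rm = TRUE)) stop("inclusion counts must be non-negative")
  vapply(vals, function(x) as.integer(sum(x, na.rm = TRUE)),
         integer(1))
}

#' Order statistics of the calcification volume fraction
#'
#' The largest and second-largest CVF across specimens, with their
#' specimen ids.  Ties are ordered stably by specimen id.
#'
#' @param table Data frame with columns `specimen` and `cvf`.
#' @return List with `max`, `second` (each a list of `cvf`, `specimen`)
#'   and the full `sorted` table.
#' @export
cvf_order_statistics <- function(table) {
  stopifnot(all(c("specimen", "cvf") %in% names(table)))
  if (nrow(table) < 2L) stop("at least two specimens are required")
  o <- order(-table$cvf, table$specimen)
  srt <- table[o, c("specimen", "cvf")]
  rownames(srt) <- NULL
  list(max = list(cvf = srt$cvf[1], specimen = srt$specimen[1]),
       second = list(cvf = srt$cvf[2], specimen = srt$specimen[2]),
       sorted = srt)
}

#' EDX elemental reading
#'
#' Calcium and phosphorus abundances from energy-dispersive X-ray
#' analysis of a calcified region, with the Ca:P ratio computed on the
#' molar scale.  Mass-percent inputs are converted with molar masses
#' Ca 40.078 and P 30.974 g/mol.
#'
#' @param region_id Identifier of the analysed region.
#' @param ca,p Calcium and phosphorus abundances, both positive.
#' @param basis `"molar"` (default) or `"mass"`.
#' @return List of class `edx_reading` with `ca_p_ratio` on the molar
#'   scale.
#' @export
edx_reading <- function(region_id, ca, p, basis = c("molar", "mass")) {
  basis <- match.arg(basis)
  if (ca <= 0 || p <= 0) stop("abundances must be positive")
  if (basis == "mass") {
    ca <- ca / 40.078
    p <- p / 30.974
  }
  structure(list(region_id = region_id, ca = ca, p = p,
                 ca_p_ratio = ca / p, basis = basis),
            class = "edx_reading")
}

#' Hydroxyapatite stoichiometry check
#'
#' Tests whether a region's molar Ca:P ratio is consistent with
#' hydroxyapatite, Ca₁₀(PO₄)₆(OH)₂, whose stoichiometric molar ratio is
#' 10/6 ≈ 1.67.  The check passes when the measured ratio is at least the
#' threshold, within a small rounding tolerance so that a ratio
#' equivalent to the printed two-decimal 1.67 (such as the exact 5/3)
#' passes.
#'
#' @param reading An [edx_reading()] (molar basis).
#' @param threshold Minimum molar Ca:P ratio (default 1.67).
#' @param tol Rounding tolerance on the comparison (default 0.005).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
hydroxyapatite_check <- function(reading, threshold = 1.67, tol = 0.005) {
  stopifnot(inherits(reading, "edx_reading"))
  reading$ca_p_ratio >= threshold - tol
}

#' Join per-modality results into one specimen table
#'
#' Merges mechanical, biochemical and structural per-specimen data frames
#' by `specimen`, recomputing the stiffness group from the stiffness
#' column so that group labels are always consistent with
#' [assign_group()].
#'
#' @param mech Data frame with `specimen`, `initial_stiffness_mpa`,
#'   `cauchy_stress_mpa`, `stretch_ratio`.
#' @param ftir Data frame with `specimen`, `calc_col`, `lip_col`.
#' @param morpho Data frame with `specimen`, `cvf`, and optionally
#'   `surface_area_mm2`, `spherical`, `sheet`, `irregular`.
#' @param breakpoints Stiffness-group breakpoints, see [assign_group()].
#' @return Data frame, one row per specimen, ordered by initial
#'   stiffness.
#' @export
specimen_table <- function(mech, ftir, morpho, breakpoints = c(1, 2)) {
  out <- merge(merge(mech, ftir, by = "specimen"), morpho, by = "specimen")
  out$group <- assign_group(out$initial_stiffness_mpa, breakpoints)
  out <- out[order(out$initial_stiffness_mpa, out$specimen), ]
  rownames(out) <- NULL
  out[c("specimen", "group",
        setdiff(names(out), c("specimen", "group")))]
}
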