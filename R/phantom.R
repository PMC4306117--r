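#' Inclusion primitives for voxel phantoms
#'
#' Constructors for the three calcification geometries embedded in
#' synthetic micro-CT phantoms.  All coordinates and sizes are in µm,
#' measured in the phantom's physical frame (origin at the corner of the
#' grid, voxel centres at `(i - 0.5) * voxel_size`).
#'
#' * `inclusion_sphere()` — a ball given by centre and diameter.
#' * `inclusion_sheet()` — an oriented slab (box) with side lengths
#'   `l > w > t` (strict) and a 3x3 rotation matrix orientation.
#' * `inclusion_irregular()` — an agglomerated macro-node: the union of
#'   overlapping spheres; the sphere intersection graph must be connected
#'   so the union forms a single component.
#'
#' @param label Unique identifier (character or integer).
#' @param centre Numeric length-3, µm.
#' @param diameter Sphere diameter, µm.
#' @param size Numeric length-3 `c(l, w, t)` for sheets, µm, strictly
#'   decreasing.
#' @param orientation 3x3 rotation matrix (columns = the slab's l/w/t
#'   axes in the phantom frame).
#' @param centres m-by-3 matrix of sphere centres for agglomerates, µm.
#' @param diameters Length-m sphere diameters for agglomerates, µm.
#' @return A list of class `inclusion_spec`.
#' @name inclusion_spec
NULL

#' @rdname inclusion_spec
#' @export
inclusion_sphere <- function(label, centre, diameter) {
  stopifnot(length(centre) == 3, diameter > 0)
  structure(list(kind = "sphere", label = label,
                 centre = as.numeric(centre), diameter = diameter),
            class = "inclusion_spec")
}

#' @rdname inclusion_spec
#' @export
inclusion_sheet <- function(label, centre, size, orientation = diag(3)) {
  stopifnot(length(centre) == 3, length(size) == 3)
  if (!(size[1] > size[2] && size[2] > size[3]))
    stop("sheet sizes must satisfy l > w > t strictly")
  if (!is.matrix(orientation) || any(dim(orientation) != c(3, 3)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation must be a 3x3 rotation matrix")
  structure(list(kind = "sheet", label = label, centre = as.numeric(centre),
                 size = as.numeric(size), orientation = orientation),
            class = "inclusion_spec")
}

#' @rdname inclusion_spec
#' @export
inclusion_irregular <- function(label, centres, diameters) {
  centres <- as.matrix(centres)
  stopifnot(ncol(centres) == 3, nrow(centres) == length(diameters),
            all(diameters > 0))
  if (nrow(centres) >= 2) {
    # union must be connected: check the sphere intersection graph
    m <- nrow(centres)
    adj <- as.matrix(stats::dist(centres)) <
      outer(diameters / 2, diameters / 2, "+")
    reach <- logical(m); reach[1] <- TRUE
    repeat {
      new <- reach | apply(adj[, reach, drop = FALSE], 1, any)
      if (all(new == reach)) break
      reach <- new
    }
    if (!all(reach))
      stop("irregular inclusion spheres do not form a connected union")
  }
  structure(list(kind = "irregular", label = label, centres = centres,
                 diameters = as.numeric(diameters)),
            class = "inclusion_spec")
}

#' Tissue-region descriptions for phantoms
#'
#' The plaque body occupied by tissue inside the phantom.
#' `tissue_cylinder()` is a circular cylinder along the z axis spanning the
#' full grid depth; `tissue_box()` is an axis-aligned box leaving a
#' fractional margin on every side.
#'
#' @param radius_frac Cylinder radius as a fraction of the smaller x/y
#'   half-extent (default 0.9, i.e. 0.45 of the grid width).
#' @param margin_frac Box margin as a fraction of each grid dimension.
#' @return A list of class `tissue_region`.
#' @export
tissue_cylinder <- function(radius_frac = 0.9) {
  stopifnot(radius_frac > 0, radius_frac <= 1)
  structure(list(type = "cylinder", radius_frac = radius_frac),
            class = "tissue_region")
}

#' @rdname tissue_cylinder
#' @export
tissue_box <- function(margin_frac = 0.1) {
  stopifnot(margin_frac >= 0, margin_frac < 0.5)
  structure(list(type = "box", margin_frac = margin_frac),
            class = "tissue_region")
}

#' Phantom specification
#'
#' Complete description of a synthetic micro-CT phantom: grid geometry,
#' tissue region, calcification inclusions, per-class grey-level means,
#' additive Gaussian noise and RNG seed.  Defaults emulate the
#' reconstructed 16-bit scans the package targets: 15.5 µm isotropic
#' voxels, background well below the tissue band (mean 100 GV), plaque
#' tissue inside 324--1249 GV (mean 700), calcification above 1250 GV
#' (mean 1800), and 30 GV noise.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size Isotropic voxel size, µm.
#' @param tissue_region A [tissue_cylinder()] or [tissue_box()].
#' @param inclusions List of [inclusion_spec] objects with unique labels.
#' @param grey_levels Named means `c(background, tissue, calcification)`,
#'   strictly increasing, with tissue inside the default threshold band.
#' @param noise_sd Gaussian grey-value noise SD.
#' @param seed Integer RNG seed; a fixed seed makes the generated volume
#'   bit-identical across runs.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(200, 200, 200), voxel_size = 15.5,
                         tissue_region = tissue_cylinder(),
                         inclusions = list(),
                         grey_levels = c(background = 100, tissue = 700,
                                         calcification = 1800),
                         noise_sd = 30, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_size > 0,
            inherits(tissue_region, "tissue_region"), noise_sd >= 0)
  gl <- grey_levels
  if (!(gl[["background"]] < gl[["tissue"]] &&
        gl[["tissue"]] < gl[["calcification"]]))
    stop("grey-level means must be strictly ordered background < tissue < calcification")
  labs <- vapply(inclusions, function(x) as.character(x$label), character(1))
  if (anyDuplicated(labs)) stop("inclusion labels must be unique")
  for (inc in inclusions) {
    if (inc$kind == "sphere" && inc$diameter <= 2 * voxel_size)
      stop(sprintf("inclusion '%s': sphere diameter must exceed 2 voxels to be resolvable",
                   inc$label))
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 tissue_region = tissue_region, inclusions = inclusions,
                 grey_levels = gl, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# logical x/y (or full) membership of the tissue region at voxel centres
.tissue_mask <- function(region, dims, h) {
  x <- (seq_len(dims[1]) - 0.5) * h
  y <- (seq_len(dims[2]) - 0.5) * h
  z <- (seq_len(dims[3]) - 0.5) * h
  if (region$type == "cylinder") {
    cx <- dims[1] * h / 2; cy <- dims[2] * h / 2
    r <- region$radius_frac * min(dims[1], dims[2]) * h / 2
    disc <- outer((x - cx)^2, (y - cy)^2, "+") <= r^2
    array(disc, dims)  # replicated along z
  } else {
    mx <- region$margin_frac
    inx <- x >= mx * dims[1] * h & x <= (1 - mx) * dims[1] * h
    iny <- y >= mx * dims[2] * h & y <= (1 - mx) * dims[2] * h
    inz <- z >= mx * dims[3] * h & z <= (1 - mx) * dims[3] * h
    outer(outer(inx, iny, "&"), inz, "&")
  }
}

# voxel indices (n x 3) whose centres lie inside an inclusion primitive;
# `grow` inflates every primitive surface outward by `grow` µm (used for
# clearance checks during random placement)
.rasterise_inclusion <- function(inc, dims, h, grow = 0) {
  centre_box <- function(lo, hi) {
    i0 <- pmax(1L, floor(lo / h - 0.5) + 1L)
    i1 <- pmin(dims, ceiling(hi / h + 0.5))
    if (any(i1 < i0)) return(NULL)
    list(i0 = i0, i1 = i1)
  }
  collect_sphere <- function(ctr, r) {
    bb <- centre_box(ctr - r, ctr + r)
    if (is.null(bb)) return(matrix(numeric(0), 0, 3))
    ii <- bb$i0[1]:bb$i1[1]; jj <- bb$i0[2]:bb$i1[2]; kk <- bb$i0[3]:bb$i1[3]
    dx2 <- ((ii - 0.5) * h - ctr[1])^2
    dy2 <- ((jj - 0.5) * h - ctr[2])^2
    dz2 <- ((kk - 0.5) * h - ctr[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    w <- which(d2 <= r^2, arr.ind = TRUE)
    if (nrow(w) == 0) return(matrix(numeric(0), 0, 3))
    cbind(ii[w[, 1]], jj[w[, 2]], kk[w[, 3]])
  }
  if (inc$kind == "sphere") {
    return(collect_sphere(inc$centre, inc$diameter / 2 + grow))
  }
  if (inc$kind == "irregular") {
    parts <- lapply(seq_along(inc$diameters), function(m)
      collect_sphere(inc$centres[m, ], inc$diameters[m] / 2 + grow))
    co <- do.call(rbind, parts)
    return(unique(co))
  }
  # sheet: oriented box
  half <- inc$size / 2 + grow
  R <- inc$orientation
  ext <- abs(R) %*% half  # axis-aligned half extents of the rotated box
  bb <- centre_box(inc$centre - ext, inc$centre + ext)
  if (is.null(bb)) return(matrix(numeric(0), 0, 3))
  ii <- bb$i0[1]:bb$i1[1]; jj <- bb$i0[2]:bb$i1[2]; kk <- bb$i0[3]:bb$i1[3]
  g <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  p <- sweep(g - 0.5, 2, inc$centre / h) * h  # physical offsets from centre
  q <- abs(p %*% R)                           # into the slab frame
  keep <- q[, 1] <= half[1] & q[, 2] <= half[2] & q[, 3] <= half[3]
  g[keep, , drop = FALSE]
}

# analytic truth (volume mm3, area mm2) for one inclusion; agglomerate
# unions have no closed form, their truth is the voxelised volume (NA area)
.inclusion_truth <- function(inc, voxel_count, h) {
  um3_to_mm3 <- 1e-9
  um2_to_mm2 <- 1e-6
  if (inc$kind == "sphere") {
    r <- inc$diameter / 2
    c(vol = 4 / 3 * pi * r^3 * um3_to_mm3, area = 4 * pi * r^2 * um2_to_mm2)
  } else if (inc$kind == "sheet") {
    s <- inc$size
    c(vol = prod(s) * um3_to_mm3,
      area = 2 * (s[1] * s[2] + s[1] * s[3] + s[2] * s[3]) * um2_to_mm2)
  } else {
    c(vol = voxel_count * (h / 1000)^3, area = NA_real_)
  }
}

.inclusion_centre <- function(inc) {
  if (inc$kind == "irregular") colMeans(inc$centres) else inc$centre
}

#' Generate a voxel phantom with ground truth
#'
#' Builds a grey-value volume from a [phantom_spec()]: the tissue region is
#' filled with the tissue grey level, every inclusion is rasterised at
#' voxel centres with the calcification grey level, Gaussian noise is
#' added, and values are rounded and clipped to the 16-bit range.  Returns
#' both the volume and a ground-truth table (one row per inclusion with
#' its analytic volume/area and voxel count) plus true per-class voxel
#' counts, from which the true calcification volume fraction follows.
#'
#' Inclusions must lie wholly inside the tissue region and must not
#' overlap one another (overlap would make the per-inclusion ground truth
#' ambiguous); violations raise an error naming the offending label.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: list with `volume` (a
#'   [voxel_volume()]), `ground_truth` (data frame), `class_counts`
#'   (background/tissue/calcification voxel counts) and `cvf_true`.
#' @export
generate_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  h <- spec$voxel_size
  tissue <- .tissue_mask(spec$tissue_region, dims, h)

  lab <- array(0L, dims)
  gt <- vector("list", length(spec$inclusions))
  for (m in seq_along(spec$inclusions)) {
    inc <- spec$inclusions[[m]]
    co <- .rasterise_inclusion(inc, dims, h)
    if (nrow(co) == 0)
      stop(sprintf("inclusion '%s' rasterises to no voxels", inc$label))
    if (!all(tissue[co]))
      stop(sprintf("inclusion '%s' extends outside the tissue region", inc$label))
    prev <- lab[co]
    if (any(prev != 0L))
      stop(sprintf("inclusion '%s' overlaps inclusion '%s': ground truth would be ambiguous",
                   inc$label,
                   spec$inclusions[[prev[prev != 0L][1]]]$label))
    lab[co] <- m
    truth <- .inclusion_truth(inc, nrow(co), h)
    ctr <- .inclusion_centre(inc)
    gt[[m]] <- data.frame(label = as.character(inc$label), kind = inc$kind,
                          centre_x_um = ctr[1], centre_y_um = ctr[2],
                          centre_z_um = ctr[3],
                          true_volume_mm3 = truth[["vol"]],
                          true_area_mm2 = truth[["area"]],
                          voxel_count = nrow(co))
  }
  gt <- if (length(gt)) do.call(rbind, gt) else
    data.frame(label = character(), kind = character(), centre_x_um = numeric(),
               centre_y_um = numeric(), centre_z_um = numeric(),
               true_volume_mm3 = numeric(), true_area_mm2 = numeric(),
               voxel_count = integer())
  rownames(gt) <- NULL
  gt$true_equivalent_diameter_um <-
    if (nrow(gt)) equivalent_diameter(gt$true_volume_mm3) else numeric()

  cls <- array(0L, dims)          # 0 background, 1 tissue, 2 calcification
  cls[tissue] <- 1L
  cls[lab > 0L] <- 2L
  means <- spec$grey_levels[c("background", "tissue", "calcification")]

  set.seed(spec$seed)
  g <- means[cls + 1L]
  if (spec$noise_sd > 0)
    g <- g + rnorm(length(g), sd = spec$noise_sd)
  g <- round(g)
  g[g < 0] <- 0; g[g > 65535] <- 65535
  g <- as.integer(g)
  dim(g) <- dims

  n_tis <- sum(cls == 1L); n_cal <- sum(cls == 2L)
  structure(list(volume = voxel_volume(g, h),
                 ground_truth = gt,
                 class_counts = c(background = sum(cls == 0L),
                                  tissue = n_tis, calcification = n_cal),
                 cvf_true = if (n_tis + n_cal > 0) n_cal / (n_tis + n_cal) else NA_real_),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d inclusion(s); true CVF %.4g\n",
              nrow(x$ground_truth), x$cvf_true))
  print(x$volume)
  invisible(x)
}

# rotation about z by `a`, then about x by `b` (radians)
.rotation_zx <- function(a, b) {
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  rz %*% rx
}

# compact agglomerated macro-node: central sphere plus four satellites on
# randomly rotated tetrahedral directions, deeply overlapping
.agglomerate_at <- function(label, centre, core_diameter = 360) {
  R0 <- core_diameter / 2
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  rot <- .rotation_zx(runif(1, 0, 2 * pi), runif(1, 0, pi / 2))
  sat <- sweep(dirs %*% t(rot) * R0, 2, centre, "+")
  inclusion_irregular(label,
                      centres = rbind(centre, sat),
                      diameters = c(core_diameter, rep(0.72 * core_diameter, 4)))
}

#' Randomised study phantom
#'
#' Places a configurable census of non-overlapping inclusions (spheres,
#' thin sheets and agglomerated macro-nodes) at random positions inside a
#' cylindrical tissue region, and returns the corresponding
#' [phantom_spec()].  Geometry defaults keep every inclusion at least 20%
#' away from the classification decision boundaries: sphere diameters
#' 100--250 µm (limit 300 µm), sheets 1600 x 640 x 96 µm (aspect steps 2.5
#' and 6.7 against the limit 2), and compact macro-nodes with equivalent
#' diameter well above 300 µm.  A clearance of two voxels between
#' inclusion surfaces guarantees that distinct inclusions stay distinct
#' components at 26-connectivity.
#'
#' @param n_spheres,n_sheets,n_irregular Number of inclusions per class.
#' @param grid_shape,voxel_size,noise_sd,seed Passed to [phantom_spec()].
#' @param sphere_diameter_range Diameter range (µm) for spherical
#'   inclusions.
#' @param sheet_size Sheet `c(l, w, t)` in µm.
#' @param max_tries Placement attempts per inclusion before giving up.
#' @return A [phantom_spec()].
#' @export
study_phantom_spec <- function(n_spheres = 16, n_sheets = 2, n_irregular = 2,
                               grid_shape = c(200, 200, 200), voxel_size = 15.5,
                               noise_sd = 30, seed = 1L,
                               sphere_diameter_range = c(100, 250),
                               sheet_size = c(1600, 640, 96),
                               max_tries = 4000) {
  set.seed(seed)
  dims <- as.integer(grid_shape)
  h <- voxel_size
  region <- tissue_cylinder()
  tissue <- .tissue_mask(region, dims, h)
  occupied <- array(FALSE, dims)
  clearance <- 2 * h
  incs <- list()
  ext <- dims * h

  try_place <- function(make_inc) {
    for (t in seq_len(max_tries)) {
      inc <- make_inc()
      grown <- .rasterise_inclusion(inc, dims, h, grow = clearance)
      if (nrow(grown) == 0) next
      if (!all(tissue[grown])) next       # keep clearance inside tissue too
      if (any(occupied[grown])) next
      actual <- .rasterise_inclusion(inc, dims, h)
      occupied[actual] <<- TRUE
      return(inc)
    }
    stop("could not place an inclusion: region too crowded")
  }
  rand_centre <- function(margin) {
    # uniform in the cylinder cross-section, margin µm inside the boundary
    r_max <- region$radius_frac * min(dims[1], dims[2]) * h / 2 - margin
    repeat {
      xy <- runif(2, -r_max, r_max)
      if (sum(xy^2) <= r_max^2) break
    }
    c(ext[1] / 2 + xy[1], ext[2] / 2 + xy[2],
      runif(1, margin, ext[3] - margin))
  }

  for (s in seq_len(n_sheets)) {
    incs[[length(incs) + 1]] <- try_place(function() {
      rot <- .rotation_zx(runif(1, 0, 2 * pi), runif(1, -pi / 12, pi / 12))
      bound <- sqrt(sum((sheet_size / 2)^2)) + clearance + h
      inclusion_sheet(sprintf("sheet_%02d", s), rand_centre(bound),
                      sheet_size, rot)
    })
  }
  for (s in seq_len(n_irregular)) {
    incs[[length(incs) + 1]] <- try_place(function() {
      bound <- 360 / 2 * (1 + 0.72) + clearance + h
      .agglomerate_at(sprintf("irregular_%02d", s), rand_centre(bound))
    })
  }
  for (s in seq_len(n_spheres)) {
    incs[[length(incs) + 1]] <- try_place(function() {
      d <- runif(1, sphere_diameter_range[1], sphere_diameter_range[2])
      inclusion_sphere(sprintf("sphere_%02d", s),
                       rand_centre(d / 2 + clearance + h), d)
    })
  }

  phantom_spec(grid_shape = dims, voxel_size = h, tissue_region = region,
               inclusions = incs, noise_sd = noise_sd, seed = seed)
}
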