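# CT morphometry: calibration, segmentation, labelling, measurement,
# classification, CVF.

test_that("grey-value calibration interpolates two references exactly and matches OLS beyond", {
  v <- voxel_volume(array(c(100, 600, 350, 1100), c(2, 2, 1)))
  refs <- data.frame(material = c("air", "water"),
                     measured = c(100, 600), target = c(-1000, 0))
  cal <- calibrate_grey_values(v, refs)
  expect_equal(cal$grid[1, 1, 1], -1000)
  expect_equal(cal$grid[2, 1, 1], 0)
  # identity references leave the volume unchanged
  ident <- calibrate_grey_values(v, data.frame(material = c("a", "b"),
                                               measured = c(0, 1000),
                                               target = c(0, 1000)))
  expect_equal(ident$grid, v$grid)
  # three collinear points fit exactly
  col3 <- calibrate_grey_values(v, data.frame(material = letters[1:3],
                                              measured = c(0, 500, 1000),
                                              target = c(10, 510, 1010)))
  expect_equal(attr(col3, "calibration")$residuals, rep(0, 3), tolerance = 1e-10)
  # non-collinear points reproduce the closed-form OLS line
  rp <- data.frame(material = letters[1:3],
                   measured = c(100, 600, 1500), target = c(-990, 30, 1800))
  cal3 <- calibrate_grey_values(v, rp)
  oracle <- ols_line(rp$measured, rp$target)
  expect_equal(attr(cal3, "calibration")$slope, oracle[["slope"]])
  expect_equal(attr(cal3, "calibration")$intercept, oracle[["intercept"]])
  expect_equal(attr(cal3, "calibration")$residuals,
               rp$target - oracle[["intercept"]] - oracle[["slope"]] * rp$measured)
  expect_error(calibrate_grey_values(v, data.frame(material = c("a", "b"),
                                                   measured = c(5, 5),
                                                   target = c(0, 1))),
               "singular")
})

test_that("threshold segmentation assigns bands inclusively and leaves background out", {
  g <- array(c(100, 700, 1800, 324, 1249, 1250, 0, 65535), c(2, 2, 2))
  seg <- segment_volume(voxel_volume(g), threshold_config())
  expect_equal(as.vector(seg$tissue),
               c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(as.vector(seg$calc),
               c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_false(any(seg$tissue & seg$calc))
  # all-background volume flags an undefined CVF downstream
  blank <- voxel_volume(array(10L, c(4, 4, 4)))
  expect_warning(rep <- run_morphometry(blank), "undefined")
  expect_true(is.na(rep$cvf))
})

test_that("connected-component labelling matches the connectivity definition and a flood-fill oracle", {
  # two voxels sharing only a corner: one component at 26, two at 6
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- m[2, 2, 2] <- TRUE
  expect_equal(max(label_components(m, 26)), 1L)
  expect_equal(max(label_components(m, 6)), 2L)
  # two separated spheres
  spec <- phantom_spec(grid_shape = c(60, 30, 30), voxel_size = 15.5,
                       tissue_region = tissue_box(0.05),
                       inclusions = list(
                         inclusion_sphere("a", c(220, 230, 230), 150),
                         inclusion_sphere("b", c(700, 230, 230), 150)),
                       noise_sd = 0)
  seg <- segment_volume(generate_phantom_volume(spec)$volume)
  expect_equal(max(label_components(seg$calc)), 2L)
  # random sparse masks against the brute-force oracle
  set.seed(42)
  for (i in 1:8) {
    conn <- if (i %% 2 == 0) 6 else 26
    m <- array(runif(12^3) < 0.18, c(12, 12, 12))
    lab <- label_components(m, conn)
    oracle <- flood_fill_components(m, conn)
    expect_equal(max(lab), oracle$n)
    # identical partition: labels must be a relabelling of the oracle's
    expect_equal(length(unique(paste(lab[m], oracle$labels[m]))), oracle$n)
  }
})

test_that("component volume is voxel count times voxel volume and approaches the analytic sphere", {
  m <- array(FALSE, c(12, 12, 12)); m[3:12, 2:5, 2:3] <- TRUE
  expect_equal(measure_volume(m, 15.5), 80 * (15.5 / 1000)^3)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(measure_volume(one, 15.5), 3.723875e-06, tolerance = 1e-6)
  expect_error(measure_volume(array(FALSE, c(2, 2, 2)), 15.5), "empty")
  sph <- dig_sphere(10)
  expect_equal(measure_volume(sph, 15.5),
               4 / 3 * pi * (10 * 15.5 / 1000)^3, tolerance = 0.05)
})

test_that("isosurface area matches analytic spheres and boxes and is axis-permutation invariant", {
  # digitised sphere, radius 10 voxels: within 3% of 4 pi r^2
  h <- 15.5
  sph <- dig_sphere(10)
  A <- measure_surface_area(sph, h)
  expect_equal(attr(A, "method"), "mesh")
  expect_equal(as.numeric(A), 4 * pi * (10 * h / 1000)^2, tolerance = 0.03)
  # voxel-face counting would overshoot the sphere by ~50%
  cr <- plaquemorph:::.crop_mask(sph, 2L)
  A_faces <- plaquemorph:::.exposed_faces(as.logical(cr), as.integer(dim(cr))) *
    (h / 1000)^2
  expect_gt(A_faces / (4 * pi * (10 * h / 1000)^2), 1.4)
  # axis-aligned boxes: midpoint mesh is near-exact; the smoothed default
  # needs the box resolved well beyond the smoothing scale
  bx <- box_mask(20, 16, 12)
  true_small <- 2 * (20 * 16 + 16 * 12 + 20 * 12) * (h / 1000)^2
  expect_equal(as.numeric(measure_surface_area(bx, h, smoothing_sigma = 0)),
               true_small, tolerance = 0.05)
  bx2 <- box_mask(60, 48, 36)
  true_big <- 2 * (60 * 48 + 48 * 36 + 60 * 36) * (h / 1000)^2
  expect_equal(as.numeric(measure_surface_area(bx2, h)), true_big,
               tolerance = 0.05)
  # permuting axes leaves the area unchanged
  expect_equal(as.numeric(measure_surface_area(box_mask(10, 4, 2), h)),
               as.numeric(measure_surface_area(box_mask(2, 10, 4), h)))
  # sub-meshable component falls back to voxel faces, flagged
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  A1 <- measure_surface_area(one, h)
  expect_equal(attr(A1, "method"), "voxel-faces")
  expect_equal(as.numeric(A1), 6 * (h / 1000)^2)
})

test_that("sphericity closed forms hold and scale as 1/area", {
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1)
  expect_equal(sphericity(1, 6), (pi / 6)^(1 / 3))
  psi <- sphericity(2.5, 11)
  expect_equal(sphericity(2.5, 5.5), 2 * psi)
  expect_error(sphericity(0, 1), "positive")
})

test_that("equivalent diameter inverts the sphere volume and is monotone", {
  expect_equal(equivalent_diameter(pi / 6), 1000)
  v <- sort(runif(10, 1e-6, 1))
  expect_true(all(diff(equivalent_diameter(v)) > 0))
  # a 150 um phantom sphere's voxelised volume maps back to ~150 um
  spec <- phantom_spec(grid_shape = c(30, 30, 30),
                       tissue_region = tissue_box(0.05),
                       inclusions = list(inclusion_sphere("s", rep(15 * 15.5, 3), 150)),
                       noise_sd = 0)
  seg <- segment_volume(generate_phantom_volume(spec)$volume)
  d <- equivalent_diameter(measure_volume(seg$calc, 15.5))
  expect_lt(abs(d - 150), 15.5)
})

test_that("principal extents recover box dimensions, survive rotation, and are isotropic for spheres", {
  h <- 15.5
  ext <- principal_extents(box_mask(10, 4, 2), h)
  expect_equal(unname(ext), c(10, 4, 2) * h)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(unname(principal_extents(one, h)), rep(h, 3))
  # box rotated 45 degrees about z, re-voxelised through the sheet rasteriser
  rot <- matrix(c(cos(pi / 4), sin(pi / 4), 0,
                  -sin(pi / 4), cos(pi / 4), 0, 0, 0, 1), 3, 3)
  spec <- phantom_spec(grid_shape = c(60, 60, 30),
                       tissue_region = tissue_box(0.05),
                       inclusions = list(
                         inclusion_sheet("rb", c(30, 30, 15) * h,
                                         c(10, 4, 2) * h, rot)),
                       noise_sd = 0)
  seg <- segment_volume(generate_phantom_volume(spec)$volume)
  ext_r <- principal_extents(seg$calc, h)
  expect_equal(unname(ext_r), c(10, 4, 2) * h, tolerance = 0.15)
  # digitised sphere: near-equal extents
  ext_s <- principal_extents(dig_sphere(8), h)
  expect_lt(diff(range(ext_s)) / mean(ext_s), 0.1)
})

test_that("geometry classification follows the spherical -> sheet -> irregular precedence", {
  params <- morphometry_params()
  rec <- function(d, psi, l, w, t)
    list(equivalent_diameter_um = d, sphericity = psi,
         length_um = l, width_um = w, thickness_um = t)
  expect_equal(classify_inclusion(rec(150, 0.95, 160, 150, 140), params), "spherical")
  expect_equal(classify_inclusion(rec(540, 0.4, 2000, 800, 100), params), "sheet")
  expect_equal(classify_inclusion(rec(600, 0.6, 500, 400, 350), params), "irregular")
  # boundary: aspect ratio exactly at the limit counts as sheet; just below, irregular
  expect_equal(classify_inclusion(rec(600, 0.6, 800, 400, 200), params), "sheet")
  expect_equal(classify_inclusion(rec(600, 0.6, 790, 400, 210), params), "irregular")
  # a small low-sphericity particle is not spherical
  expect_equal(classify_inclusion(rec(150, 0.5, 300, 100, 90), params), "irregular")
})

test_that("CVF is the calcification share of total plaque volume", {
  expect_equal(compute_cvf(0, 10), 0)
  expect_equal(compute_cvf(5, 5), 0.5)
  expect_warning(out <- compute_cvf(0, 0), "undefined")
  expect_true(is.na(out))
  # heavily calcified phantom (true CVF near 0.5, like the stiffest
  # specimen's 0.52) recovers its own ground truth within 2%
  h <- 15.5
  spec <- phantom_spec(grid_shape = c(34, 34, 34),
                       tissue_region = tissue_box(0.03),
                       inclusions = list(inclusion_sphere("big", rep(17 * h, 3),
                                                          31 * h)),
                       noise_sd = 20, seed = 2L)
  ph <- generate_phantom_volume(spec)
  rep <- run_morphometry(ph$volume)
  expect_gt(ph$cvf_true, 0.4)  # a heavily calcified section
  expect_equal(rep$cvf, ph$cvf_true, tolerance = 0.02)
})

test_that("full morphometry reproduces the generator census and conserves voxels", {
  ph <- generate_phantom_volume(small_census_spec(noise_sd = 20))
  rep <- run_morphometry(ph$volume)
  expect_equal(unname(rep$counts), c(3, 1, 1))
  seg <- segment_volume(ph$volume)
  expect_equal(sum(rep$inclusions$voxel_count), sum(seg$calc))
  expect_equal(rep$cvf, ph$cvf_true, tolerance = 0.02)
})

test_that("morphometry is scale-equivariant in the voxel size", {
  ph <- generate_phantom_volume(small_census_spec(noise_sd = 0))
  v1 <- ph$volume
  v2 <- voxel_volume(v1$grid, v1$voxel_size * 3)
  r1 <- run_morphometry(v1)
  # the spherical-class size rule is an absolute physical threshold, so
  # classification equivariance holds when that threshold scales too
  r2 <- run_morphometry(v2, params = morphometry_params(d_max_um = 300 * 3))
  o1 <- order(r1$inclusions$voxel_count)
  o2 <- order(r2$inclusions$voxel_count)
  expect_equal(r2$inclusions$volume_mm3[o2], r1$inclusions$volume_mm3[o1] * 27)
  expect_equal(r2$inclusions$surface_area_mm2[o2],
               r1$inclusions$surface_area_mm2[o1] * 9)
  expect_equal(r2$inclusions$sphericity[o2], r1$inclusions$sphericity[o1])
  expect_identical(r2$inclusions$geometry_class[o2],
                   r1$inclusions$geometry_class[o1])
  expect_equal(r2$cvf, r1$cvf)
})

test_that("sphericity of resolved digitised spheres stays within the mesh tolerance band", {
  h <- 15.5
  for (r in c(10, 16)) {
    m <- dig_sphere(r, off = c(0.3, -0.2, 0.1))
    psi <- sphericity(measure_volume(m, h),
                      as.numeric(measure_surface_area(m, h)))
    expect_gt(psi, 0.95)
    expect_lt(psi, 1.03)
  }
})
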