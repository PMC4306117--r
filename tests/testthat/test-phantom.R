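# Synthetic phantom generators: construction, ground truth, determinism.

test_that("phantom ground truth mirrors the constructed inclusion census", {
  spec <- small_census_spec()
  ph <- generate_phantom_volume(spec)
  gt <- ph$ground_truth
  expect_equal(nrow(gt), 5L)
  expect_equal(sum(gt$kind == "sphere"), 3L)
  expect_equal(sum(gt$kind == "sheet"), 1L)
  expect_equal(sum(gt$kind == "irregular"), 1L)
  # analytic sphere truth
  r <- 150 / 2
  expect_equal(gt$true_volume_mm3[gt$label == "s1"], 4 / 3 * pi * r^3 * 1e-9)
  expect_equal(gt$true_equivalent_diameter_um[gt$label == "s1"], 150)
})

test_that("an empty inclusion list yields an empty calcification mask and CVF 0", {
  spec <- phantom_spec(grid_shape = c(30, 30, 30),
                       tissue_region = tissue_box(0.1),
                       inclusions = list(), noise_sd = 0)
  ph <- generate_phantom_volume(spec)
  seg <- segment_volume(ph$volume)
  expect_false(any(seg$calc))
  expect_identical(ph$cvf_true, 0)
  rep <- run_morphometry(ph$volume)
  expect_equal(rep$cvf, 0)
  expect_equal(nrow(rep$inclusions), 0L)
})

test_that("a connected 5-sphere agglomerate labels as exactly one component", {
  spec <- small_census_spec()
  only_agg <- spec
  only_agg$inclusions <- spec$inclusions[5]
  ph <- generate_phantom_volume(only_agg)
  seg <- segment_volume(ph$volume)
  lab <- label_components(seg$calc, connectivity = 26)
  expect_equal(max(lab), 1L)
})

test_that("invalid phantom constructions are rejected with the offending label", {
  h <- 15.5
  ext <- 40 * h
  # sphere poking outside the tissue region
  spec <- phantom_spec(grid_shape = c(40, 40, 40),
                       tissue_region = tissue_box(0.2),
                       inclusions = list(inclusion_sphere("runaway",
                                                          c(0.05, 0.5, 0.5) * ext, 100)),
                       noise_sd = 0)
  expect_error(generate_phantom_volume(spec), "runaway")
  # overlapping inclusions of different labels
  spec2 <- phantom_spec(grid_shape = c(40, 40, 40),
                        tissue_region = tissue_box(0.1),
                        inclusions = list(
                          inclusion_sphere("a", c(0.5, 0.5, 0.5) * ext, 150),
                          inclusion_sphere("b", c(0.55, 0.5, 0.5) * ext, 150)),
                        noise_sd = 0)
  expect_error(generate_phantom_volume(spec2), "ambiguous")
  # unresolvable sphere and disconnected agglomerate are caught at spec time
  expect_error(phantom_spec(inclusions = list(inclusion_sphere("tiny",
                                                               c(100, 100, 100), 20))),
               "resolvable")
  expect_error(inclusion_irregular("apart", rbind(c(0, 0, 0), c(1000, 0, 0)),
                                   c(100, 100)),
               "connected")
  expect_error(inclusion_sheet("flat", c(0, 0, 0), c(100, 100, 50)), "strictly")
})

test_that("phantom generation is deterministic given spec and seed", {
  spec <- small_census_spec(noise_sd = 25, seed = 11L)
  a <- generate_phantom_volume(spec)
  b <- generate_phantom_volume(spec)
  expect_identical(a$volume$grid, b$volume$grid)
  expect_identical(a$ground_truth, b$ground_truth)
  spec2 <- small_census_spec(noise_sd = 25, seed = 12L)
  expect_false(identical(generate_phantom_volume(spec2)$volume$grid,
                         a$volume$grid))
})

test_that("grey-level classes stay within their threshold bands under noise", {
  spec <- small_census_spec(noise_sd = 45, seed = 3L)
  ph <- generate_phantom_volume(spec)
  th <- threshold_config()
  g <- ph$volume$grid
  n <- length(g)
  # class identity is recoverable from the noiseless phantom
  truth <- generate_phantom_volume(small_census_spec(noise_sd = 0))$volume$grid
  misclassified <-
    sum(g[truth == 700] < th$tissue_low | g[truth == 700] > th$tissue_high) +
    sum(g[truth == 1800] < th$calc_low) +
    sum(g[truth == 100] >= th$tissue_low)
  expect_lt(misclassified / n, 0.001)
})

test_that("voxelised sphere volume agrees with the analytic volume within the surface bound", {
  for (r_um in c(100, 160, 220)) {
    spec <- phantom_spec(grid_shape = c(40, 40, 40),
                         tissue_region = tissue_box(0.05),
                         inclusions = list(inclusion_sphere("s", rep(20 * 15.5, 3), 2 * r_um)),
                         noise_sd = 0)
    ph <- generate_phantom_volume(spec)
    seg <- segment_volume(ph$volume)
    vox_mm3 <- (15.5 / 1000)^3
    v_vox <- sum(seg$calc) * vox_mm3
    v_true <- 4 / 3 * pi * (r_um / 1000)^3
    n_surface <- surface_voxel_count(seg$calc)
    expect_lte(abs(v_vox - v_true), n_surface * vox_mm3)
  }
})

test_that("synthetic spectra integrate to their specified band areas", {
  sp <- spectrum_spec(bands = data.frame(component = "x", centre = 1500,
                                         fwhm = 30, area = 2),
                      baseline = c(0, 0), noise_sd = 0)
  s <- generate_spectrum(sp)
  w <- band_window("x", 1500 - 120, 1500 + 120, "none")  # +/- 4 FWHM
  expect_equal(integrate_band(s, w), 2, tolerance = 0.01)
  # equal lipid and collagen areas give Lip:Col = 1 downstream
  s2 <- generate_spectrum(spectrum_spec(bands = default_bands(lip_col = 1,
                                                              calc_col = 0.5)))
  r <- composition_ratios(s2)
  expect_equal(r$lip_col, 1, tolerance = 0.01)
})

test_that("spectrum generation honours the descending grid and determinism", {
  sp <- spectrum_spec(noise_sd = 0.004, seed = 5L)
  s1 <- generate_spectrum(sp)
  s2 <- generate_spectrum(sp)
  expect_identical(s1$absorbance, s2$absorbance)
  expect_true(all(diff(s1$wavenumber) < 0))
  expect_equal(range(s1$wavenumber), c(700, 4000))
  expect_error(ftir_spectrum(c(1000, 1000, 1200), c(1, 2, 3)), "monotone")
})

test_that("mechanical curve generation inverts the Cauchy definition and is deterministic", {
  spec <- mech_curve_spec(a = 0.2, b = 3, lambda_u = 1.44)
  rec <- generate_mechanical_curve(spec)
  expect_identical(rec$displacement[1], 0)
  crv <- to_stress_stretch(rec)
  lambda <- crv$lambda
  expect_equal(crv$stress, 0.2 * (exp(3 * (lambda - 1)) - 1), tolerance = 1e-12)
  # determinism under noise
  spec_n <- mech_curve_spec(noise_sd = 0.02, seed = 9L)
  expect_identical(generate_mechanical_curve(spec_n)$force,
                   generate_mechanical_curve(spec_n)$force)
  expect_error(mech_curve_spec(lambda_u = 1), "exceed 1")
})
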