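# Independent oracles and fixture builders used across the suite.

# Digitised sphere of radius r voxels, centred on a voxel-centre grid with
# an `off` sub-voxel offset, padded by 3 voxels.
dig_sphere <- function(r, off = c(0, 0, 0)) {
  n <- ceiling(2 * r) + 6
  ctr <- (n + 1) / 2 + off
  d2 <- outer(outer(((1:n) - ctr[1])^2, ((1:n) - ctr[2])^2, "+"),
              ((1:n) - ctr[3])^2, "+")
  array(d2 <= r^2, c(n, n, n))
}

# Axis-aligned solid box of a x b x c voxels with 4 voxels of padding.
box_mask <- function(a, b, c) {
  m <- array(FALSE, c(a, b, c) + 8L)
  m[5:(4 + a), 5:(4 + b), 5:(4 + c)] <- TRUE
  m
}

# Brute-force flood-fill component count, independent of the package's
# labelling implementation.  Pure R breadth-first search; intended for
# masks up to ~20^3 voxels.
flood_fill_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man > 0 & (if (connectivity == 6) man == 1 else man <= 3), ,
               drop = FALSE]
  lab <- array(0L, dims)
  ncomp <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] > 0L) next
    ncomp <- ncomp + 1L
    queue <- matrix(arrayInd(s, dims), ncol = 3)
    lab[s] <- ncomp
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, ]
        if (any(w < 1) || any(w > dims)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- ncomp
          queue <- rbind(queue, w)
        }
      }
    }
  }
  list(n = ncomp, labels = lab)
}

# Voxels of a mask with at least one exposed face (6-neighbourhood).
surface_voxel_count <- function(mask) {
  d <- dim(mask)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  interior <- p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    interior <- interior & p[2:(d[1] + 1) + sh[1],
                             2:(d[2] + 1) + sh[2],
                             2:(d[3] + 1) + sh[3]]
  }
  sum(mask & !interior)
}

# Closed-form simple-linear-regression coefficients (OLS oracle).
ols_line <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

# Small deterministic phantom: three spheres, one sheet, one five-sphere
# agglomerate in a box-shaped tissue region.  Grid 120^3 at 15.5 um.
small_census_spec <- function(noise_sd = 0, seed = 7L) {
  h <- 15.5
  ext <- 120 * h
  agg_ctr <- c(0.7, 0.7, 0.5) * ext
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  phantom_spec(
    grid_shape = c(120, 120, 120), voxel_size = h,
    tissue_region = tissue_box(margin_frac = 0.05),
    inclusions = list(
      inclusion_sphere("s1", c(0.25, 0.25, 0.25) * ext, 150),
      inclusion_sphere("s2", c(0.75, 0.3, 0.3) * ext, 200),
      inclusion_sphere("s3", c(0.3, 0.75, 0.75) * ext, 120),
      inclusion_sheet("sh1", c(0.5, 0.5, 0.75) * ext, c(1000, 400, 60)),
      inclusion_irregular("ir1",
                          centres = rbind(agg_ctr,
                                          sweep(dirs * 180, 2, agg_ctr, "+")),
                          diameters = c(360, rep(260, 4)))),
    noise_sd = noise_sd, seed = seed)
}
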