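# a reusable band-limited test map: a few blobs in a 30 A cubic cell
prep_map <- function(d_lim = 3) {
  cached(paste0("prepmap", d_lim), {
    cell <- unit_cell(30, 30, 30)
    set.seed(3)
    mdl <- atom_model("C", matrix(rnorm(60, 15, 3), 20, 3), B = 20)
    phasex:::lowpass_map(
      model_density_map(mdl, cell, grid_for_resolution(cell, d_lim)),
      d_lim)
  })
}

test_that("sharpening follows exp(B s^2/4), is invertible, and B=0 is identity", {
  m <- prep_map()
  id <- sharpen_map(m, 0)
  expect_lt(max(abs(id$rho - m$rho)) / max(abs(m$rho)), 1e-10)
  rt <- sharpen_map(sharpen_map(m, 80), -80)
  expect_lt(max(abs(rt$rho - m$rho)) / max(abs(m$rho)), 1e-8)
  # closed form on a single mode at d = 10 A
  cell <- unit_cell(10, 10, 10)
  n <- c(12, 12, 12)
  xf <- phasex:::voxel_frac_coords(n)
  cosm <- map_grid(cell, array(cos(2 * pi * xf[, 1]), n))
  sh <- sharpen_map(cosm, 100)
  expect_equal(max(sh$rho) / max(cosm$rho), exp(100 / 400),
               tolerance = 1e-9)
})

test_that("FOM weighting applies C_ref per shell, zeroes FSC<=0, keeps phases", {
  m <- prep_map()
  sfa <- structure_factors_from_map(m, 3)
  # FSC 1 everywhere: unchanged
  u <- fom_weight_map(m, shell_curve(Inf, 0.1, 1))
  expect_lt(max(abs(u$rho - m$rho)) / max(abs(m$rho)), 1e-9)
  # FSC = 1/3 in the high shell: amplitudes x sqrt(0.5); FSC 0 kills a shell
  fsc <- shell_curve(c(Inf, 6, 4), c(6, 4, 2.8), c(1, 1 / 3, 0))
  w <- fom_weight_map(m, fsc)
  sfb <- structure_factors_from_map(w, 3)
  mid <- sfa$d < 6 & sfa$d >= 4
  hi <- sfa$d < 4
  expect_equal(sfb$F[mid] / sfa$F[mid], rep(sqrt(0.5), sum(mid)),
               tolerance = 1e-6)
  expect_lt(max(sfb$F[hi]), 1e-9)
  live <- sfb$F > max(sfb$F) * 1e-6
  expect_lt(max(abs(phasex:::wrap_deg(sfb$phi[live] - sfa$phi[live]))),
            1e-6)
  # sharpening keeps phases too (of numerically live coefficients)
  sfs <- structure_factors_from_map(sharpen_map(m, 50), 3)
  live2 <- sfa$F > max(sfa$F) * 1e-6
  expect_lt(max(abs(phasex:::wrap_deg(sfs$phi[live2] - sfa$phi[live2]))),
            1e-6)
})

test_that("FOM weighting reports coverage gaps and rejects bad FSC", {
  m <- prep_map()
  expect_error(fom_weight_map(m, shell_curve(Inf, 5, 0.9)), "gap")
  expect_error(fom_weight_map(m, shell_curve(Inf, 0.1, 1.2)), "FSC")
})

test_that("magnification correction is exact at scale 1 and near-exact on inversion", {
  m <- prep_map()
  expect_identical(correct_magnification(m, 1)$rho, m$rho)
  rt <- correct_magnification(correct_magnification(m, 1.02), 1 / 1.02)
  expect_gt(cor(as.vector(rt$rho), as.vector(m$rho)), 0.999)
  expect_error(correct_magnification(m, 1.5), "bounds")
})

test_that("magnification scales blob width, keeps centroid and total density", {
  cell <- unit_cell(30, 30, 30)
  blob <- atom_model("C", c(15, 15, 15), B = 60)
  bm <- model_density_map(blob, cell, grid_for_resolution(cell, 2))
  bs <- correct_magnification(bm, 1.05)
  mom <- function(m) {
    r <- pmax(as.vector(m$rho), 0)
    xf <- phasex:::voxel_frac_coords(dim(m$rho))
    ctr <- colSums(xf * r) / sum(r)
    list(ctr = ctr * 30,
         w = sqrt(sum(r * rowSums(sweep(xf, 2, ctr)^2)) / sum(r)) * 30,
         tot = sum(r))
  }
  a <- mom(bm); b <- mom(bs)
  expect_lt(sqrt(sum((a$ctr - b$ctr)^2)), 0.1)
  expect_equal(b$w / a$w, 1.05, tolerance = 0.01)
  expect_equal(b$tot / a$tot, 1, tolerance = 0.01)
})

test_that("P1 boxing pads by the requested factor around the density", {
  m <- prep_map()
  ext <- phasex:::estimate_extent(m, 1)
  bx <- place_in_p1_box(m, 2.5)
  expect_equal(bx$cell$a, 2.5 * ext$diameter, tolerance = 0.05)
  expect_gte(bx$cell$a, 2 * ext$diameter)
  # boxed density centred: centre of mass near the box centre
  r <- pmax(as.vector(bx$map$rho), 0)
  xf <- phasex:::voxel_frac_coords(dim(bx$map$rho))
  ctr <- colSums(xf * r) / sum(r)
  expect_lt(max(abs(ctr - 0.5)), 0.05)
  expect_error(place_in_p1_box(m, 1.5), "padding_factor")
  zero <- map_grid(unit_cell(10, 10, 10), array(0, c(8, 8, 8)))
  expect_error(place_in_p1_box(zero, 2), "no density")
})

test_that("a synthetic blob of known diameter is boxed to the expected edge", {
  cell <- unit_cell(60, 60, 60)
  # shell of pseudo-atoms of radius 15 => thresholded diameter ~30 A
  set.seed(8)
  u <- matrix(rnorm(90), 30, 3)
  u <- u / sqrt(rowSums(u^2)) * 15
  mdl <- atom_model("C", sweep(u, 2, c(30, 30, 30), "+"), B = 40)
  m <- model_density_map(mdl, cell, grid_for_resolution(cell, 4))
  bx <- place_in_p1_box(m, 2.5)
  ext <- phasex:::estimate_extent(m, 1)
  expect_equal(bx$cell$a, 2.5 * ext$diameter, tolerance = 0.05)
  expect_equal(ext$diameter, 30, tolerance = 3)
})

test_that("prep operations commute with global density scaling", {
  m <- prep_map()
  s <- 3.7
  ms <- map_grid(m$cell, m$rho * s)
  expect_equal(sharpen_map(ms, 60)$rho, sharpen_map(m, 60)$rho * s,
               tolerance = 1e-9)
  fsc <- shell_curve(c(Inf, 5), c(5, 2.8), c(0.9, 0.4))
  expect_equal(fom_weight_map(ms, fsc)$rho, fom_weight_map(m, fsc)$rho * s,
               tolerance = 1e-9)
  expect_equal(correct_magnification(ms, 1.03)$rho,
               correct_magnification(m, 1.03)$rho * s, tolerance = 1e-9)
})
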