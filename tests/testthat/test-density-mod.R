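test_that("solvent mask separates a blob from empty solvent", {
  cell <- unit_cell(40, 40, 40)
  set.seed(31)
  # spiky atomic density filling the x < 20 half of the cell; the Wang
  # mask keys on local |rho| structure, so the protein must fluctuate
  mdl <- atom_model("C", cbind(runif(600, 2, 18), runif(600, 2, 38),
                               runif(600, 2, 38)), B = 60)
  m <- model_density_map(mdl, cell, c(40, 40, 40))
  mask <- solvent_mask(m, solvent_fraction = 0.5, smoothing_radius = 6)
  # protein flag should coincide with the occupied half
  xf <- phasex:::voxel_frac_coords(c(40, 40, 40)) * 40
  inside <- xf[, 1] < 20
  pm <- as.vector(mask$rho) >= 0.5
  jaccard <- sum(pm & inside) / sum(pm | inside)
  expect_gt(jaccard, 0.8)
  expect_equal(mean(pm), 0.5, tolerance = 0.03)
  # limits
  tiny <- solvent_mask(m, 0.001, 6)
  expect_gt(mean(tiny$rho), 0.99)
  flat <- solvent_mask(map_grid(cell, array(1, c(10, 10, 10))), 0.5, 6)
  expect_true(isTRUE(attr(flat, "degenerate")))
  expect_error(solvent_mask(m, 1.2), "solvent_fraction")
})

test_that("solvent flattening acts only on the solvent region", {
  cell <- unit_cell(20, 20, 20)
  set.seed(32)
  rho <- array(rnorm(8000), c(20, 20, 20))
  m <- map_grid(cell, rho)
  allp <- map_grid(cell, array(1, c(20, 20, 20)))
  expect_identical(solvent_flatten(m, allp)$rho, m$rho)
  alls <- map_grid(cell, array(0, c(20, 20, 20)))
  out <- solvent_flatten(m, alls)
  expect_lt(diff(range(out$rho)), 1e-12)
  half <- map_grid(cell, array(rep(c(0, 1), each = 4000), c(20, 20, 20)))
  out2 <- solvent_flatten(m, half)
  expect_identical(out2$rho[half$rho >= 0.5], m$rho[half$rho >= 0.5])
  expect_lt(diff(range(out2$rho[half$rho < 0.5])), 1e-12)
})

test_that("histogram matching is rank-preserving, close in KS, and idempotent", {
  cell <- unit_cell(20, 20, 20)
  set.seed(33)
  m <- map_grid(cell, array(rnorm(8000)^3, c(20, 20, 20)))
  target <- histogram_of(rgamma(20000, 2, 1), 64)
  out <- histogram_match(m, target)
  # rank preservation
  expect_true(all(diff(as.vector(out$rho)[order(as.vector(m$rho))]) >= 0))
  # Kolmogorov-Smirnov distance to the target
  tq <- phasex:::histogram_quantile(target, seq(0.005, 0.995, 0.005))
  ks <- suppressWarnings(ks.test(as.vector(out$rho), tq)$statistic)
  expect_lt(ks, 0.05)
  # matching twice equals matching once (within bin resolution)
  out2 <- histogram_match(out, target)
  expect_lt(max(abs(out2$rho - out$rho)),
            2 * max(diff(target$edges)))
  # matching to the map's own histogram is near-identity
  own <- histogram_of(as.vector(m$rho), 128)
  self <- histogram_match(m, own)
  expect_lt(median(abs(self$rho - m$rho)), max(diff(own$edges)))
  expect_error(histogram_match(m, histogram_of(rnorm(100), 5)), "10 bins")
})

test_that("reference histograms are sampling-invariant and normalized", {
  cell <- unit_cell(24, 24, 24)
  set.seed(34)
  mdl <- atom_model("C", matrix(runif(60, 6, 18), 20, 3), B = 25)
  h1 <- reference_histogram(mdl, cell, c(30, 30, 30), d_min = 3)
  h2 <- reference_histogram(mdl, cell, c(60, 60, 60), d_min = 3)
  expect_equal(sum(h1$freq), 1, tolerance = 1e-12)
  q <- seq(0.01, 0.99, 0.01)
  q1 <- phasex:::histogram_quantile(h1, q)
  q2 <- phasex:::histogram_quantile(h2, q)
  scale <- diff(range(q1))
  expect_lt(max(abs(q1 - q2)) / scale, 0.1)
  # single-atom map: heavy-tailed, mode in the low-density bins
  hs <- reference_histogram(atom_model("C", c(12, 12, 12), B = 30), cell,
                            c(30, 30, 30), d_min = 3)
  expect_lt(which.max(hs$freq), length(hs$freq) / 2)
})

test_that("NCS averaging is exact on symmetric maps and reduces noise by sqrt(2)", {
  sc <- small_scenario()
  grid <- sc$config$grid
  truth <- sc$truth_phases
  truth$fom <- 1
  m <- map_from_structure_factors(truth, grid = grid, use_fom_weights = TRUE)
  # identity-only operators change nothing
  ident <- ncs_operator(diag(3), c(0, 0, 0), c(0, 0, 0), 10)
  expect_identical(ncs_average(m, list(ident))$rho, m$rho)
  # exact operators on the exactly symmetric map: near-identity inside masks
  av <- ncs_average(m, sc$ncs_ops)
  expect_gt(cor(as.vector(av$rho), as.vector(m$rho)), 0.98)
  # Monte-Carlo: independent smooth noise is averaged down by ~1/sqrt(2)
  ratios <- vapply(1:10, function(s) {
    nz <- smooth_noise_map(sc$cell, grid, 2.8 * 1.5, 100 + s)
    noisy <- map_grid(sc$cell, m$rho + nz$rho)
    avn <- ncs_average(noisy, sc$ncs_ops)
    op <- sc$ncs_ops[[1]]
    cf <- as.vector(cart_to_frac(op$center, sc$cell))
    xf <- phasex:::voxel_frac_coords(grid)
    dfr <- sweep(xf, 2, cf); dfr <- dfr - round(dfr)
    sel <- rowSums((dfr %*% t(cell_orth(sc$cell)))^2) <= (op$radius * 0.8)^2
    resid <- (avn$rho - m$rho)[sel]
    sd(resid) / sd(nz$rho[sel])
  }, numeric(1))
  expect_equal(mean(ratios), 1 / sqrt(2), tolerance = 0.1)
})

test_that("a misaligned NCS operator averages worse than the exact one", {
  sc <- small_scenario()
  grid <- sc$config$grid
  truth <- sc$truth_phases
  truth$fom <- 1
  m <- map_from_structure_factors(truth, grid = grid, use_fom_weights = TRUE)
  nz <- smooth_noise_map(sc$cell, grid, 2.8 * 1.5, 77)
  noisy <- map_grid(sc$cell, m$rho + 0.5 * sd(m$rho) / sd(nz$rho) * nz$rho)
  good <- ncs_average(noisy, sc$ncs_ops)
  tilt <- euler_to_matrix(5, 0, 0)
  bad_ops <- lapply(sc$ncs_ops, function(op)
    ncs_operator(op$R %*% tilt, op$t, op$center, op$radius))
  bad <- ncs_average(noisy, bad_ops)
  cc_good <- cor(as.vector(good$rho), as.vector(m$rho))
  cc_bad <- cor(as.vector(bad$rho), as.vector(m$rho))
  expect_gt(cc_good, cc_bad)
})

test_that("prime-and-switch is near its fixed point from true phases", {
  sc <- small_scenario()
  truth <- sc$truth_phases
  truth$fom <- 1
  cfg <- sc$config
  cfg$extension_schedule <- min(sc$config$extension_schedule)
  cfg$n_inner_cycles <- 1
  out <- prime_and_switch(sc$obs, truth, cfg, sc$reference_hist)
  expect_lt(weighted_mean_phase_error(out, sc$truth_phases), 10)
})

test_that("prime-and-switch recovers from heavy phase noise and extends", {
  sc <- small_scenario()
  set.seed(9)
  tt <- sc$truth_phases[sc$truth_phases$d >= 5.0, , drop = FALSE]
  noisy <- reflection_set(tt$h, tt$k, tt$l, tt$F, sc$cell,
                          phi = tt$phi + rnorm(nrow(tt), 0, 60), fom = 0.7)
  w0 <- weighted_mean_phase_error(noisy, sc$truth_phases)
  out <- prime_and_switch(sc$obs, noisy, sc$config, sc$reference_hist)
  w1 <- weighted_mean_phase_error(out, sc$truth_phases)
  expect_lt(w1, w0)
  expect_equal(min(out$d[!is.na(out$phi)]), min(sc$obs$d), tolerance = 0.02)
})

test_that("with every operator disabled the phases round-trip unchanged", {
  sc <- small_scenario()
  cfg <- sc$config
  cfg$use_solvent <- cfg$use_histogram <- cfg$use_ncs <- FALSE
  cfg$extension_schedule <- 5.0
  cfg$n_inner_cycles <- 3
  out <- prime_and_switch(sc$obs, sc$start_phases, cfg)
  m <- match_reflections(out, sc$start_phases)
  expect_lt(max(abs(phasex:::wrap_deg(m$a$phi - m$b$phi))), 1e-6)
})

test_that("prime-and-switch validates its inputs", {
  sc <- small_scenario()
  cfg <- sc$config
  cfg$extension_schedule <- c(5, 1.5)
  expect_error(prime_and_switch(sc$obs, sc$start_phases, cfg,
                                sc$reference_hist), "beyond")
  expect_error(dm_config(extension_schedule = c(3, 4)), "decreasing")
  expect_error(dm_config(solvent_fraction = 0, extension_schedule = 3),
               "solvent_fraction")
  cfg2 <- sc$config
  expect_error(prime_and_switch(sc$obs, sc$start_phases, cfg2, NULL),
               "reference_hist")
})
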