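test_that("peak search finds blob centres with sub-voxel accuracy", {
  cell <- unit_cell(24, 24, 24)
  ctr <- c(11.63, 12.41, 10.87)  # deliberately off-grid
  m <- model_density_map(atom_model("C", ctr, B = 40), cell, c(30, 30, 30))
  pk <- find_peaks(m, 1)
  expect_equal(nrow(pk), 1)
  expect_lt(sqrt(sum((as.numeric(pk[1, 1:3]) - ctr)^2)), 0.25 * 24 / 30)
  flat <- map_grid(cell, array(1, c(10, 10, 10)))
  expect_equal(nrow(find_peaks(flat, 1)), 0)
  two <- model_density_map(
    atom_model(c("C", "C"), rbind(c(6, 6, 6), c(17, 17, 17)), B = 40,
               occ = c(0.6, 1)), cell, c(30, 30, 30))
  pk2 <- find_peaks(two, 0.5)
  expect_gte(nrow(pk2), 2)
  expect_gt(pk2$height[1], pk2$height[2])
  expect_lt(sqrt(sum((as.numeric(pk2[1, 1:3]) - c(17, 17, 17))^2)), 0.5)
})

# an ideal curved helical trace with 3.8 A spacing
ideal_trace <- function(n = 20) {
  t <- seq_len(n)
  xyz <- cbind(8 * cos(t / 3) + 20, 8 * sin(t / 3) + 20, 1.9 * t + 4)
  # renormalise successive distances to exactly 3.8
  for (i in 2:n) {
    v <- xyz[i, ] - xyz[i - 1, ]
    xyz[i, ] <- xyz[i - 1, ] + v / sqrt(sum(v^2)) * 3.8
  }
  xyz
}

test_that("greedy tracing recovers an ideal trace in order", {
  xyz <- ideal_trace(20)
  peaks <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      height = seq(2, 1, length.out = 20))
  built <- trace_ca_chain(peaks)
  expect_equal(nrow(built), 20)
  expect_equal(length(unique(built$chain)), 1)
  # consecutive residues are consecutive trace points
  d <- sqrt(rowSums(diff(model_xyz(built))^2))
  expect_true(all(abs(d - 3.8) < 0.7))
})

test_that("tracing discards sparse peaks and tolerates decoys", {
  set.seed(41)
  far <- data.frame(x = runif(30, 0, 100) * 7, y = runif(30) * 300,
                    z = runif(30) * 300, height = runif(30))
  # guarantee mutual distances > 5 A by spreading on a coarse lattice
  lat <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10), z = 0)
  sparse <- data.frame(x = lat$x[1:30], y = lat$y[1:30], z = 9 * (1:30),
                       height = runif(30))
  expect_equal(nrow(trace_ca_chain(sparse)), 0)
  # ideal trace plus 30% decoy peaks: >= 80% of true positions recovered
  xyz <- ideal_trace(30)
  dec <- matrix(runif(27, 0, 40), 9, 3)
  # keep decoys away from the trace so they are unambiguous decoys
  keep <- apply(dec, 1, function(p)
    min(sqrt(rowSums(sweep(xyz, 2, p)^2))) > 6)
  peaks <- data.frame(
    x = c(xyz[, 1], dec[keep, 1]), y = c(xyz[, 2], dec[keep, 2]),
    z = c(xyz[, 3], dec[keep, 3]),
    height = c(runif(30, 1, 2), runif(sum(keep), 1, 2)))
  built <- trace_ca_chain(peaks)
  truth <- atom_model("C", xyz, B = 20)
  expect_gte(ca_recovery(built, truth, cutoff = 1.5), 0.8)
})

test_that("ca_recovery scores constructed displacement cases", {
  # straight trace: displacements have unambiguous nearest neighbours
  xyz <- cbind(10, 10, 3.8 * (1:20))
  truth <- atom_model("C", xyz, B = 20)
  built <- atom_model("X", xyz, B = 30)
  expect_equal(ca_recovery(built, truth), 1)
  expect_equal(ca_recovery(
    atom_model("X", sweep(xyz, 2, c(2, 0, 0), "+"), B = 30), truth), 0)
  half <- rbind(sweep(xyz[1:10, ], 2, c(0.5, 0, 0), "+"),
                sweep(xyz[11:20, ], 2, c(3, 0, 0), "+"))
  expect_equal(ca_recovery(atom_model("X", half, B = 30), truth), 0.5)
})

test_that("ca_recovery is symmetric under a rigid motion of both models", {
  xyz <- ideal_trace(15)
  set.seed(42)
  built <- xyz + matrix(rnorm(45, 0, 0.8), 15, 3)
  r0 <- ca_recovery(atom_model("X", built, B = 30),
                    atom_model("C", xyz, B = 20))
  R <- euler_to_matrix(20, 40, 60)
  shift <- c(5, -3, 2)
  mv <- function(m) sweep(m %*% t(R), 2, shift, "+")
  r1 <- ca_recovery(atom_model("X", mv(built), B = 30),
                    atom_model("C", mv(xyz), B = 20))
  expect_equal(r0, r1)
})

test_that("ca_recovery honours crystal symmetry and periodicity", {
  sc <- small_scenario()
  tm <- sc$truth_model[sc$truth_model$role == "main", , drop = FALSE]
  # shift built atoms by a full lattice translation: recovery must be 1
  shifted <- tm
  shifted[, c("x", "y", "z")] <- sweep(model_xyz(tm), 2,
                                       c(sc$cell$a, 0, 0), "+")
  expect_equal(ca_recovery(shifted, sc$truth_model, cell = sc$cell,
                           sym = sc$sym), 1)
})

test_that("phases from the true model are excellent at low resolution", {
  sc <- small_scenario()
  mp <- phases_from_built_model(sc$truth_model, sc$obs)
  sa <- attr(mp, "sigma_a")
  expect_gt(sa$value[1], 0.8)
  lowres <- mp$d > 5
  expect_gt(mean(mp$fom[lowres]), 0.9)
  expect_error(phases_from_built_model(
    atom_model(character(0), matrix(numeric(0), 0, 3)), sc$obs),
    "no atoms")
})

test_that("decoy contamination monotonically degrades model-phase FOMs", {
  sc <- small_scenario()
  tm <- sc$truth_model[sc$truth_model$role == "main", , drop = FALSE]
  mean_fom_at <- function(frac_decoy, seed) {
    set.seed(seed)
    n <- nrow(tm)
    nkeep <- round((1 - frac_decoy) * n)
    keep <- model_xyz(tm)[sample(n, nkeep), , drop = FALSE]
    dec <- cbind(runif(n - nkeep, 0, sc$cell$a),
                 runif(n - nkeep, 0, sc$cell$b),
                 runif(n - nkeep, 0, sc$cell$c))
    mdl <- atom_model("X", rbind(keep, dec), B = 30)
    mean(phases_from_built_model(mdl, sc$obs)$fom)
  }
  for (seed in 1:2) {
    f <- vapply(c(0, 0.4, 0.8), mean_fom_at, numeric(1), seed = seed)
    expect_true(all(diff(f) < 0))
  }
})

test_that("a 38%-correct model phases better than random but worse than truth", {
  sc <- small_scenario()
  tm <- sc$truth_model[sc$truth_model$role == "main", , drop = FALSE]
  set.seed(43)
  n <- nrow(tm)
  nkeep <- round(0.38 * n)
  keep <- model_xyz(tm)[sample(n, nkeep), , drop = FALSE]
  dec <- cbind(runif(n - nkeep, 0, sc$cell$a),
               runif(n - nkeep, 0, sc$cell$b),
               runif(n - nkeep, 0, sc$cell$c))
  mp <- phases_from_built_model(atom_model("X", rbind(keep, dec), B = 30),
                                sc$obs)
  w <- weighted_mean_phase_error(mp, sc$truth_phases)
  expect_gt(w, 10)
  expect_lt(w, 88)
})
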