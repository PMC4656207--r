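# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a small but complete two-copy scenario for module-level tests
small_scenario <- function(seed = 4) {
  cached(paste0("small", seed),
         standard_scenario(seed, n_residues = 30, cell_edge = 42,
                           d_min = 2.8, em_res = 5.0))
}

# the full-size standard scenario (acceptance conditions)
std_scenario <- function(seed) {
  cached(paste0("std", seed), standard_scenario(seed))
}

# full 4-cycle pipeline fit on the standard scenario
std_fit <- function(seed) {
  cached(paste0("fit", seed), {
    sc <- std_scenario(seed)
    phase_extend(sc$obs, sc$start_phases, sc$config, sc$reference_hist,
                 sym = sc$sym, n_cycles = 4, truth_phases = sc$truth_phases,
                 truth_model = sc$truth_model, early_exit_tol = 0)
  })
}

# P2_1 molecular-replacement ground-truth case: a small molecule placed at
# a known rotation/translation, with observed amplitudes and a boxed map
p21_case <- function(seed) {
  cached(paste0("p21", seed), {
    cell <- unit_cell(28, 22, 26)
    sym <- sym_p21()
    toy <- make_toy_structure(16, 1, seed = seed)
    m0 <- toy$model
    m0[, c("x", "y", "z")] <- sweep(model_xyz(m0), 2,
                                    colMeans(model_xyz(m0)))
    set.seed(seed + 40)
    ang <- runif(3, 0, 360) * c(1, 0.5, 1)
    R_true <- euler_to_matrix(ang[1], ang[2], ang[3])
    u_true <- c(runif(1), 0, runif(1))
    xc <- model_xyz(m0) %*% t(R_true) +
      matrix(as.vector(frac_to_cart(u_true, cell)), nrow(m0), 3,
             byrow = TRUE)
    mc <- m0
    mc[, c("x", "y", "z")] <- xc
    sim <- simulate_observed(mc, cell, sym, d_min = 3.0,
                             amp_noise_frac = 0.03, seed = seed + 1)
    em <- simulate_em_map(m0, cell = NULL, resolution = 3.2,
                          phase_noise_deg = 10, B_blur = 30,
                          seed = seed + 2)
    list(cell = cell, sym = sym, model_centred = m0, model_crystal = mc,
         R_true = R_true, u_true = u_true, obs = sim$obs,
         truth = sim$truth, em = em)
  })
}

# Is the found (rotation, translation) equivalent to the truth in P2_1?
# Equivalences: the symmetry-related orientation, origin shifts of 1/2
# along a and c, and the arbitrary origin along the polar b axis.
p21_solution_error <- function(R_found, t_found, R_true, u_true, cell) {
  R2 <- diag(c(-1, 1, -1))
  cands <- list()
  for (alt in list(list(R = R_true, u = u_true),
                   list(R = R2 %*% R_true,
                        u = c(-u_true[1], u_true[2] + 0.5, -u_true[3])))) {
    rd <- rotation_distance(R_found, alt$R)
    for (sx in c(0, 0.5)) for (sz in c(0, 0.5)) {
      dfr <- t_found - (alt$u + c(sx, 0, sz))
      dfr <- dfr - round(dfr)
      dfr[2] <- 0  # polar axis: origin along b is arbitrary
      td <- sqrt(sum(as.vector(frac_to_cart(dfr, cell))^2))
      cands[[length(cands) + 1]] <- list(rot = rd, trans = td)
    }
  }
  score <- vapply(cands, function(c) c$rot + 10 * c$trans, numeric(1))
  cands[[which.min(score)]]
}

# band-limited (smooth) unit-variance noise map, reproducible per seed
smooth_noise_map <- function(cell, n, d_limit, seed) {
  set.seed(seed)
  rho <- array(rnorm(prod(n)), n)
  m <- phasex:::lowpass_map(map_grid(cell, rho), d_limit)
  m$rho <- m$rho / sd(as.vector(m$rho))
  m
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
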