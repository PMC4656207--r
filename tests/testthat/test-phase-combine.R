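# independent Bessel oracle: I_n(x) = (1/pi) Int_0^pi exp(x cos t) cos(n t) dt
bessel_I_oracle <- function(n, x) {
  vapply(x, function(xx)
    integrate(function(t) exp(xx * cos(t) - xx) * cos(n * t), 0, pi,
              rel.tol = 1e-12)$value / pi, numeric(1))
}

test_that("E-value normalization gives unit mean square per shell", {
  cell <- unit_cell(30, 30, 30)
  g <- hkl_hemisphere(cell, 3)
  set.seed(51)
  r <- reflection_set(g$h, g$k, g$l, sqrt(rexp(nrow(g), 1 / 50)), cell)
  e <- normalize_amplitudes(r, 8)
  sh <- attr(e, "shell")
  ms <- tapply(e$F^2, sh, mean)
  expect_lt(max(abs(ms - 1)), 1e-6)
  # constant F per shell gives E = 1; doubling F changes nothing
  rc <- reflection_set(g$h, g$k, g$l, rep(7, nrow(g)), cell)
  expect_lt(max(abs(normalize_amplitudes(rc, 8)$F - 1)), 1e-9)
  r2 <- r; r2$F <- 2 * r2$F
  expect_equal(normalize_amplitudes(r2, 8)$F, e$F, tolerance = 1e-12)
})

test_that("sigma-A hits its limits for perfect, independent, and mixed models", {
  cell <- unit_cell(30, 30, 30)
  g <- hkl_hemisphere(cell, 3)
  set.seed(52)
  n <- nrow(g)
  Fo <- sqrt(rexp(n, 1 / 50))
  eo <- normalize_amplitudes(reflection_set(g$h, g$k, g$l, Fo, cell), 8)
  # perfect model
  sa <- estimate_sigma_a(eo, eo, 8)
  expect_true(all(sa$value >= 0.95))
  # independent model: the estimated moment (sigma_A^4) is statistically
  # zero - below 3 standard errors of the product moment
  Fi <- sqrt(rexp(n, 1 / 50))
  ei <- normalize_amplitudes(reflection_set(g$h, g$k, g$l, Fi, cell), 8)
  sai <- estimate_sigma_a(eo, ei, 8)
  nshell <- n / 8
  expect_true(all(sai$value^4 < 3 / sqrt(nshell)))
  # half-scrambled model sits strictly between the two limits
  Fm <- ifelse(seq_len(n) %% 2 == 0, Fo, Fi)
  em <- normalize_amplitudes(reflection_set(g$h, g$k, g$l, Fm, cell), 8)
  sam <- estimate_sigma_a(eo, em, 8)
  expect_gt(mean(sam$value), mean(sai$value) + 0.1)
  expect_true(all(sam$value < sa$value))
})

test_that("FOM formula matches the Bessel oracle and is monotone", {
  x <- c(0.1, 0.5, 1, 2, 5, 20, 100)
  m <- phasex:::bessel_ratio(x)
  oracle <- bessel_I_oracle(1, x) / bessel_I_oracle(0, x)
  expect_lt(max(abs(m - oracle)), 1e-8)
  expect_equal(phasex:::bessel_ratio(2), 0.6978, tolerance = 1e-4)
  expect_true(all(diff(phasex:::bessel_ratio(seq(0, 50, 0.5))) > 0))
  # sigma_A = 0 gives m = 0
  sa0 <- shell_curve(Inf, 0.1, 0)
  expect_equal(fom_from_sigma_a(sa0, runif(5, 0.5, 2), runif(5, 0.5, 2),
                                rep(3, 5)), rep(0, 5))
})

test_that("fom<->concentration inversion round-trips to 1e-6", {
  expect_equal(fom_to_concentration(0), 0)
  expect_equal(fom_to_concentration(0.6978), 2, tolerance = 1e-3)
  m <- c(seq(0.1, 0.95, 0.05), 0.99)
  x <- fom_to_concentration(m)
  expect_lt(max(abs(phasex:::bessel_ratio(x) - m)), 1e-8)
  xs <- c(0.05, 0.3, 1, 2.7, 8, 40)
  expect_lt(max(abs(fom_to_concentration(phasex:::bessel_ratio(xs)) - xs)),
            1e-6)
})

test_that("phase combination handles null, reinforcing, and cancelling sources", {
  cell <- unit_cell(20, 20, 20)
  g <- head(hkl_hemisphere(cell, 4), 50)
  set.seed(53)
  phi1 <- runif(50, 0, 360)
  s1 <- reflection_set(g$h, g$k, g$l, runif(50, 1, 10), cell, phi = phi1,
                       fom = runif(50, 0.3, 0.9))
  # null second source
  s2 <- s1
  s2$fom <- 0
  s2$phi <- runif(50, 0, 360)
  out <- combine_phases(s1, s2)
  mm <- match_reflections(out, s1)
  expect_lt(max(abs(phasex:::wrap_deg(mm$a$phi - mm$b$phi))), 1e-9)
  expect_equal(mm$a$fom, mm$b$fom, tolerance = 1e-6)
  # reinforcement: same phases, fom must not decrease
  s3 <- s1
  s3$fom <- pmin(s1$fom + 0.05, 0.95)
  out2 <- combine_phases(s1, s3)
  mm2 <- match_reflections(out2, s1)
  expect_lt(max(abs(phasex:::wrap_deg(mm2$a$phi - mm2$b$phi))), 1e-9)
  expect_true(all(mm2$a$fom >= pmax(mm2$b$fom, s3$fom[match(
    phasex:::hkl_key(mm2$b), phasex:::hkl_key(s3))]) - 1e-9))
  # exact cancellation
  a <- reflection_set(1, 0, 0, 1, cell, phi = 0, fom = 0.5)
  b <- reflection_set(1, 0, 0, 1, cell, phi = 180, fom = 0.5)
  z <- combine_phases(a, b)
  expect_lt(z$fom, 1e-6)
})

test_that("phase combination is commutative and clipped", {
  cell <- unit_cell(20, 20, 20)
  g <- head(hkl_hemisphere(cell, 4), 80)
  set.seed(54)
  mk <- function() reflection_set(g$h, g$k, g$l, runif(80, 1, 10), cell,
                                  phi = runif(80, 0, 360),
                                  fom = runif(80, 0, 0.999))
  s1 <- mk(); s2 <- mk()
  ab <- combine_phases(s1, s2)
  ba <- combine_phases(s2, s1)
  expect_lt(max(abs(phasex:::wrap_deg(ab$phi - ba$phi))), 1e-10)
  expect_lt(max(abs(ab$fom - ba$fom)), 1e-10)
  expect_true(all(ab$fom >= 0 & ab$fom <= 0.9999))
  # duplicated indices within one source are rejected
  dup <- rbind(as.data.frame(s1), as.data.frame(s1)[1, ])
  expect_error(combine_phases(dup, s2), "duplicated")
  # reflections present in only one source pass through
  extra <- reflection_set(c(g$h, 9), c(g$k, 0), c(g$l, 0),
                          c(s1$F, 5), cell, phi = c(s1$phi, 123),
                          fom = c(s1$fom, 0.7))
  out <- combine_phases(extra, s2)
  row <- out[out$h == 9 & out$k == 0 & out$l == 0, ]
  expect_equal(row$phi, 123)
  expect_equal(row$fom, 0.7)
})
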