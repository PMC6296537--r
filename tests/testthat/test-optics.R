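# Closed-form and forward-model oracles for the depth-resolved estimators.

test_that("geometric A-line matches the closed-form attenuation", {
  # I[j] = 1000 * 0.99^j, dz = 0.005: the linearised estimator's infinite-tail
  # closed form is mu = (1 - r) / (2 * dz * r) = 1.010101 mm^-1; the exact
  # discrete form gives log(1/r) / (2 * dz) = 1.005034 mm^-1.
  I <- matrix(1000 * 0.99^(0:1023), nrow = 1)
  fr <- polar_frame(I, 0.005, 0L)
  interior <- 3:512   # deep enough tail, away from smoothing edge

  lin <- estimate_attenuation(fr, method = "linear", smooth = c(0, 0), noise_floor = 0)
  expect_true(all(abs(lin$mu[1, interior] / 1.010101 - 1) < 0.02))
  expect_equal(lin$mu[1, 3], 1.010101, tolerance = 1e-3)

  ex <- estimate_attenuation(fr, method = "exact", smooth = c(0, 0), noise_floor = 0)
  # finite-tail truncation adds ~ r^(n-j) relative bias, here ~ 3.5e-5
  expect_equal(ex$mu[1, 3], log(1 / 0.99) / 0.01, tolerance = 1e-4)
  expect_true(all(abs(ex$mu[1, interior] / 1.010101 - 1) < 0.02))

  # defaults (smoothing on) leave the interior untouched: a depth boxcar
  # preserves exponential decay rates
  def <- estimate_attenuation(fr, noise_floor = 0)
  expect_equal(def$mu[1, interior], ex$mu[1, interior], tolerance = 1e-6)
})

test_that("Beer-Lambert forward line is recovered without bias", {
  line <- 1000 * exp(-2 * 0.6 * (0:2047) * 0.005)
  fr <- polar_frame(matrix(line, nrow = 1), 0.005, 0L)
  ex <- estimate_attenuation(fr, noise_floor = 0)
  expect_equal(median(ex$mu[1, ], na.rm = TRUE), 0.6, tolerance = 0.02 * 0.6)
  # linearised form carries the documented discrete-sum bias ~ (e^{2 mu dz}-1)/(2 mu dz)
  lin <- estimate_attenuation(fr, method = "linear", noise_floor = 0)
  bias <- median(lin$mu[1, ], na.rm = TRUE) / 0.6
  expect_gt(bias, 1.0); expect_lt(bias, 1.01)
})

test_that("validity mask: zero lines, catheter region, tail guard", {
  I <- matrix(0, 3, 100)
  I[2, ] <- 1000 * exp(-2 * 1 * (0:99) * 0.005)
  fr <- polar_frame(I, 0.005, catheter_offset = 10L)
  att <- expect_no_error(estimate_attenuation(fr, noise_floor = 0, smooth = c(0, 0)))
  expect_false(any(att$valid[1, ]))               # all-zero A-line
  expect_false(any(att$valid[3, ]))
  expect_false(any(att$valid[, 1:10]))            # catheter interior
  expect_false(any(att$valid[, 91:100]))          # deepest 10% guarded
  expect_true(all(att$valid[2, 11:90]))
  expect_true(all(is.na(att$mu[!att$valid])))
  expect_true(all(att$mu[att$valid] >= 0))
})

test_that("monotone recovery across true mu values, noiseless", {
  meds <- vapply(c(0.5, 1, 2, 4), function(mu) {
    fr <- beer_lambert_frame(mu, n_alines = 4L)
    median(estimate_attenuation(fr, noise_floor = 0)$mu, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_true(all(abs(meds / c(0.5, 1, 2, 4) - 1) < 0.05))
})

test_that("speckle robustness: median over a large region within 10%", {
  set.seed(2024)
  fr <- beer_lambert_frame(1.5, n_alines = 32L, n_depth = 2048L, speckle = TRUE)
  att <- estimate_attenuation(fr, noise_floor = 0)
  region <- att$mu[, 101:800]                      # > 1000 homogeneous pixels
  expect_gt(sum(is.finite(region)), 1000)
  expect_lt(abs(median(region, na.rm = TRUE) / 1.5 - 1), 0.10)
})

test_that("extrapolated-tail mode removes the truncation bias deep down", {
  I <- matrix(1000 * 0.99^(0:511), nrow = 1)
  fr <- polar_frame(I, 0.005, 0L)
  guard <- estimate_attenuation(fr, method = "linear", smooth = c(0, 0),
                                noise_floor = 0, tail_guard_fraction = 0.1)
  extr <- estimate_attenuation(fr, method = "linear", smooth = c(0, 0),
                               noise_floor = 0, tail_guard_fraction = 0.1,
                               tail_mode = "extrapolate")
  j <- 440  # near the guard boundary, truncation inflates the plain estimate
  expect_gt(guard$mu[1, j] / 1.010101, 1.10)
  expect_equal(extr$mu[1, j], 1.010101, tolerance = 0.01)
})

test_that("backscatter: constancy, decade shift, gain offset", {
  mk <- function(beta) {
    line <- 1023 * beta * 1.5 * exp(-2 * 1.5 * (0:511) * 0.005)
    polar_frame(matrix(rep(line, 8), nrow = 8, byrow = TRUE), 0.005, 0L)
  }
  f1 <- mk(0.1)
  a1 <- estimate_attenuation(f1, noise_floor = 0)
  b1 <- estimate_backscatter(f1, a1)
  v <- b1$b[1, 10:400]
  expect_lt((max(v) - min(v)) / abs(mean(v)), 0.01)   # constant along depth

  f2 <- mk(1.0)
  b2 <- estimate_backscatter(f2, estimate_attenuation(f2, noise_floor = 0))
  expect_equal(mean(b2$b[1, 10:400]) - mean(v), 1.0, tolerance = 1e-9)

  b0 <- estimate_backscatter(f1, a1, gain = 0)
  d <- b1$b - b0$b
  expect_equal(range(d[b1$valid]), c(5, 5))
})

test_that("scale equivariance: mu invariant, b shifts by log10(c)", {
  set.seed(77)
  base <- beer_lambert_frame(1.0, n_alines = 8L, n_depth = 512L, speckle = TRUE)
  a0 <- estimate_attenuation(base, noise_floor = 0)
  b0 <- estimate_backscatter(base, a0)
  for (c in c(0.1, 3, 37)) {
    fr <- polar_frame(base$intensity * c, base$axial_pitch_mm, base$catheter_offset)
    a <- estimate_attenuation(fr, noise_floor = 0)
    b <- estimate_backscatter(fr, a)
    expect_equal(a$mu, a0$mu, tolerance = 1e-9)
    expect_equal(b$b[b$valid], b0$b[b0$valid] + log10(c), tolerance = 1e-9)
  }
})

test_that("shadow emergence: a high-mu layer lowers deep estimates", {
  with_layer <- simulate_frame(phantom_spec(class = "red", seed = 11))
  without <- simulate_frame(phantom_spec(class = "red", mu_thrombus = 0.01,
                                         beta_thrombus = 0.001, seed = 11))
  deep <- 240:400   # wall zone behind the thrombus arc
  rows <- 65:192
  mu_shadowed <- median(estimate_attenuation(with_layer$frame)$mu[rows, deep], na.rm = TRUE)
  mu_open <- median(estimate_attenuation(without$frame)$mu[rows, deep], na.rm = TRUE)
  expect_lt(mu_shadowed, mu_open)
})

test_that("mu cap bounds speckle outliers and backscatter contract holds", {
  set.seed(5)
  fr <- beer_lambert_frame(4, n_alines = 8L, n_depth = 1024L, speckle = TRUE)
  att <- estimate_attenuation(fr, noise_floor = 0, mu_cap = 6)
  expect_lte(max(att$mu, na.rm = TRUE), 6)
  bsc <- estimate_backscatter(fr, att)
  expect_true(all(is.finite(bsc$b[bsc$valid])))
  other <- polar_frame(fr$intensity, 0.005, 0L, frame_id = "other")
  expect_error(estimate_backscatter(other, att), class = "octhrombus_validation_error")
})
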