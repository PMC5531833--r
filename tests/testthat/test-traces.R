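make_movie <- function(frames, rate = 10) movie(frames, rate)

test_that("ROI traces are per-frame means over the mask", {
  fr <- array(7, dim = c(5, 4, 4))
  mov <- make_movie(fr)
  roi <- matrix(TRUE, 4, 4)
  expect_equal(extract_trace(mov, roi)$values, rep(7, 5))

  fr2 <- array(0, dim = c(3, 2, 2))
  fr2[, 1, 1] <- c(1, 2, 3)
  fr2[, 2, 2] <- c(9, 9, 9)
  one <- matrix(FALSE, 2, 2); one[1, 1] <- TRUE
  expect_equal(extract_trace(make_movie(fr2), one)$values, c(1, 2, 3))

  fr3 <- array(0, dim = c(4, 1, 2))
  fr3[, 1, 1] <- 4; fr3[, 1, 2] <- 6
  expect_equal(extract_trace(make_movie(fr3), matrix(TRUE, 1, 2))$values,
               rep(5, 4))
  expect_error(extract_trace(mov, matrix(FALSE, 4, 4)), "empty")
})

test_that("rigid registration recovers, clamps, and leaves static movies alone", {
  base <- matrix(0, 16, 16)
  base[6:9, 6:9] <- 100
  drift_movie <- function(d_per_frame, n = 5) {
    fr <- array(0, dim = c(n, 16, 16))
    for (t in seq_len(n)) {
      dx <- (t - 1) * d_per_frame
      fr[t, , ] <- 0
      fr[t, 6:9, (6 + dx):(9 + dx)] <- 100
    }
    make_movie(fr)
  }
  mc <- motion_correct(drift_movie(1), max_shift = 5)
  expect_equal(mc$shifts[, "dx"], -(0:4))
  expect_equal(mc$shifts[, "dy"], rep(0L, 5))
  # corrected movie is static
  expect_equal(mc$movie$frames[5, , ], mc$movie$frames[1, , ])

  fr_static <- array(0, dim = c(4, 16, 16))
  for (t in 1:4) fr_static[t, , ] <- base
  mc0 <- motion_correct(make_movie(fr_static), max_shift = 3)
  expect_true(all(mc0$shifts == 0))

  # drift of 2 px/frame exceeds max_shift = 3 by frame 3: shifts clamp
  mc2 <- motion_correct(drift_movie(2, n = 4), max_shift = 3)
  expect_equal(mc2$shifts[, "dx"], c(0, -2, -3, -3))
})

test_that("baseline window selection matches brute force and handles ties", {
  x <- c(rep(50, 10), 100 + 7 * sin(1:40))
  b <- compute_f0(trace(x, 1))
  expect_equal(b$f0, 50)
  expect_equal(b$window_start, 1)

  flat <- compute_f0(trace(rep(100, 30), 1))
  expect_equal(flat$f0, 100)
  expect_equal(flat$window_start, 1)   # earliest wins ties

  set.seed(12)
  y <- 100 + rnorm(50, 0, 10)
  y[23:32] <- 80 + rnorm(10, 0, 0.01)  # interior quiet patch
  got <- compute_f0(trace(y, 1))
  ora <- brute_f0(y, 10)
  expect_equal(got$window_start, ora$window_start)
  expect_equal(got$f0, ora$f0)
  expect_error(compute_f0(trace(1:5, 1)), "shorter")
  expect_error(compute_f0(trace(rep(-3, 15), 1)), "positive")
})

test_that("dff transforms and inverts exactly", {
  tr <- trace(c(100, 150, 80, 100), 2)
  d <- dff(tr, f0 = 100)
  expect_equal(d$values, c(0, 0.5, -0.2, 0))
  expect_equal(dff_inverse(d)$values, tr$values)
  expect_error(dff(tr, f0 = 0), "f0")
  # automatic baseline: constant trace equal to F0 gives zeros
  z <- dff(trace(rep(70, 20), 1))
  expect_equal(z$values, rep(0, 20))
  expect_equal(z$f0, 70)
  # round trip with estimated baseline
  set.seed(4)
  noisy <- trace(100 + abs(rnorm(40, 0, 5)), 1)
  expect_equal(dff_inverse(dff(noisy))$values, noisy$values)
})

test_that("normalize01 attains both bounds and respects negation symmetry", {
  expect_equal(normalize01(trace(c(2, 4, 6), 1))$values, c(0, 0.5, 1))
  ramp <- trace(seq(0, 1, length.out = 11), 1)
  expect_equal(normalize01(ramp)$values, ramp$values)
  x <- trace(c(3, -1, 7, 2), 1)
  expect_equal(normalize01(trace(-x$values, 1))$values,
               1 - normalize01(x)$values)
  expect_error(normalize01(trace(rep(5, 4), 1)), "constant")
})

test_that("pearson handles identity, negation, orthogonality, and constants", {
  t_s <- seq(0, 10 - 0.1, by = 0.1)
  a <- trace(sin(2 * pi * t_s / 2), 10)
  b <- trace(cos(2 * pi * t_s / 2), 10)
  expect_equal(pearson(a, a), 1)
  expect_equal(pearson(a, trace(-a$values, 10)), -1)
  expect_lt(abs(pearson(a, b)), 1e-10)   # integer number of periods
  expect_true(is.na(pearson(a, trace(rep(1, length(t_s)), 10))))
})

test_that("correlation maps recover signs and mark undefined pixels", {
  t_s <- 0:59
  ref <- sin(2 * pi * t_s / 20)
  fr <- array(0, dim = c(60, 4, 4))
  for (i in 1:4) for (j in 1:4) {
    fr[, i, j] <- if (i <= 2) ref else -ref
  }
  fr[, 1, 4] <- 5  # constant pixel
  cm <- correlation_map(make_movie(fr, 1), trace(ref, 1))
  expect_true(is.na(cm$r[1, 4]))
  expect_equal(cm$r[2, 2], 1)
  expect_equal(cm$r[4, 4], -1)
  expect_true(all(abs(cm$r[!is.na(cm$r)]) <= 1))
  expect_error(correlation_map(make_movie(fr, 1), trace(ref[1:10], 1)),
               "length")
  # every pixel = ref + independent noise: all defined entries positive
  set.seed(8)
  fr2 <- array(rep(ref, 16), dim = c(60, 4, 4)) +
    array(rnorm(60 * 16, 0, 0.1), dim = c(60, 4, 4))
  cm2 <- correlation_map(make_movie(fr2, 1), trace(ref, 1))
  expect_true(all(cm2$r > 0))
})

test_that("cycle length finds spectral peaks and matches a direct DFT", {
  tr <- trace(sin(2 * pi * (0:199) / 20), 1)
  est <- cycle_length(tr)
  expect_equal(est$period, 20)

  # square wave, period 71 s at 1.5 Hz, six cycles
  t_s <- (0:638) / 1.5
  sq <- trace(as.numeric(t_s %% 71 < 35.5), 1.5)
  est2 <- cycle_length(sq)
  bin <- 1.5 / length(sq$values)
  expect_lte(abs(est2$frequency - 1 / 71), bin)

  set.seed(9)
  wn <- trace(rnorm(128), 4)
  expect_equal(cycle_length(wn)$frequency,
               brute_dft_peak(wn$values, 4)$frequency)
  expect_error(cycle_length(trace(rep(2, 50), 1)), "constant")
  expect_error(cycle_length(trace(1:5, 1)), "8 frames")
})

test_that("cycle length is invariant to affine transforms of the trace", {
  set.seed(10)
  tr <- trace(100 + 40 * sin(2 * pi * (0:299) / 47) + rnorm(300), 1)
  base <- cycle_length(tr)
  shifted <- cycle_length(trace(3.7 * tr$values - 250, 1))
  expect_equal(shifted$frequency, base$frequency)
  expect_equal(shifted$period, base$period)
})

test_that("cohort summaries report median, band fraction, and histogram", {
  mk <- function(p) trace(sin(2 * pi * (0:(20 * p - 1)) / p), 1)
  s <- cycle_length_summary(list(mk(60), mk(71), mk(90)))
  expect_equal(s$median_period, 71)
  expect_equal(s$fraction_in_band, 1)
  s2 <- cycle_length_summary(list(mk(40), mk(71), mk(120)))
  expect_equal(s2$fraction_in_band, 1 / 3)
  expect_equal(sum(s2$histogram$count), 3)
  expect_error(cycle_length_summary(list(trace(rep(1, 50), 1))), "constant")
})

test_that("derivatives are exact on ramps and bounded on sines", {
  expect_equal(derivative(trace(2 * (0:9), 1))$values, rep(2, 10))
  expect_equal(derivative(trace(rep(5, 10), 1))$values, rep(0, 10))
  f <- 0.05; rate <- 1
  t_s <- (0:199) / rate
  d <- derivative(trace(sin(2 * pi * f * t_s), rate))
  analytic <- 2 * pi * f * cos(2 * pi * f * t_s)
  err <- abs(d$values - analytic)[2:199]
  expect_lt(max(err), 2 * (pi * f / rate)^2)
  expect_error(derivative(trace(c(1, 2), 1)), "3 frames")
})
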