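test_that("APDs of a synthetic triangular AP match closed-form values", {
  # instant upstroke over 1 ms from -80 to +20, linear repolarization
  # over 100 ms back to -80: APDx = 1 + x% of 100 ms (measured from the
  # dV/dt-max instant at the upstroke midpoint, amplitude 100 mV)
  t_up <- seq(0, 1, by = 0.5)
  t_down <- seq(1.5, 101, by = 0.5)
  tt <- c(t_up, t_down, seq(101.5, 200, by = 0.5))
  V <- c(-80 + 100 * t_up, 20 - (t_down - 1), rep(-80, length(tt) -
           length(t_up) - length(t_down)))
  tr <- cbind(time = tt, V = V)
  m <- compute_beat_metrics(tr, 0)
  expect_true(m$has_ap)
  expect_equal(m$apd25, 25.5, tolerance = 1)
  expect_equal(m$apd50, 50.5, tolerance = 1)
  expect_equal(m$apd90, 90.5, tolerance = 1)
  expect_equal(m$resting_potential, -80)
})

test_that("beat metrics agree with a naive re-scan of the sampled trace", {
  st <- steady_of("wt")
  tr <- st$trace
  m <- compute_beat_metrics(tr, 0)
  V <- tr[, "V"]; tt <- tr[, "time"]
  dv <- diff(V) / diff(tt)
  i_up <- which.max(dv)
  expect_equal(m$dvdt_max, max(dv))
  v_peak <- max(V)
  amp <- v_peak - min(V[tt >= tt[i_up] - 20 & tt <= tt[i_up]])
  expect_equal(m$ap_amplitude, amp)
  # brute-force APD90: first sample after the peak below the 90% level
  lev <- v_peak - 0.9 * amp
  i_pk <- which.max(V)
  k <- i_pk + which(V[i_pk:length(V)] <= lev)[1] - 1
  expect_lt(abs((tt[k] - tt[i_up]) - m$apd90), 1)
  expect_equal(m$cat_amplitude, max(tr[, "Ca_i"]) - min(tr[1:i_up, "Ca_i"]))
})

test_that("halving the sampling interval moves APDs by less than a millisecond", {
  st <- steady_of("wt")
  p <- st$params
  y <- st$state
  m1 <- compute_beat_metrics(run_cell(y, 1000, p, dt = 0.5), 0)
  m2 <- compute_beat_metrics(run_cell(y, 1000, p, dt = 0.25), 0)
  expect_lt(abs(m1$apd90 - m2$apd90), 1)
  expect_lt(abs(m1$apd50 - m2$apd50), 1)
})

test_that("no-AP beats are flagged absent rather than zero", {
  tt <- seq(0, 500, by = 0.5)
  tr <- cbind(time = tt, V = rep(-80, length(tt)))
  m <- compute_beat_metrics(tr, 0)
  expect_false(m$has_ap)
  expect_true(is.na(m$apd90))
})

test_that("the steady-state criterion is strict and matches its formula", {
  expect_true(steady_state_check(c(a = 1, b = 2), c(a = 1, b = 2),
                                 c(a = 1, b = 2)))
  # boundary: a change of exactly 1e-5 of basal fails the strict test
  expect_false(steady_state_check(c(a = 1), c(a = 1 + 1e-5), c(a = 1)))
  expect_error(steady_state_check(c(a = 1), c(a = 1), c(a = 0)), "non-zero")
  set.seed(9)
  for (i in 1:1000) {
    k <- stats::runif(4, 0.5, 2)
    k1 <- k * (1 + stats::rnorm(4, 0, 2e-5))
    basal <- stats::runif(4, 0.5, 2)
    expect_identical(steady_state_check(k, k1, basal),
                     max(abs(k1 - k) / basal) < 1e-5)
  }
})

test_that("the DAD detector recovers injected events exactly", {
  tt <- seq(0, 20000, by = 0.5)
  V <- rep(-80, length(tt))
  # paced APs every 1000 ms (skinny 30 ms triangles)
  stim <- seq(0, 19000, by = 1000)
  for (s in stim) {
    idx <- tt >= s & tt < s + 30
    V[idx] <- -80 + 100 * (1 - abs(tt[idx] - s - 15) / 15)
  }
  # injected DADs: 12 mV bumps at known diastolic times
  inj <- c(2400, 5600, 11300, 17650)
  for (s in inj) {
    idx <- tt >= s & tt < s + 120
    V[idx] <- V[idx] + 12 * sin(pi * (tt[idx] - s) / 120)^2
  }
  # sub-threshold bumps that must NOT be detected
  sub <- c(3500, 9500)
  for (s in sub) {
    idx <- tt >= s & tt < s + 120
    V[idx] <- V[idx] + 2 * sin(pi * (tt[idx] - s) / 120)^2
  }
  got <- detect_dads(cbind(time = tt, V = V), stim)
  expect_equal(nrow(got$dads), length(inj))
  expect_true(all(abs(sort(got$dads$time) - (inj + 60)) < 5))
  expect_equal(nrow(got$triggered), 0)
})

test_that("a flat diastolic trace yields no events", {
  tt <- seq(0, 5000, by = 0.5)
  got <- detect_dads(cbind(time = tt, V = rep(-82, length(tt))),
                     stim_times = c(0))
  expect_equal(nrow(got$dads), 0)
})
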