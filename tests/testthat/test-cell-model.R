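test_that("the unstimulated cell sits at a genuine resting point", {
  p <- cell_params()
  y <- cell_initial_state(p)
  tr <- run_cell(y, 10000, p, dt = 10)
  yq <- tr[nrow(tr), cell_state_names()]
  d <- cell_derivatives(yq, 0, p)
  expect_lt(abs(d$deriv[["V"]]), 1e-3)
})

test_that("the resting potential holds within 0.5 mV over a minute", {
  p <- cell_params()
  y <- cell_initial_state(p)
  tr <- run_cell(y, 10000, p, dt = 10)
  y <- tr[nrow(tr), cell_state_names()]
  tr2 <- run_cell(y, 60000, p, dt = 20)
  expect_lt(diff(range(tr2[, "V"])), 0.5)
})

test_that("whole-cell Ca bookkeeping closes over a paced beat in every variant", {
  for (preset in c("wt", "oe", "oe_ros")) {
    st <- steady_of(preset)
    audit <- calcium_audit(st$trace, st$params)
    expect_lt(audit$rel_error, 1e-3)
  }
})

test_that("wild-type pacing reaches the one-hundred-thousandth criterion", {
  st <- steady_of("wt")
  expect_true(st$converged)
  m <- st$metrics
  expect_true(m$has_ap)
  expect_true(m$apd25 < m$apd50 && m$apd50 < m$apd90)
})

test_that("APD90 shortens at 10 Hz relative to 1 Hz (rate adaptation)", {
  st <- steady_of("wt")
  b <- burst_of("wt")
  tr <- b$trace
  # a late burst cycle, well into rate adaptation
  sel <- tr[, "time"] >= 13800 & tr[, "time"] < 13900
  m10 <- compute_beat_metrics(tr[sel, , drop = FALSE], 13800)
  expect_true(m10$has_ap)
  expect_lt(m10$apd90, st$metrics$apd90)
})

test_that("six-fold CaMKII raises phosphorylation of all targets and [Na+]i", {
  wt <- steady_of("wt"); oe <- steady_of("oe")
  expect_gt(oe$state[["phos_LTCC"]], wt$state[["phos_LTCC"]])
  expect_gt(oe$state[["phos_PLB"]], wt$state[["phos_PLB"]])
  expect_gt(oe$state[["phos_RyR"]], wt$state[["phos_RyR"]])
  expect_gt(oe$state[["Na_i"]], wt$state[["Na_i"]])
})

test_that("the compiled kinase block agrees with the R reference implementation", {
  p <- cell_params()
  kp <- kinase_params()
  set.seed(3)
  for (i in 1:50) {
    y <- cell_initial_state(p)
    kj <- random_kinase_state(runif)
    y[paste0("kj_", names(kj))] <- kj
    y["Ca_jn"] <- runif(1, 0.05, 80)
    d <- cell_derivatives(y, 0, p)
    # reconstruct the CaM drive the compiled side derives from junctional Ca
    ca <- y[["Ca_jn"]]
    x <- (ca / p[["KdCaM1"]])^2; yq <- (ca / p[["KdCaM2"]])^2
    den <- 1 + x + x * yq
    drv <- kinase_drive(Ca4CaM = p[["CaMtot_jn"]] * x * yq / den,
                        Ca2CaM = p[["CaMtot_jn"]] * x / den,
                        ROS = p[["ros"]])
    kp_loc <- kp
    kp_loc$camkii_total <- p[["camkii_tot_jn"]]
    dr <- kinase_derivatives(kj, drv, kp_loc) * 1e-3   # per s -> per ms
    expect_equal(unname(d$deriv[paste0("kj_", names(kj))]), unname(dr),
                 tolerance = 1e-10)
  }
})

test_that("integration is reproducible bit for bit", {
  p <- cell_params(stim_amp = 24, stim_tend = 2000)
  y <- cell_initial_state(p)
  tr1 <- run_cell(y, 2000, p)
  tr2 <- run_cell(y, 2000, p)
  expect_identical(tr1, tr2)
})

test_that("invalid states are rejected with a diagnostic", {
  p <- cell_params()
  y <- cell_initial_state(p)
  y["V"] <- NaN
  expect_error(cell_derivatives(y, 0, p), "non-finite")
})
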