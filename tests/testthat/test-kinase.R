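test_that("inherited and oxidation rate constants take their published defaults", {
  p <- kinase_params()
  expect_equal(p$k_bi, 2.2)
  expect_equal(p$k_ib, 2.2 / 33.5e-3)
  expect_equal(p$k_ox, 6.48e-6)
  expect_equal(p$Km_ROS, 60)
  expect_equal(p$Km_MsrA, 0.34)
  expect_equal(p$k_redox, 0.28)
  expect_error(kinase_params(k_ox = -1), ">= 0")
  expect_error(kinase_params(nonsense = 1), "unknown")
})

test_that("derivatives conserve total occupancy on random states and drives", {
  set.seed(11)
  p <- kinase_params()
  for (i in 1:1000) {
    s <- random_kinase_state(runif)
    d <- kinase_drive(Ca4CaM = runif(1, 0, 50), Ca2CaM = runif(1, 0, 50),
                      ROS = runif(1, 0, 500))
    expect_lt(abs(sum(kinase_derivatives(s, d, p))), 1e-11)
  }
})

test_that("zero ROS switches the oxidation pathway off exactly", {
  p <- kinase_params()
  set.seed(4)
  for (i in 1:25) {
    s <- random_kinase_state(runif)
    s[c("Pot", "Po")] <- 0
    s <- s / sum(s)
    d0 <- kinase_derivatives(s, kinase_drive(Ca4CaM = 2, Ca2CaM = 1, ROS = 0), p)
    # the six-state field: same params with the oxidation/reduction rates removed
    p6 <- kinase_params(k_ox = 0, k_redox = 0)
    d6 <- kinase_derivatives(s, kinase_drive(Ca4CaM = 2, Ca2CaM = 1, ROS = 0), p6)
    expect_equal(unname(d0), unname(d6), tolerance = 1e-14)
    expect_equal(unname(d0[["Pot"]]), 0)
    expect_equal(unname(d0[["Po"]]), 0)
  }
})

test_that("oxidation flux is half-maximal at [ROS] = Km_ROS", {
  p <- kinase_params()
  s <- kinase_state(Pi = 0, Pb = 1)
  d <- kinase_derivatives(s, kinase_drive(ROS = p$Km_ROS), p)
  # with no CaM drive and no active-state mass elsewhere, the only influx
  # into Pot is the oxidation flux k_ox / 2
  expect_equal(unname(d[["Pot"]]), 0.5 * p$k_ox, tolerance = 1e-12)
  expect_equal(unname(d[["Pot"]]), 3.24e-6, tolerance = 1e-9)
})

test_that("active fraction covers the four activation states and both oxidized states", {
  expect_equal(active_fraction(kinase_state(Pi = 1)), 0)
  expect_equal(active_fraction(kinase_state(Pi = 0, Po = 1)), 1)
  set.seed(7)
  for (i in 1:200) {
    s <- random_kinase_state(runif)
    expect_equal(active_fraction(s), 1 - s[["Pi"]] - s[["Pb2"]],
                 tolerance = 1e-12)
  }
})

test_that("steady state under zero drive is fully inactive", {
  s <- kinase_steady_state(kinase_drive(), kinase_params())
  expect_equal(unname(s[["Pi"]]), 1, tolerance = 1e-9)
})

test_that("integrated two-state oxidation balance matches the closed form", {
  # only Pb <-> Pot transitions: every other rate switched off
  p <- kinase_params(k_bi = 0, k_auto = 0, v_pp1 = 0, k_b2i = 0,
                     k_t_off = 0, k_t2_off = 0)
  p$k_ib <- 0
  for (r in c(20, 60, 200)) {
    a <- p$k_ox * r / (r + p$Km_ROS)
    b <- p$k_redox * p$MsrA_conc / (p$MsrA_conc + p$Km_MsrA)
    y0 <- kinase_state(Pi = 0, Pb = 1)
    rhs <- function(t, y, parms)
      list(kinase_derivatives(y, kinase_drive(ROS = r), p))
    sol <- deSolve::lsoda(y0, c(0, 1e9), rhs, parms = NULL,
                          rtol = 1e-12, atol = 1e-14)
    y <- sol[2, names(y0)]
    expect_equal(unname(y[["Pot"]] / (y[["Pb"]] + y[["Pot"]])),
                 a / (a + b), tolerance = 1e-6)
  }
})

test_that("steady active fraction grows with ROS and with CaM drive", {
  p <- kinase_params()
  act_ros <- camkii_dose_response(c(0, 10, 60, 200, 1000), p,
                                  ca4cam = 0.05, normalize = FALSE)$activity
  expect_true(all(diff(act_ros) >= -1e-9))
  act_cam <- vapply(c(0, 0.02, 0.1, 0.5, 2), function(c4)
    active_fraction(kinase_steady_state(kinase_drive(Ca4CaM = c4), p,
                                        tol = 1e-9)), numeric(1))
  expect_true(all(diff(act_cam) >= -1e-9))
})

test_that("dose-response fitting recovers the shipped oxidation parameters", {
  p <- kinase_params()
  ros <- c(0, 10, 25, 45, 70, 110, 200, 400, 1000)
  tab <- camkii_dose_response(ros, p)
  names(tab) <- c("ros_um", "activity_norm")
  fit <- fit_oxidation_params(tab, p)
  expect_lt(abs(fit$k_ox - p$k_ox) / p$k_ox, 0.01)
  expect_lt(abs(fit$Km_ROS - p$Km_ROS) / p$Km_ROS, 0.01)
  expect_false(fit$boundary)
})

test_that("fitting degrades gracefully on degenerate inputs", {
  flat <- data.frame(ros_um = c(0, 50, 200), activity_norm = c(0, 0, 0))
  fit <- fit_oxidation_params(flat)
  expect_true(fit$boundary)
  expect_error(fit_oxidation_params(
    data.frame(ros_um = c(50, 50, 50), activity_norm = c(0.1, 0.2, 0.3))),
    "degenerate")
  expect_error(fit_oxidation_params(
    data.frame(ros_um = c(0, 50), activity_norm = c(0, 1))), "3")
})

test_that("Km_ROS is recoverable from noisy dose-response data", {
  p <- kinase_params()
  ros <- c(0, 10, 25, 45, 70, 110, 200, 400, 1000)
  clean <- camkii_dose_response(ros, p)$activity
  set.seed(42)
  errs <- replicate(20, {
    noisy <- pmin(1, pmax(0, clean * (1 + rnorm(length(ros), 0, 0.05))))
    fit <- fit_oxidation_params(data.frame(ros_um = ros,
                                           activity_norm = noisy), p)
    abs(fit$Km_ROS - p$Km_ROS) / p$Km_ROS
  })
  expect_lt(median(errs), 0.25)
})
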