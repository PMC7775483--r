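test_that("restarting from a converged state converges within one beat", {
  st <- steady_of("wt")
  again <- pace_to_steady_state(scenario_presets("wt"), init = st$state)
  expect_true(again$converged)
  expect_lte(again$n_beats, 2)
})

test_that("clamped quantities stay exactly on their level", {
  cfg <- scenario_presets("wt")
  h <- camkatria:::ryr_hold(cfg, 450, 0.4, probe_mode = TRUE,
                            init = steady_of("wt"), hold_s = 2)
  p <- h$params
  y <- h$state
  tr <- run_cell(y, 1000, p, dt = 1)
  expect_lt(max(abs(tr[, "Ca_SR"] - 450)) / 450, 1e-9)
  expect_lt(max(abs(tr[, "phos_RyR"] - 0.4)), 1e-9)
})

test_that("clamping a variable at its own steady level leaves the beat unchanged", {
  st <- steady_of("wt")
  na0 <- unname(st$state["Na_i"])
  clamped <- clamp_experiment(scenario_presets("wt"), "na_i", na0,
                              init = NULL, recovery_s = 2)
  # compare the pre-burst 1 Hz beat against the unclamped steady beat
  tr <- clamped$trace
  b <- tr[tr[, "time"] >= 1000 & tr[, "time"] < 2000, , drop = FALSE]
  m <- compute_beat_metrics(b, 1000)
  expect_lt(abs(m$apd90 - st$metrics$apd90), 1.5)
  expect_lt(abs(m$ap_amplitude - st$metrics$ap_amplitude), 1.5)
})

test_that("without stimulus there are neither APs nor DADs", {
  cfg <- scenario_presets("wt")
  p <- cfg$params                      # stim_amp stays 0
  y <- preset_initial_state(cfg)
  tr <- run_cell(y, 5000, p, dt = 1)
  expect_lt(max(tr[, "V"]), -60)
  got <- detect_dads(tr, stim_times = seq(0, 4000, by = 1000))
  expect_equal(nrow(got$dads), 0)
})

test_that("the found activation threshold brackets the release criterion", {
  cfg <- scenario_presets("wt")
  res <- cached("thrB", ryr_threshold_search(cfg, 450, 0.4,
                                             init = steady_of("wt")))
  expect_false(res$always_open)
  expect_true(is.finite(res$threshold))
  expect_gte(res$released_frac, 0.25)
  # one resolution step below the threshold must fail the criterion
  below <- camkatria:::probe_release_fraction(cfg, 450, 0.4,
                                              res$threshold - 0.1,
                                              init = steady_of("wt"))
  expect_lt(below, 0.25)
})

test_that("bisection agrees with a linear amplitude scan", {
  cfg <- scenario_presets("wt")
  res <- cached("thrB", ryr_threshold_search(cfg, 450, 0.4,
                                             init = steady_of("wt")))
  amps <- seq(0.5, 6, by = 0.5)
  fr <- vapply(amps, function(a)
    camkatria:::probe_release_fraction(cfg, 450, 0.4, a,
                                       init = steady_of("wt")), numeric(1))
  first <- amps[which(fr >= 0.25)[1]]
  expect_lt(abs(first - res$threshold), 0.5 + 1e-9)
})

test_that("the high-load high-phosphorylation corner stays open with no stimulus", {
  cfg <- scenario_presets("wt")
  res <- ryr_threshold_search(cfg, 600, 0.6, init = steady_of("wt"))
  expect_true(res$always_open)
})

test_that("DAD counts are ordered wild type <= overexpression <= overexpression + ROS", {
  n <- vapply(c("wt", "oe", "oe_ros"), function(nm) nrow(burst_of(nm)$dads),
              numeric(1))
  expect_lte(n[["wt"]], n[["oe"]])
  expect_lte(n[["oe"]], n[["oe_ros"]])
})

test_that("identical configurations give identical protocol outputs", {
  a <- pace_to_steady_state(scenario_presets("wt"), max_beats = 30)
  b <- pace_to_steady_state(scenario_presets("wt"), max_beats = 30)
  expect_identical(a$state, b$state)
  expect_identical(a$metrics, b$metrics)
})

test_that("time to stability is reproducible from the stored per-beat series", {
  res <- cached("relB", release_after_unclamp(scenario_presets("wt"), 450, 0.4,
                                              init = steady_of("wt"),
                                              n_beats = 40))
  pk <- res$jrel_peaks
  # independent recomputation of the <1% sustained-variation rule
  rel <- abs(diff(pk)) / pmax(abs(pk[-length(pk)]), 1e-12)
  bad <- which(rel >= 0.01)
  expected <- if (!length(bad)) 0
  else if (max(bad) == length(rel)) Inf else max(bad)
  expect_equal(res$t_stab_s, expected)
  expect_equal(res$first_jrel, pk[1])
})

test_that("protocol preconditions are enforced", {
  cfg <- scenario_presets("wt")
  expect_error(ryr_threshold_search(cfg, 100, 0.4), "200")
  expect_error(ryr_threshold_search(cfg, 450, 0.95), "0.8")
})
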