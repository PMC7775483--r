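test_that("the overexpression recipe changes exactly the five published entries", {
  wt <- cell_params()
  oe <- apply_overexpression(wt)
  d <- params_diff(wt, oe)
  expect_setequal(d$name, c("camkii_tot_jn", "hL_vshift", "kf_to", "gK1", "vncx"))
  expect_equal(d$ratio[d$name == "camkii_tot_jn"], 6)
  expect_equal(oe[["hL_vshift"]] - wt[["hL_vshift"]], 6.8)
  expect_equal(d$ratio[d$name == "kf_to"], 5)
  expect_equal(d$ratio[d$name == "gK1"], 0.6)
  expect_equal(d$ratio[d$name == "vncx"], 1.3)
})

test_that("applying the recipe twice is rejected", {
  oe <- apply_overexpression(cell_params())
  expect_error(apply_overexpression(oe), "already applied")
})

test_that("zero ROS keeps the oxidized occupancies at zero for all time", {
  cfg <- scenario_presets("wt")
  expect_equal(cfg$params[["ros"]], 0)
  p <- cfg$params
  p["stim_amp"] <- 24; p["stim_tend"] <- 1e12
  y <- preset_initial_state(cfg)
  tr <- run_cell(y, 3000, p, dt = 5)
  ox <- tr[, c("kj_Pot", "kj_Po", "kc_Pot", "kc_Po")]
  expect_equal(max(abs(ox)), 0)
})

test_that("the ROS presets carry the pathophysiological level", {
  expect_equal(scenario_presets("oe_ros")$ros_um, 200)
  expect_equal(scenario_presets("wt_ros")$params[["ros"]], 200)
  expect_error(apply_ros(cell_params(), -5), ">= 0")
})

test_that("beat-averaged CaMKII activity is non-decreasing in ROS", {
  cfg <- scenario_presets("wt")
  avg <- vapply(c(0, 35, 200), function(r) {
    p <- apply_ros(cfg$params, r)
    p["stim_amp"] <- 24; p["stim_tend"] <- 1e12
    y <- preset_initial_state(cfg)
    if (r > 0) y <- equilibrate_oxidation(y, p)
    tr <- run_cell(y, 2000, p, dt = 2)
    mean(tr[tr[, "time"] >= 1000, "camkii_act_jn"])
  }, numeric(1))
  expect_true(all(diff(avg) > 0))
})

test_that("scenario construction is pure and serialization round-trips", {
  a <- scenario_presets("oe_ros")
  b <- scenario_presets("oe_ros")
  expect_identical(unclass(a$params), unclass(b$params))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  cfg <- scenario_config(variant = "CaMKII-OE", ros_um = 200,
                         clamps = list(na_i_mM = 12),
                         seed = 7L)
  write_scenario_json(cfg, f)
  back <- read_scenario_json(f)
  expect_equal(back$variant, cfg$variant)
  expect_equal(back$ros_um, cfg$ros_um)
  expect_equal(back$clamps, cfg$clamps)
  expect_equal(unclass(back$params), unclass(cfg$params), tolerance = 1e-12)
})

test_that("clamp levels outside the schema bounds are refused", {
  expect_error(scenario_config(clamps = list(na_i_mM = 50)), "bounds")
  expect_error(scenario_config(clamps = list(phos_RyR = 1.5)), "bounds")
  expect_error(scenario_config(clamps = list(banana = 1)), "unknown clamp")
})
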