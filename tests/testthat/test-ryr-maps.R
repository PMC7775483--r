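# small grids keep the map tests inside a few minutes; the qualitative
# structure (monotone thresholds, upper-right always-open region, balance
# region narrowing with phosphorylation) is scale-free

test_that("thresholds fall toward higher SR load and phosphorylation, ending always-open", {
  cfg <- scenario_presets("wt")
  map <- cached("thr_map",
                build_threshold_map(cfg, ca_sr_grid = c(300, 450, 600),
                                    phos_grid = c(0.2, 0.4, 0.6),
                                    init = steady_of("wt")))
  expect_true(all(is.na(map$error)))
  # treat always-open as threshold 0 and no-release as +Inf for ordering
  val <- ifelse(map$always_open, 0, map$threshold_pApF)
  m <- matrix(val, nrow = 3)        # rows: ca_sr, cols: phos
  for (j in 1:3) expect_true(all(diff(m[, j]) <= 1e-9))
  for (i in 1:3) expect_true(all(diff(m[i, ]) <= 1e-9))
  # always-open region is upper-right connected
  ao <- matrix(map$always_open, nrow = 3)
  for (i in 1:3) for (j in 1:3) if (ao[i, j]) {
    expect_true(all(ao[i:3, j:3]))
  }
  expect_true(ao[3, 3])
})

test_that("the balance region narrows as RyR phosphorylation rises", {
  cfg <- scenario_presets("wt")
  rel <- cached("rel_map",
                build_release_map(cfg, ca_sr_grid = seq(250, 650, by = 100),
                                  phos_grid = c(0.2, 0.4, 0.6),
                                  init = steady_of("wt"), n_beats = 1))
  expect_true(all(is.na(rel$error)))
  width <- tapply(rel$in_balance, rel$phos_ryr, sum)
  expect_true(all(diff(width) <= 0))
  expect_gt(width[[1]], 0)
})

test_that("always-open cells lie outside the balance region", {
  map <- cached("thr_map",
                build_threshold_map(scenario_presets("wt"),
                                    ca_sr_grid = c(300, 450, 600),
                                    phos_grid = c(0.2, 0.4, 0.6),
                                    init = steady_of("wt")))
  rel3 <- cached("rel_map3",
                 build_release_map(scenario_presets("wt"),
                                   ca_sr_grid = c(300, 450, 600),
                                   phos_grid = c(0.2, 0.4, 0.6),
                                   init = steady_of("wt"), n_beats = 1))
  ao <- map$always_open
  expect_true(all(!rel3$in_balance[ao]))
})

test_that("maps are reproducible", {
  cfg <- scenario_presets("wt")
  a <- build_threshold_map(cfg, ca_sr_grid = c(450), phos_grid = c(0.4),
                           init = steady_of("wt"))
  b <- build_threshold_map(cfg, ca_sr_grid = c(450), phos_grid = c(0.4),
                           init = steady_of("wt"))
  expect_identical(a, b)
})
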