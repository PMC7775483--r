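#' Run a scenario protocol and write its outputs
#'
#' Loads or builds a scenario configuration, executes the requested
#' protocol, and writes traces (CSV), metrics/summary (JSON), and a run
#' manifest (JSON: configuration hash, solver settings, output inventory,
#' wall time, convergence flags).
#'
#' @param scenario a preset name (see [scenario_presets()]), a path to a
#'   scenario JSON file, or a `scenario_config`.
#' @param protocol one of `"steady"`, `"burst"`, `"clamp"`, `"threshold"`,
#'   `"release-map"`.
#' @param outdir output directory (created if needed).
#' @param clamp,level clamp target and level for `protocol = "clamp"`.
#' @param ca_sr_grid,phos_grid grid for the map protocols.
#' @param trace_cols trace columns written to CSV.
#' @return the manifest, invisibly.
#' @export
run_scenario <- function(scenario, protocol = c("steady", "burst", "clamp",
                                                "threshold", "release-map"),
                         outdir = ".", clamp = "phos_RyR", level = NULL,
                         ca_sr_grid = seq(200, 800, by = 100),
                         phos_grid = seq(0.1, 0.8, by = 0.1),
                         trace_cols = c("time", "V", "Ca_i", "Ca_SR",
                                        "Na_i", "camkii_act_jn",
                                        "phos_LTCC", "phos_PLB", "phos_RyR",
                                        "J_rel", "J_up")) {
  protocol <- match.arg(protocol)
  cfg <- if (inherits(scenario, "scenario_config")) scenario
  else if (is.character(scenario) && file.exists(scenario))
    read_scenario_json(scenario)
  else scenario_presets(scenario)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  files <- character(0)
  converged <- TRUE
  summary <- list()

  wtrace <- function(tr, name) {
    f <- file.path(outdir, name)
    utils::write.csv(as.data.frame(tr[, intersect(trace_cols, colnames(tr)),
                                      drop = FALSE]),
                     f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (protocol == "steady") {
    res <- pace_to_steady_state(cfg)
    converged <- res$converged
    wtrace(res$trace, "steady_final_beat.csv")
    summary <- c(res$metrics[c("apd25", "apd50", "apd90", "ap_amplitude",
                               "dvdt_max", "resting_potential",
                               "cat_amplitude", "diastolic_ca")],
                 list(n_beats = res$n_beats, converged = res$converged))
  } else if (protocol %in% c("burst", "clamp")) {
    res <- if (protocol == "burst") burst_protocol(cfg)
    else clamp_experiment(cfg, clamp, level)
    converged <- res$init$converged
    wtrace(res$trace, "burst_trace.csv")
    f <- file.path(outdir, "dad_events.json")
    jsonlite::write_json(res$dads, f, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, f)
    summary <- list(n_dads = nrow(res$dads),
                    n_triggered = nrow(res$triggered))
  } else if (protocol == "threshold") {
    map <- build_threshold_map(cfg, ca_sr_grid, phos_grid)
    f <- file.path(outdir, "threshold_map.csv")
    utils::write.csv(map, f, row.names = FALSE)
    files <- c(files, f)
    summary <- list(n_always_open = sum(map$always_open),
                    n_cells = nrow(map))
  } else {
    map <- build_release_map(cfg, ca_sr_grid, phos_grid)
    f <- file.path(outdir, "release_map.csv")
    utils::write.csv(map, f, row.names = FALSE)
    files <- c(files, f)
    summary <- list(n_in_balance = sum(map$in_balance),
                    n_cells = nrow(map))
  }

  manifest <- list(
    protocol = protocol,
    variant = cfg$variant, ros_um = cfg$ros_um, clamps = cfg$clamps,
    config_hash = config_hash(cfg),
    solver = cfg$solver, seed = cfg$seed,
    outputs = basename(files),
    wall_time_s = round(proc.time()[["elapsed"]] - t0, 2),
    converged = converged,
    summary = summary)
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# stable hash of the resolved configuration (parameters + clamps + solver)
#' @keywords internal
config_hash <- function(cfg) {
  s <- paste(
    cfg$variant, cfg$ros_um,
    paste(names(cfg$clamps), unlist(cfg$clamps), collapse = ";"),
    paste(names(cfg$params), format(unclass(cfg$params), digits = 17),
          collapse = ";"),
    paste(names(cfg$solver), unlist(cfg$solver), collapse = ";"),
    sep = "|")
  # 31-bit polynomial rolling hash, dependency-free
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Generate regression fixtures
#'
#' Produces the short reference artifacts used by the regression tests:
#' a 5-beat 1 Hz voltage/Ca trace per preset (sampled at 1 ms) and a
#' kinase-only steady-state table at ROS 0 / 60 / 200 uM. Regeneration on
#' unchanged code is byte-identical.
#'
#' @param outdir output directory.
#' @param beats beats per preset trace.
#' @return character vector of written files, invisibly.
#' @export
generate_fixtures <- function(outdir, beats = 5) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in scenario_presets()) {
    cfg <- scenario_presets(nm)
    p <- cfg$params
    p["stim_amp"] <- default_stim()["amp"]
    p["stim_dur"] <- default_stim()["dur"]
    p["stim_period"] <- 1000
    p["stim_t0"] <- 0; p["stim_tend"] <- 1e12
    y <- preset_initial_state(cfg)
    if (cfg$ros_um > 0) y <- equilibrate_oxidation(y, p)
    tr <- run_cell(y, beats * 1000, p, dt = 1)
    keep <- c("time", "V", "Ca_i", "Ca_SR", "Na_i", "camkii_act_jn",
              "phos_LTCC", "phos_PLB", "phos_RyR", "J_rel", "J_up")
    f <- file.path(outdir, paste0("trace_", nm, ".csv"))
    df <- as.data.frame(round(tr[, keep], 6))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  # kinase-only steady states under a fixed CaM drive
  kp <- kinase_params()
  rows <- lapply(c(0, 60, 200), function(r) {
    s <- kinase_steady_state(kinase_drive(Ca4CaM = 0.1, ROS = r), kp)
    data.frame(ros_um = r, t(as.numeric(s)),
               active_fraction = active_fraction(s))
  })
  tab <- do.call(rbind, rows)
  names(tab)[2:9] <- c("Pi", "Pb", "Pt", "Pt2", "Pa", "Pb2", "Pot", "Po")
  tab[, 2:10] <- round(tab[, 2:10], 10)
  f <- file.path(outdir, "kinase_steady_states.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
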