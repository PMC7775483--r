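#' @keywords internal
default_stim <- function() c(amp = 24, dur = 2)   # pA/pF, ms

# Apply the configured clamps to a (params, state) pair.
#' @keywords internal
apply_clamps <- function(params, y, clamps) {
  map <- list(na_i_mM = c("clamp_nai", "Na_i"),
              ca_sr_um = c("clamp_casr", "Ca_SR"),
              phos_LTCC = c("clamp_pL", "phos_LTCC"),
              phos_PLB = c("clamp_pP", "phos_PLB"),
              phos_RyR = c("clamp_pR", "phos_RyR"))
  for (nm in names(clamps)) {
    params[map[[nm]][1]] <- clamps[[nm]]
    y[map[[nm]][2]] <- clamps[[nm]]
  }
  list(params = params, y = y)
}

#' Pre-equilibrate the slow CaMKII oxidation pool
#'
#' The oxidation/reduction pair operates orders of magnitude slower than
#' every electrophysiological process, so over any simulated protocol the
#' oxidized mass is effectively a constant set by the ROS exposure history.
#' This helper imposes the equilibrium directly: it paces a few beats to
#' measure the time-averaged calmodulin-bound occupancy, solves the slow
#' pool's balance X = a*phi*(1-X) / b for the oxidized mass X (a: oxidation
#' rate at the configured ROS, b: effective MsrA reduction rate, phi:
#' CaM-bound occupancy per unit non-oxidized mass), and rescales the state.
#'
#' @param y state vector.
#' @param params cell parameters (with `ros` set).
#' @param freq_hz pacing frequency used for the probe beats.
#' @param n_beats number of probe beats for the time average.
#' @param iterations fixed-point refinements.
#' @return state vector with the oxidized pool at equilibrium.
#' @export
equilibrate_oxidation <- function(y, params, freq_hz = 1, n_beats = 4,
                                  iterations = 2) {
  ros <- unname(params["ros"])
  kin_j <- paste0("kj_", c("Pi", "Pb", "Pt", "Pt2", "Pa", "Pb2", "Pot", "Po"))
  kin_c <- sub("kj", "kc", kin_j)
  a <- unname(params["kox"] * ros / (ros + params["KmROS"]))
  b <- unname(params["kredox"] * params["MsrA"] /
                (params["MsrA"] + params["KmMsrA"]))
  if (ros <= 0 || a <= 0) {
    y[c("kj_Pot", "kj_Po", "kc_Pot", "kc_Po")] <- 0
    return(y)
  }
  period <- 1000 / freq_hz
  for (it in seq_len(iterations)) {
    p <- params
    p["stim_amp"] <- default_stim()["amp"]
    p["stim_dur"] <- default_stim()["dur"]
    p["stim_period"] <- period
    p["stim_t0"] <- 0; p["stim_tend"] <- n_beats * period
    tr <- run_cell(y, n_beats * period, p, dt = 2)
    sel <- tr[, "time"] >= (n_beats - 2) * period   # last two beats
    for (blk in list(kin_j, kin_c)) {
      pb_bar <- mean(tr[sel, blk[2]])
      x_cur <- mean(tr[sel, blk[7]] + tr[sel, blk[8]])
      phi <- pb_bar / max(1 - x_cur, 1e-9)
      x_new <- a * phi / (a * phi + b)
      yk <- y[blk]
      x0 <- yk[7] + yk[8]
      yk[1:6] <- yk[1:6] * (1 - x_new) / max(1 - x0, 1e-9)
      # split the oxidized pool by the CaM-binding balance at diastole
      c4 <- tr[nrow(tr), "Ca4CaM_jn"]
      w_pot <- unname(params["kib"] * c4 /
                        (params["kib"] * c4 + params["kbi"]))
      yk[7] <- x_new * w_pot
      yk[8] <- x_new * (1 - w_pot)
      y[blk] <- yk / sum(yk)
    }
  }
  y
}

#' Pace to steady state
#'
#' Paces the configured cell at `freq_hz` until the beat-to-beat change of
#' every tracked ion concentration falls below one hundred-thousandth of
#' its basal level, or the beat cap is reached (then the result is flagged
#' non-converged rather than raising an error). The returned result holds
#' the final densely-sampled beat, its metrics, and the per-beat ion
#' series.
#'
#' @param config a `scenario_config`.
#' @param freq_hz pacing frequency, Hz.
#' @param max_beats beat cap.
#' @param init optional initial state (defaults to the preset's stored
#'   state, with the oxidation pool pre-equilibrated when ROS > 0).
#' @param block beats integrated per solver call during the coarse phase.
#' @return list of class `protocol_result`: `trace` (final beat, dense),
#'   `metrics`, `ion_series`, `converged`, `n_beats`, `state`, `params`.
#' @export
pace_to_steady_state <- function(config, freq_hz = 1, max_beats = 600,
                                 init = NULL, block = 40) {
  p <- config$params
  period <- 1000 / freq_hz
  p["stim_amp"] <- default_stim()["amp"]
  p["stim_dur"] <- default_stim()["dur"]
  p["stim_period"] <- period
  p["stim_t0"] <- 0
  p["stim_tend"] <- 1e12
  y <- if (is.null(init)) preset_initial_state(config) else init
  ac <- apply_clamps(p, y, config$clamps)
  p <- ac$params; y <- ac$y
  if (config$ros_um > 0 && is.null(init))
    y <- equilibrate_oxidation(y, p, freq_hz)

  ions <- c("Na_i", "K_i", "Ca_i", "Ca_SR", "Ca_jn")
  basal <- abs(y[ions])
  basal[basal == 0] <- 1
  ion_rows <- list(y[ions])
  converged <- FALSE
  beat <- 0
  while (beat < max_beats && !converged) {
    nb <- min(block, max_beats - beat)
    tr <- run_cell(y, nb * period, p, dt = period,
                   rtol = config$solver$rtol, atol = config$solver$atol,
                   hmax = config$solver$hmax)
    # rows are beat boundaries 0..nb
    for (k in seq_len(nb)) {
      prev <- tr[k, ions]; cur <- tr[k + 1, ions]
      ion_rows[[length(ion_rows) + 1]] <- cur
      beat <- beat + 1
      if (steady_state_check(prev, cur, basal)) { converged <- TRUE; break }
    }
    y <- tr[if (converged) k + 1 else nb + 1, cell_state_names()]
  }
  # final beat, densely sampled
  tr_f <- run_cell(y, period, p, dt = config$solver$dt_out,
                   rtol = config$solver$rtol, atol = config$solver$atol,
                   hmax = config$solver$hmax)
  res <- list(trace = tr_f, metrics = compute_beat_metrics(tr_f, 0),
              ion_series = do.call(rbind, ion_rows),
              converged = converged, n_beats = beat,
              state = tr_f[nrow(tr_f), cell_state_names()],
              stim = default_stim(), period = period, params = p)
  class(res) <- "protocol_result"
  res
}

#' Burst-pacing protocol
#'
#' The DAD-provocation schedule: a 1 Hz initialization segment (2 s), 10 Hz
#' burst pacing for 12 s, then resumption of 1 Hz for 26 s (40 s total).
#' The model is first paced to 1 Hz steady state. DAD detection runs on
#' the recovery segment.
#'
#' @param config a `scenario_config`.
#' @param init optional pre-paced `protocol_result` (from
#'   [pace_to_steady_state()]); computed when absent.
#' @param recovery_s length of the 1 Hz recovery segment, s.
#' @return `protocol_result` with `trace` (full 40 s), `stim_times`,
#'   `dads`, `triggered`, recovery-segment `metrics`, and the underlying
#'   steady-state result as `init`.
#' @export
burst_protocol <- function(config, init = NULL, recovery_s = 26) {
  if (is.null(init)) init <- pace_to_steady_state(config)
  p <- init$params
  y <- init$state
  dt <- config$solver$dt_out
  seg <- function(y, t0, t1, period, amp) {
    p["stim_amp"] <- amp
    p["stim_period"] <- period
    p["stim_t0"] <- t0
    p["stim_tend"] <- t1
    run_cell(y, t1, p, t0 = t0, dt = dt, rtol = config$solver$rtol,
             atol = config$solver$atol, hmax = config$solver$hmax)
  }
  amp <- default_stim()["amp"]
  t_burst0 <- 2000; t_burst1 <- 14000
  t_end <- t_burst1 + recovery_s * 1000
  tr1 <- seg(y, 0, t_burst0, 1000, amp)
  tr2 <- seg(tr1[nrow(tr1), cell_state_names()], t_burst0, t_burst1, 100, amp)
  tr3 <- seg(tr2[nrow(tr2), cell_state_names()], t_burst1, t_end, 1000, amp)
  trace <- rbind(tr1[-nrow(tr1), ], tr2[-nrow(tr2), ], tr3)
  stim1 <- seq(0, t_burst0 - 1, by = 1000)
  stim2 <- seq(t_burst0, t_burst1 - 1, by = 100)
  stim3 <- seq(t_burst1, t_end - 1, by = 1000)
  rec <- trace[trace[, "time"] >= t_burst1, , drop = FALSE]
  dd <- detect_dads(rec, stim3)
  res <- list(trace = trace, stim_times = c(stim1, stim2, stim3),
              recovery_start = t_burst1, dads = dd$dads,
              triggered = dd$triggered, metrics = beat_series(rec, stim3),
              state = trace[nrow(trace), cell_state_names()],
              init = init, params = init$params)
  class(res) <- "protocol_result"
  res
}

#' Clamp experiment on the burst protocol
#'
#' Runs [burst_protocol()] with one quantity clamped throughout (including
#' the initializing 1 Hz pacing): intracellular Na, or the CaMKII-dependent
#' phosphorylation level of RyR, LTCC, or PLB.
#'
#' @param config a `scenario_config`.
#' @param clamp one of `"na_i"`, `"phos_RyR"`, `"phos_LTCC"`, `"phos_PLB"`.
#' @param level clamp level (mM for Na, fraction for phosphorylation).
#' @param ... passed to [burst_protocol()].
#' @return `protocol_result`, as [burst_protocol()].
#' @export
clamp_experiment <- function(config, clamp = c("na_i", "phos_RyR",
                                               "phos_LTCC", "phos_PLB"),
                             level, ...) {
  clamp <- match.arg(clamp)
  key <- switch(clamp, na_i = "na_i_mM", phos_RyR = "phos_RyR",
                phos_LTCC = "phos_LTCC", phos_PLB = "phos_PLB")
  cfg <- config
  cfg$clamps[[key]] <- level
  # re-validate against the schema bounds
  cfg <- scenario_config(variant = cfg$variant, ros_um = cfg$ros_um,
                         clamps = cfg$clamps, pacing = cfg$pacing,
                         solver = cfg$solver, seed = cfg$seed,
                         params = cfg$params)
  burst_protocol(cfg, ...)
}

# total SR Ca content (free + calsequestrin-bound), arbitrary-consistent units
#' @keywords internal
sr_content <- function(ca_sr, params) {
  ca_sr + params["Bsr"] * ca_sr / (params["Ksr"] + ca_sr)
}

# shared 10-s hold with [Ca]SR and phos_RyR clamped, no stimulus
#' @keywords internal
ryr_hold <- function(config, ca_sr_um, phos_ryr, probe_mode, init = NULL,
                     hold_s = 10) {
  if (ca_sr_um < 200 || ca_sr_um > 800)
    stop("ca_sr_um must lie in [200, 800] uM")
  if (phos_ryr < 0.1 || phos_ryr > 0.8)
    stop("phos_ryr must lie in [0.1, 0.8]")
  if (is.null(init)) init <- pace_to_steady_state(config)
  p <- init$params
  y <- init$state
  p["stim_amp"] <- 0
  p["clamp_casr"] <- ca_sr_um
  p["clamp_pR"] <- phos_ryr
  p["probe_on"] <- if (probe_mode) 1 else 0
  p["probe_amp"] <- 0
  p["probe_t0"] <- -1e9
  y["Ca_SR"] <- ca_sr_um
  y["phos_RyR"] <- phos_ryr
  tr <- run_cell(y, hold_s * 1000, p, dt = 10)
  list(params = p, state = tr[nrow(tr), cell_state_names()], init = init)
}

#' Released fraction for a single probe amplitude
#'
#' Runs the hold-and-probe sequence once at a given square-pulse amplitude
#' and returns the fraction of free SR Ca released within the measurement
#' window. Used as the brute-force oracle behind the bisection search.
#'
#' @inheritParams ryr_threshold_search
#' @param amp probe amplitude, pA/pF.
#' @return released fraction of the pre-probe free SR Ca.
#' @keywords internal
probe_release_fraction <- function(config, ca_sr_um, phos_ryr, amp,
                                   init = NULL, window_ms = 500) {
  h <- ryr_hold(config, ca_sr_um, phos_ryr, probe_mode = TRUE, init = init)
  p <- h$params
  p["clamp_casr"] <- -1
  p["probe_amp"] <- amp
  p["probe_t0"] <- 10
  tr <- run_cell(h$state, 10 + window_ms + 10, p, dt = 1)
  pre <- tr[max(which(tr[, "time"] <= 10)), "Ca_SR"]
  win <- tr[, "time"] >= 10 & tr[, "time"] <= 10 + window_ms
  unname((pre - min(tr[win, "Ca_SR"])) / pre)
}

#' RyR activation threshold at a clamped operating point
#'
#' Clamps [Ca]SR and the RyR phosphorylation fraction for 10 s with no
#' stimulus (the L-type current is replaced by a controllable square Ca
#' probe current), then releases the SR clamp and probes with 5-ms square
#' Ca-current pulses of increasing amplitude until at least a quarter of
#' the SR Ca content (free + calsequestrin-bound) is released within 1 s
#' of the probe. The smallest releasing amplitude, located by a coarse
#' doubling bracket plus bisection to 0.1 pA/pF, is the activation
#' threshold. If the store releases with no probe at all the operating
#' point is reported as ALWAYS_OPEN.
#'
#' @param config a `scenario_config`.
#' @param ca_sr_um clamped SR Ca, uM, in [200, 800].
#' @param phos_ryr clamped RyR phosphorylation fraction, in [0.1, 0.8].
#' @param init optional pre-paced `protocol_result` shared across calls.
#' @param amp_res bisection resolution, pA/pF.
#' @param amp_max search cap, pA/pF.
#' @param release_frac released-fraction criterion (of pre-probe content).
#' @param window_ms measurement window after probe onset, ms.
#' @return list with `threshold` (pA/pF; NA when `always_open`, Inf when
#'   no probe up to `amp_max` meets the release criterion),
#'   `always_open`, `released_frac` at threshold, `n_evals`, and
#'   `hold_state`.
#' @export
ryr_threshold_search <- function(config, ca_sr_um, phos_ryr, init = NULL,
                                 amp_res = 0.1, amp_max = 200,
                                 release_frac = 0.25, window_ms = 500) {
  h <- ryr_hold(config, ca_sr_um, phos_ryr, probe_mode = TRUE, init = init)
  p <- h$params
  y0 <- h$state
  released <- function(amp) {
    p["clamp_casr"] <- -1
    p["probe_amp"] <- amp
    p["probe_t0"] <- 10
    tr <- run_cell(y0, 10 + window_ms + 10, p, dt = 1)
    pre <- tr[max(which(tr[, "time"] <= 10)), "Ca_SR"]
    win <- tr[, "time"] >= 10 & tr[, "time"] <= 10 + window_ms
    unname((pre - min(tr[win, "Ca_SR"])) / pre)
  }
  n_evals <- 1L
  # standing release at the end of the hold (junctional Ca far above
  # diastolic) marks the channel as open without any stimulus
  if (y0["Ca_jn"] > 5)
    return(list(threshold = NA_real_, always_open = TRUE,
                released_frac = NA_real_, n_evals = 0L, hold_state = y0))
  f0 <- released(0)
  if (f0 >= release_frac)
    return(list(threshold = NA_real_, always_open = TRUE,
                released_frac = f0, n_evals = n_evals, hold_state = y0))
  a <- 0.4
  fa <- released(a); n_evals <- n_evals + 1L
  while (fa < release_frac && a < amp_max) {
    a <- a * 2
    fa <- released(a); n_evals <- n_evals + 1L
  }
  if (fa < release_frac)
    return(list(threshold = Inf, always_open = FALSE, released_frac = fa,
                n_evals = n_evals, hold_state = y0))
  lo <- if (a == 0.4) 0 else a / 2
  hi <- a
  while (hi - lo > amp_res) {
    mid <- (lo + hi) / 2
    fm <- released(mid); n_evals <- n_evals + 1L
    if (fm >= release_frac) hi <- mid else lo <- mid
  }
  list(threshold = hi, always_open = FALSE, released_frac = released(hi),
       n_evals = n_evals + 1L, hold_state = y0)
}

#' Release amplitude and re-stabilization after unclamping
#'
#' Clamps [Ca]SR and RyR phosphorylation for 10 s (no stimulus), releases
#' the SR clamp, and applies `n_beats` stimuli at 1 Hz with the
#' phosphorylation clamp maintained. Records the per-beat peak SR release
#' flux and peak [Ca]SR, the first-beat release amplitude, and the time to
#' stability (first beat from which consecutive-beat variation of the
#' release-peak series stays below 1%).
#'
#' @inheritParams ryr_threshold_search
#' @param n_beats number of 1 Hz stimuli after unclamping.
#' @return list with `first_jrel` (uM/ms), `jrel_peaks`, `casr_peaks`,
#'   `t_stab_s` (s; Inf when never stable), `first_beat_trace`, `state`.
#' @export
release_after_unclamp <- function(config, ca_sr_um, phos_ryr, init = NULL,
                                  n_beats = 200) {
  h <- ryr_hold(config, ca_sr_um, phos_ryr, probe_mode = FALSE, init = init)
  p <- h$params
  y <- h$state
  p["clamp_casr"] <- -1
  p["stim_amp"] <- default_stim()["amp"]
  p["stim_dur"] <- default_stim()["dur"]
  p["stim_period"] <- 1000
  p["stim_t0"] <- 0
  p["stim_tend"] <- 1e12
  jrel_peaks <- casr_peaks <- numeric(n_beats)
  first_tr <- NULL
  for (k in seq_len(n_beats)) {
    tr <- run_cell(y, 1000, p, dt = 0.5)
    jrel_peaks[k] <- max(tr[, "J_rel"])
    casr_peaks[k] <- max(tr[, "Ca_SR"])
    if (k == 1) first_tr <- tr
    y <- tr[nrow(tr), cell_state_names()]
  }
  t_stab <- time_to_stability(jrel_peaks, period_s = 1)
  list(first_jrel = jrel_peaks[1], jrel_peaks = jrel_peaks,
       casr_peaks = casr_peaks, t_stab_s = t_stab,
       first_beat_trace = first_tr, state = y)
}

#' Time to stability of a per-beat series
#'
#' First beat from which the relative consecutive-beat variation stays
#' strictly below `tol` for the rest of the series, expressed in seconds.
#'
#' @param peaks per-beat peak series.
#' @param period_s beat period, s.
#' @param tol relative variation threshold.
#' @return time in seconds (0 when stable from the first interval);
#'   `Inf` when the series never settles.
#' @export
time_to_stability <- function(peaks, period_s = 1, tol = 0.01) {
  n <- length(peaks)
  if (n < 2) return(0)
  rel <- abs(diff(peaks)) / pmax(abs(peaks[-n]), 1e-12)
  ok <- rel < tol
  # last index where the criterion fails; stable from the next interval on
  bad <- which(!ok)
  if (!length(bad)) return(0)
  if (max(bad) == n - 1) return(Inf)
  max(bad) * period_s
}
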