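#' Per-beat action-potential and Ca-transient metrics
#'
#' Computes the standard beat summary from a sampled trace spanning one
#' cardiac cycle. Conventions: the take-off potential is the diastolic
#' minimum immediately preceding the upstroke; AP amplitude is peak V
#' minus take-off; APD25/50/90 run from the dV/dt-max instant to 25/50/90%
#' repolarization of the amplitude (linear interpolation between samples);
#' resting potential is the diastolic minimum; CaT amplitude is the
#' systolic peak minus the diastolic minimum of bulk [Ca].
#'
#' @param trace matrix with at least columns `time` and `V` (and `Ca_i`,
#'   `J_rel` for the Ca metrics), covering one full cycle.
#' @param stim_time stimulus onset, ms (same clock as `trace`).
#' @param min_amplitude mV; below this upstroke the beat is flagged as
#'   "no AP" and the AP metrics are NA rather than zero.
#' @return list of class `beat_metrics`: `apd25`, `apd50`, `apd90` (ms),
#'   `ap_amplitude` (mV), `dvdt_max` (mV/ms), `resting_potential` (mV),
#'   `cat_amplitude`, `diastolic_ca` (uM), `peak_jrel` (uM/ms), `has_ap`.
#' @export
compute_beat_metrics <- function(trace, stim_time = trace[1, "time"],
                                 min_amplitude = 30) {
  tt <- trace[, "time"]
  V <- trace[, "V"]
  n <- length(tt)
  if (n < 5) stop("trace too short for beat metrics")
  dvdt <- diff(V) / diff(tt)
  i_up <- which.max(dvdt)
  dvdt_max <- dvdt[i_up]
  # take-off: diastolic minimum just before the upstroke (the sampled
  # dV/dt-max instant sits mid-upstroke and would understate amplitude)
  pre <- which(tt >= tt[i_up] - 20 & tt <= tt[i_up])
  v_takeoff <- min(V[pre])
  i_peak <- which.max(V)
  v_peak <- V[i_peak]
  amp <- v_peak - v_takeoff
  rest <- min(V)
  ca <- if ("Ca_i" %in% colnames(trace)) trace[, "Ca_i"] else rep(NA_real_, n)
  jrel <- if ("J_rel" %in% colnames(trace)) trace[, "J_rel"] else rep(NA_real_, n)
  dia_ca <- suppressWarnings(min(ca[seq_len(max(i_up, 2))]))
  cat_amp <- suppressWarnings(max(ca)) - dia_ca

  if (!is.finite(amp) || amp < min_amplitude || i_peak < i_up) {
    out <- list(apd25 = NA_real_, apd50 = NA_real_, apd90 = NA_real_,
                ap_amplitude = NA_real_, dvdt_max = dvdt_max,
                resting_potential = rest, cat_amplitude = cat_amp,
                diastolic_ca = dia_ca,
                peak_jrel = suppressWarnings(max(jrel)), has_ap = FALSE)
    class(out) <- "beat_metrics"
    return(out)
  }

  t_up <- tt[i_up]
  apd_at <- function(frac) {
    v_target <- v_peak - frac * amp
    idx <- which(V[i_peak:n] <= v_target)
    if (!length(idx)) return(NA_real_)
    k <- i_peak + idx[1] - 1
    if (k == 1) return(NA_real_)
    # linear interpolation across the crossing
    t_cross <- tt[k - 1] + (tt[k] - tt[k - 1]) *
      (V[k - 1] - v_target) / (V[k - 1] - V[k])
    t_cross - t_up
  }
  out <- list(apd25 = apd_at(0.25), apd50 = apd_at(0.50),
              apd90 = apd_at(0.90), ap_amplitude = amp,
              dvdt_max = dvdt_max, resting_potential = rest,
              cat_amplitude = cat_amp, diastolic_ca = dia_ca,
              peak_jrel = suppressWarnings(max(jrel)), has_ap = TRUE)
  class(out) <- "beat_metrics"
  out
}

#' Beat-wise metrics over a multi-beat trace
#'
#' Splits a trace at the stimulus times and computes [compute_beat_metrics()]
#' for each cycle.
#'
#' @param trace sampled trace (matrix with `time`, `V`, ...).
#' @param stim_times stimulus onset times, ms.
#' @return data.frame, one row per beat.
#' @export
beat_series <- function(trace, stim_times) {
  stim_times <- sort(stim_times)
  tt <- trace[, "time"]
  ends <- c(stim_times[-1], max(tt))
  rows <- lapply(seq_along(stim_times), function(i) {
    sel <- tt >= stim_times[i] & tt <= ends[i]
    if (sum(sel) < 5) return(NULL)
    m <- compute_beat_metrics(trace[sel, , drop = FALSE], stim_times[i])
    data.frame(beat = i, stim_time = stim_times[i],
               apd25 = m$apd25, apd50 = m$apd50, apd90 = m$apd90,
               ap_amplitude = m$ap_amplitude, dvdt_max = m$dvdt_max,
               resting_potential = m$resting_potential,
               cat_amplitude = m$cat_amplitude, diastolic_ca = m$diastolic_ca,
               peak_jrel = m$peak_jrel, has_ap = m$has_ap)
  })
  do.call(rbind, rows)
}

#' Detect delayed afterdepolarizations
#'
#' Scans the diastolic portions of a trace for spontaneous depolarization
#' events: local voltage maxima rising at least `dv_thresh` above the
#' post-repolarization diastolic baseline, not evoked by a stimulus, and
#' staying below `ap_frac` of the preceding AP amplitude (larger events
#' are classified as triggered APs and reported separately). The criterion
#' is an operational definition; the threshold is configurable.
#'
#' @param trace matrix with columns `time` and `V`.
#' @param stim_times stimulus onset times, ms. Events inside a
#'   stimulus-evoked AP window (from stimulus until V first returns to
#'   within 2 mV of the running baseline, capped at `ap_window_max`) are
#'   ignored.
#' @param dv_thresh minimum depolarization above diastolic baseline, mV.
#' @param ap_frac events above this fraction of the preceding AP amplitude
#'   count as triggered APs, not DADs.
#' @param ap_window_max cap on the stimulus-evoked window, ms.
#' @param ref_amplitude reference AP amplitude (mV) used for the
#'   triggered-AP split when the trace itself contains no stimulus-evoked
#'   AP.
#' @return list with `dads` (data.frame: `time`, `delta_v`, `cycle`) and
#'   `triggered` (same layout).
#' @export
detect_dads <- function(trace, stim_times, dv_thresh = 5, ap_frac = 0.8,
                        ap_window_max = 300, ref_amplitude = 100) {
  tt <- trace[, "time"]
  V <- trace[, "V"]
  n <- length(tt)
  stim_times <- sort(stim_times)
  in_ap <- rep(FALSE, n)
  amp_prev <- ref_amplitude
  base_global <- as.numeric(stats::quantile(V, 0.05))
  for (s in stim_times) {
    i0 <- which(tt >= s)[1]
    if (is.na(i0)) next
    i1 <- min(n, i0 + which(tt >= s + ap_window_max)[1] - i0)
    if (is.na(i1) || !length(i1)) i1 <- n
    seg <- i0:i1
    # window ends when V first returns near baseline after the upstroke
    vp <- max(V[seg])
    if (vp > base_global + 30) amp_prev <- vp - base_global
    rec <- which(V[seg] <= base_global + 2)
    rec <- rec[rec > which.max(V[seg])]
    iend <- if (length(rec)) seg[rec[1]] else max(seg)
    in_ap[i0:iend] <- TRUE
  }
  # candidate events: local maxima outside AP windows
  cand <- which(!in_ap)
  if (!length(cand)) {
    empty <- data.frame(time = numeric(0), delta_v = numeric(0),
                        cycle = integer(0))
    return(list(dads = empty, triggered = empty))
  }
  # split candidates into contiguous runs; one event per local max above
  # the run's own baseline
  runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
  ev_t <- ev_dv <- numeric(0)
  for (r in runs) {
    if (length(r) < 5) next
    v <- V[r]
    base <- as.numeric(stats::quantile(v, 0.1))
    # local maxima with simple 1-sample prominence
    im <- which(diff(sign(diff(v))) == -2) + 1
    for (k in im) {
      dv <- v[k] - base
      if (dv >= dv_thresh) {
        # require a true rise-and-fall around the peak
        left_min <- min(v[max(1, k - 400):k])
        if (v[k] - left_min >= dv_thresh * 0.8) {
          ev_t <- c(ev_t, tt[r[k]]); ev_dv <- c(ev_dv, dv)
        }
      }
    }
  }
  if (!length(ev_t)) {
    empty <- data.frame(time = numeric(0), delta_v = numeric(0),
                        cycle = integer(0))
    return(list(dads = empty, triggered = empty))
  }
  cyc <- findInterval(ev_t, stim_times)
  is_trig <- ev_dv > ap_frac * amp_prev
  mk <- function(sel) data.frame(time = ev_t[sel], delta_v = ev_dv[sel],
                                 cycle = cyc[sel])
  list(dads = mk(!is_trig), triggered = mk(is_trig))
}

#' Steady-state pacing criterion
#'
#' TRUE iff the largest relative beat-to-beat change of the tracked ion
#' concentrations is strictly below `tol` of the basal level (default: one
#' hundred-thousandth).
#'
#' @param beat_k,beat_k1 named vectors of ion concentrations on two
#'   consecutive beats (sampled at the same phase).
#' @param basal named vector of basal (reference) levels; all > 0.
#' @param tol relative tolerance (strict inequality).
#' @return logical scalar.
#' @export
steady_state_check <- function(beat_k, beat_k1, basal, tol = 1e-5) {
  if (any(basal == 0)) stop("basal levels must be non-zero")
  nm <- names(beat_k)
  if (!is.null(nm)) {
    beat_k1 <- beat_k1[nm]; basal <- basal[nm]
  }
  max(abs(beat_k1 - beat_k) / abs(basal)) < tol
}
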