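#' Canonical state names of the cell model
#'
#' 38 states: membrane potential, gating variables, RyR Markov states,
#' Ca/Na/K concentrations, phosphorylation fractions, and the two
#' eight-state CaMKII compartments (junctional `kj_*`, cytosolic `kc_*`).
#'
#' @return Character vector of length 38.
#' @export
cell_state_names <- function() {
  c("V", "m", "h", "j", "hL", "d", "f", "ato", "ito", "aur", "iur",
    "rR", "rO", "rI",
    "Ca_jn", "Ca_i", "Ca_SR", "Na_i", "K_i",
    "phos_LTCC", "phos_PLB", "phos_RyR",
    paste0("kj_", c("Pi", "Pb", "Pt", "Pt2", "Pa", "Pb2", "Pot", "Po")),
    paste0("kc_", c("Pi", "Pb", "Pt", "Pt2", "Pa", "Pb2", "Pot", "Po")))
}

#' Auxiliary output names returned by the integrator
#' @return Character vector of length 20.
#' @export
cell_output_names <- function() {
  c("I_Na", "I_NaL", "I_CaL", "I_to", "I_Kur", "I_ss", "I_K1", "I_NCX",
    "I_NaK", "I_pCa", "I_Cab", "I_Nab", "I_stim", "J_rel", "J_up",
    "J_leak", "camkii_act_jn", "camkii_act_cyt", "Ca4CaM_jn", "I_probe")
}

#' Baseline cell-model parameters
#'
#' Full parameter vector of the mouse atrial myocyte model, in the fixed
#' order expected by the compiled right-hand side. Conventions: time ms,
#' voltage mV, membrane currents pA/pF, Ca in uM, Na/K in mM, volumes in
#' liters, all rates per ms. Kinase rates are inherited from
#' [kinase_params()] (s^-1 there) and converted to per-ms here.
#'
#' Clamp entries (`clamp_*`) use -1 for "off"; a non-negative value holds
#' the corresponding state's derivative at zero (protocols also set the
#' state itself to the level at the start of the clamp window).
#'
#' @param ... named overrides.
#' @param kinase a `kinase_params` object supplying the signaling rates.
#' @return Named numeric vector of length 117 with class `cell_params`.
#' @export
cell_params <- function(..., kinase = kinase_params()) {
  kp <- kinase
  ms <- 1e-3   # s^-1 -> ms^-1
  p <- c(
    # geometry / environment
    Cm = 50, Vmyo = 1.3e-11, Vjn = 2.0e-13, Vsr = 7.0e-13,
    Nao = 140, Ko = 5.4, Cao = 1.8,
    # membrane currents
    gNa = 23, gNaL = 0.06, hL_vshift = 0, tau_hL = 40,
    gCaL = 0.5, Km_fCa = 15, gto = 0.10, kf_to = 1,
    gKur = 0.05, gss = 0.02, gK1 = 0.75,
    vncx = 1200, KmNa_ncx = 87.5, KmCa_ncx = 1.38, ksat_ncx = 0.1,
    eta_ncx = 0.35, Kd_ncxact = 0.15, fjn_ncx = 0.05,
    ibarNaK = 1.7, KmNaip = 12, KmKo = 1.5,
    gpCa = 0.05, KmpCa = 0.5, gCab = 0.0008, gNab = 0.0005,
    # SR release / uptake
    ks_rel = 0.2, koCa = 6e-5, kom = 0.15, kiCa = 1.8e-4, kim = 0.004,
    ec50SR = 450, maxSR = 15, minSR = 1,
    Vmax_up = 2.5, Kmf_up = 0.3, Kmr_up = 1700, hill_up = 1.787,
    kleak = 1.5e-6, tau_diff = 0.5,
    # buffers
    Btn = 70, Ktn = 0.6, Bcd = 24, Kcd = 7,
    Bjn = 80, Kjn = 13, Bsr = 14000, Ksr = 650,
    # stimulus schedule (set by protocols)
    stim_amp = 0, stim_dur = 2, stim_period = 1000,
    stim_t0 = 0, stim_tend = 0,
    # CaMKII pools and chain rates (per ms)
    camkii_tot_jn = kp$camkii_total, camkii_cyt_ratio = 1 / 60,
    ros = 0,
    kbi = kp$k_bi * ms, kib = kp$k_ib * ms, kox = kp$k_ox * ms,
    KmROS = kp$Km_ROS, kredox = kp$k_redox * ms, MsrA = kp$MsrA_conc,
    KmMsrA = kp$Km_MsrA,
    kauto = kp$k_auto * ms, kt_off = kp$k_t_off * ms,
    kt2_off = kp$k_t2_off * ms, kb2i = kp$k_b2i * ms,
    vpp1_jn = kp$v_pp1 * ms, vpp1_cyt = kp$v_pp1 * ms, KmPP1 = kp$Km_PP1,
    CaMtot_jn = 25, CaMtot_cyt = 6, KdCaM1 = 10, KdCaM2 = 25,
    # phosphorylation kinetics (per ms) and anchors
    kp_L = 1.64e-3, Km_L = 80, kd_L = 4e-4,
    kp_P = 6.24e-4, Km_P = 300, kd_P = 4e-4,
    kp_R = 4.16e-4, Km_R = 200, kd_R = 4e-4,
    pL_ref = 0.53, pP_ref = 0.046, pR_ref = 0.192,
    cL_g = 0.3, cL_tf = 1.0, cP_km = 0.8, cR_ko = 12, cR_ec = 0.9,
    # clamps / probe (off by default)
    clamp_nai = -1, clamp_casr = -1,
    clamp_pL = -1, clamp_pP = -1, clamp_pR = -1,
    probe_on = 0, probe_amp = 0, probe_t0 = 0, probe_dur = 5,
    kinase_frozen = 0,
    kib2_scale = kp$k_ib2_scale,
    hill_srf = 4,
    n_L = 8, n_P = 2.5, n_R = 1,
    hill_ryr = 3,
    k_lum = 0.1, casr_th = 600, w_lum = 1, ca_gate_km = 0.02
  )
  stopifnot(length(p) == 117)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown cell parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "cell_params"
  p
}

#' Default initial state of the cell model
#'
#' A resting-like configuration; protocols normally pre-pace to a true
#' steady state before measuring anything.
#'
#' @param params cell parameters (used for consistency of anchors).
#' @return Named numeric state vector of length 38.
#' @export
cell_initial_state <- function(params = cell_params()) {
  y <- c(
    V = -78, m = 0.002, h = 0.97, j = 0.98, hL = 0.25,
    d = 0, f = 1, ato = 0, ito = 1, aur = 0, iur = 1,
    rR = 0.85, rO = 1e-6, rI = 1e-6,
    Ca_jn = 0.25, Ca_i = 0.12, Ca_SR = 450, Na_i = 12, K_i = 143,
    phos_LTCC = unname(params["pL_ref"]),
    phos_PLB = unname(params["pP_ref"]),
    phos_RyR = unname(params["pR_ref"]),
    setNames(c(1, rep(0, 7)), paste0("kj_", c("Pi", "Pb", "Pt", "Pt2",
                                              "Pa", "Pb2", "Pot", "Po"))),
    setNames(c(1, rep(0, 7)), paste0("kc_", c("Pi", "Pb", "Pt", "Pt2",
                                              "Pa", "Pb2", "Pot", "Po")))
  )
  stopifnot(identical(names(y), cell_state_names()))
  y
}

#' Evaluate the cell-model right-hand side once
#'
#' Direct single evaluation of the compiled derivative field, including the
#' auxiliary current/flux outputs. Mainly for testing, conservation audits,
#' and rest-point checks.
#'
#' @param state named state vector ([cell_initial_state()] layout).
#' @param t time, ms (matters only for stimulus/probe windows).
#' @param params cell parameters.
#' @return list with `deriv` (named, d/dt per ms) and `outputs` (named
#'   currents pA/pF and fluxes uM/ms).
#' @export
cell_derivatives <- function(state, t = 0, params = cell_params()) {
  if (is.null(names(state))) names(state) <- cell_state_names()
  state <- state[cell_state_names()]
  if (any(!is.finite(state))) stop("non-finite state entry")
  res <- .C("camk_rhs_direct", t = as.double(t), y = as.double(state),
            parms = as.double(params), ydot = double(38), yout = double(20),
            NAOK = FALSE, PACKAGE = "camkatria")
  dy <- setNames(res$ydot, cell_state_names())
  if (any(!is.finite(dy))) {
    bad <- names(dy)[!is.finite(dy)]
    stop("non-finite derivative in state(s): ", paste(bad, collapse = ", "))
  }
  list(deriv = dy, outputs = setNames(res$yout, cell_output_names()))
}

#' Integrate the cell model
#'
#' Thin wrapper around [deSolve::lsoda()] using the compiled model. Output
#' is sampled on a fixed grid (default 0.5 ms) so that downstream beat
#' metrics see a consistent sampling density.
#'
#' @param y0 initial state (named, [cell_state_names()] layout).
#' @param t_end end time, ms (integration starts at `t0`).
#' @param params cell parameters.
#' @param t0 start time, ms.
#' @param dt output sampling interval, ms.
#' @param rtol,atol solver tolerances.
#' @param hmax maximum solver step, ms.
#' @return Matrix (deSolve class) with time, states, and auxiliary outputs.
#' @export
run_cell <- function(y0, t_end, params, t0 = 0, dt = 0.5,
                     rtol = 1e-7, atol = 1e-9, hmax = 1) {
  times <- seq(t0, t_end, by = dt)
  out <- deSolve::lsoda(
    y = y0, times = times, func = "camk_derivs", parms = as.double(params),
    dllname = "camkatria", initfunc = "camk_initmod",
    nout = 20, outnames = cell_output_names(),
    rtol = rtol, atol = atol, hmax = hmax, maxsteps = 100000)
  colnames(out) <- c("time", cell_state_names(), cell_output_names())
  out
}
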