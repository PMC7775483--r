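#' CaMKII signaling parameters
#'
#' Rate and concentration parameters for the eight-state CaMKII Markov chain
#' (six activation states plus the two oxidized states). All rates are in
#' s^-1 (binding rates in uM^-1 s^-1), ROS and CaM concentrations in uM,
#' MsrA in mM.
#'
#' The oxidation parameters are: `k_ox` (maximal oxidation rate of the
#' calmodulin-bound state Pb), `Km_ROS` (Michaelis constant of the ROS
#' dependence), `k_redox` and `Km_MsrA` (MsrA-catalyzed reduction), and
#' `MsrA_conc`. Only the saturated product
#' `k_redox * MsrA / (MsrA + Km_MsrA)` enters the equations; the default
#' `MsrA_conc` is chosen so this effective reduction rate is 1.5e-6 s^-1,
#' which places the oxidized pool on the slow (minutes-to-hours) timescale
#' that makes the oxidation level an essentially static property of a given
#' ROS exposure.
#'
#' @param ... named overrides of any default parameter.
#' @return A named list of class `kinase_params`.
#' @examples
#' p <- kinase_params()
#' p$k_ox
#' kinase_params(k_ox = 1e-5)$k_ox
#' @export
kinase_params <- function(...) {
  b_eff <- 1.5e-6   # documented effective reduction rate, s^-1
  p <- list(
    # CaM binding/unbinding, inherited from the activation chain
    k_bi    = 2.2,              # s^-1, Ca4CaM dissociation from Pb (and Pot)
    k_ib    = 2.2 / 33.5e-3,    # uM^-1 s^-1, Ca4CaM association
    k_b2i   = 10,               # s^-1, Ca2CaM dissociation (low-affinity pool)
    k_ib2_scale = 0.02,         # Ca2CaM association relative to Ca4CaM
    k_t_off = 2.2e-3,           # s^-1, Ca4CaM dissociation from trapped Pt
    k_t2_off = 2.2e-1,          # s^-1, Ca2CaM dissociation from Pt2
    # autophosphorylation (neighbor-activity dependent)
    k_auto  = 0.04,             # s^-1, scaled by the active fraction
    # PP1 dephosphorylation of Pt/Pt2/Pa (Michaelis-Menten in substrate)
    v_pp1   = 18,               # uM s^-1, maximal dephosphorylation flux
    Km_PP1  = 10,               # uM, phosphorylated-CaMKII concentration
    # oxidation module
    k_ox      = 6.48e-6,        # s^-1
    Km_ROS    = 60,             # uM
    k_redox   = 0.28,           # s^-1
    Km_MsrA   = 0.34,           # mM
    MsrA_conc = b_eff * 0.34 / (0.28 - b_eff),  # mM, see Details
    camkii_total = 120          # uM (junctional compartment, wild type)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown kinase parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)
  if (!all(num)) stop("kinase parameters must be finite numeric scalars")
  if (any(unlist(p) < 0)) stop("kinase rates and concentrations must be >= 0")
  class(p) <- "kinase_params"
  p
}

#' CaMKII state vector
#'
#' Occupancy fractions of the eight CaMKII states. `Pi` is the inactive
#' monomer, `Pb` calmodulin-bound, `Pt` autophosphorylated and CaM-trapped,
#' `Pt2` trapped with Ca2CaM, `Pa` autonomous (autophosphorylated, CaM
#' dissociated), `Pb2` Ca2CaM-bound inactive, `Pot` oxidized with Ca4CaM
#' bound, `Po` oxidized with CaM dissociated.
#'
#' @param Pi,Pb,Pt,Pt2,Pa,Pb2,Pot,Po occupancy fractions; must be
#'   non-negative and sum to 1.
#' @param normalize divide by the sum instead of requiring it to be 1.
#' @return Named numeric vector of length 8.
#' @export
kinase_state <- function(Pi = 1, Pb = 0, Pt = 0, Pt2 = 0, Pa = 0, Pb2 = 0,
                         Pot = 0, Po = 0, normalize = FALSE) {
  s <- c(Pi = Pi, Pb = Pb, Pt = Pt, Pt2 = Pt2, Pa = Pa, Pb2 = Pb2,
         Pot = Pot, Po = Po)
  if (any(!is.finite(s)) || any(s < -1e-12))
    stop("kinase state occupancies must be finite and non-negative")
  s[s < 0] <- 0
  if (normalize) s <- s / sum(s)
  if (abs(sum(s) - 1) > 1e-6)
    stop("kinase state occupancies must sum to 1 (got ", format(sum(s)), ")")
  s
}

#' CaMKII drive
#'
#' The instantaneous concentrations seen by the kinase chain: fully and
#' half Ca-loaded calmodulin (uM) and ROS (uM).
#'
#' @param Ca4CaM,Ca2CaM,ROS concentrations in uM, each >= 0.
#' @return Named numeric vector of length 3.
#' @export
kinase_drive <- function(Ca4CaM = 0, Ca2CaM = 0, ROS = 0) {
  d <- c(Ca4CaM = Ca4CaM, Ca2CaM = Ca2CaM, ROS = ROS)
  if (any(!is.finite(d)) || any(d < 0))
    stop("kinase drive concentrations must be finite and >= 0")
  d
}

kinase_state_names <- c("Pi", "Pb", "Pt", "Pt2", "Pa", "Pb2", "Pot", "Po")

#' Time derivatives of the CaMKII chain
#'
#' Evaluates the right-hand side of the eight-state Markov chain. The
#' oxidation extension adds four transitions on top of the activation chain:
#' Pb -> Pot at rate `k_ox * [ROS]/([ROS] + Km_ROS)`, MsrA-catalyzed
#' reduction Pot -> Pb and Po -> Pi at rate
#' `k_redox * [MsrA]/([MsrA] + Km_MsrA)`, and a Ca4CaM binding pair
#' Po <-> Pot with the same association/dissociation rates as Pi <-> Pb.
#' Autophosphorylated states (Pt, Pt2, Pa) have no oxidation transitions:
#' autophosphorylation and oxidation are treated as mutually exclusive.
#'
#' @param state kinase state vector, see [kinase_state()].
#' @param drive drive vector, see [kinase_drive()].
#' @param params parameters from [kinase_params()].
#' @return Named numeric vector of d(occupancy)/dt in s^-1; sums to 0.
#' @examples
#' p <- kinase_params()
#' d <- kinase_derivatives(kinase_state(Pb = 1, Pi = 0),
#'                         kinase_drive(ROS = 60), p)
#' d[["Pot"]]  # half-saturated oxidation flux, k_ox / 2
#' @export
kinase_derivatives <- function(state, drive, params = kinase_params()) {
  if (is.null(names(state))) names(state) <- kinase_state_names
  if (any(!is.finite(state)) || any(state < -1e-9))
    stop("invalid kinase state: negative or non-finite occupancy")
  if (any(!is.finite(drive)) || any(drive < 0))
    stop("invalid kinase drive: negative or non-finite concentration")
  p <- params
  c4 <- drive[["Ca4CaM"]]; c2 <- drive[["Ca2CaM"]]; ros <- drive[["ROS"]]

  a_ox  <- p$k_ox * ros / (ros + p$Km_ROS)
  b_red <- p$k_redox * p$MsrA_conc / (p$MsrA_conc + p$Km_MsrA)
  f_act <- state[["Pb"]] + state[["Pt"]] + state[["Pt2"]] + state[["Pa"]] +
    state[["Pot"]] + state[["Po"]]
  phos_conc <- p$camkii_total *
    (state[["Pt"]] + state[["Pt2"]] + state[["Pa"]])
  r_pp <- p$v_pp1 / (p$Km_PP1 + phos_conc)

  flux <- function(from, to, rate) {
    v <- rate * state[[from]]
    out <- numeric(8); names(out) <- kinase_state_names
    out[from] <- -v; out[to] <- v
    out
  }
  d <- flux("Pi", "Pb", p$k_ib * c4) + flux("Pb", "Pi", p$k_bi) +
    flux("Pi", "Pb2", p$k_ib * p$k_ib2_scale * c2) + flux("Pb2", "Pi", p$k_b2i) +
    flux("Pb", "Pt", p$k_auto * f_act) + flux("Pt", "Pb", r_pp) +
    flux("Pt", "Pa", p$k_t_off)     + flux("Pa", "Pt", p$k_ib * c4) +
    flux("Pa", "Pt2", p$k_ib * p$k_ib2_scale * c2) + flux("Pt2", "Pa", p$k_t2_off) +
    flux("Pa", "Pi", r_pp)          + flux("Pt2", "Pb2", r_pp) +
    flux("Pb", "Pot", a_ox)         + flux("Pot", "Pb", b_red) +
    flux("Pot", "Po", p$k_bi)       + flux("Po", "Pot", p$k_ib * c4) +
    flux("Po", "Pi", b_red)
  d
}

#' Active fraction of CaMKII
#'
#' All states except `Pi` and `Pb2` carry full kinase activity: the four
#' activation-chain active states (Pb, Pt, Pt2, Pa) and both oxidized states
#' (Pot, Po). Active concentration is `active_fraction(s) * camkii_total`.
#'
#' @param state kinase state vector.
#' @return Scalar fraction in `[0, 1]`.
#' @export
active_fraction <- function(state) {
  if (is.null(names(state))) names(state) <- kinase_state_names
  unname(state[["Pb"]] + state[["Pt"]] + state[["Pt2"]] + state[["Pa"]] +
           state[["Pot"]] + state[["Po"]])
}

#' Steady state of the CaMKII chain under constant drive
#'
#' Pseudo-time integration (stiff solver) from the all-inactive state
#' `Pi = 1` until the derivative norm falls below `tol`. Integration rather
#' than a direct linear solve is used because the autophosphorylation and
#' PP1 rates depend on the state itself.
#'
#' @param drive drive vector, see [kinase_drive()].
#' @param params parameters from [kinase_params()].
#' @param tol convergence tolerance on the max-norm of the derivative
#'   (s^-1).
#' @param t_max pseudo-time horizon per attempt, s. The slow oxidation pool
#'   needs ~1/b_red seconds; the default covers it.
#' @param max_tries number of successively longer integrations before the
#'   solver gives up.
#' @return A `kinase_state` vector with attribute `deriv_norm`.
#' @export
kinase_steady_state <- function(drive, params = kinase_params(),
                                tol = 1e-10, t_max = 5e7, max_tries = 4) {
  p <- params
  y <- kinase_state()
  rhs <- function(t, y, parms) list(kinase_derivatives(y, drive, p))
  integrate_to <- function(y, horizon, rtol = 1e-10, atol = 1e-12) {
    sol <- deSolve::lsoda(y, c(0, horizon), rhs, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 50000)
    y <- sol[nrow(sol), kinase_state_names]
    y[y < 0] <- 0
    y / sum(y)
  }
  a <- p$k_ox * drive[["ROS"]] / (drive[["ROS"]] + p$Km_ROS)
  b <- p$k_redox * p$MsrA_conc / (p$MsrA_conc + p$Km_MsrA)
  # the oxidized pool is orders of magnitude slower than the activation
  # chain; equilibrate the fast subsystem by pseudo-time integration and
  # jump the slow pool through its stationarity balance, then polish
  for (i in 1:4) {
    y <- integrate_to(y, 1e5, rtol = 1e-9, atol = 1e-11)
    if (a > 0) {
      x0 <- y[["Pot"]] + y[["Po"]]
      phi <- y[["Pb"]] / max(1 - x0, 1e-12)
      x1 <- a * phi / (a * phi + b)
      act <- c("Pi", "Pb", "Pt", "Pt2", "Pa", "Pb2")
      y[act] <- y[act] * (1 - x1) / max(1 - x0, 1e-12)
      w <- p$k_ib * drive[["Ca4CaM"]] /
        (p$k_ib * drive[["Ca4CaM"]] + p$k_bi + b)
      y["Pot"] <- x1 * w
      y["Po"] <- x1 * (1 - w)
      y <- y / sum(y)
    }
  }
  horizon <- 1e6
  for (i in seq_len(max_tries + 1)) {
    y <- integrate_to(y, horizon)
    dn <- max(abs(kinase_derivatives(y, drive, p)))
    if (dn < tol) {
      attr(y, "deriv_norm") <- dn
      return(y)
    }
    horizon <- if (i == 1) t_max else horizon * 10
  }
  stop("kinase_steady_state failed to converge: derivative norm ",
       format(dn), " after ", format(horizon / 10), " s of pseudo-time")
}

#' Steady-state CaMKII activity versus ROS
#'
#' Convenience sweep used for dose-response work: the steady active
#' fraction at a fixed CaM drive over a grid of ROS concentrations,
#' normalized to its own maximum if `normalize = TRUE`.
#'
#' @param ros_um numeric vector of ROS concentrations, uM.
#' @param params kinase parameters.
#' @param ca4cam,ca2cam constant CaM drive, uM; the low default mimics
#'   an activity assay dominated by the oxidation-induced autonomy.
#' @param normalize divide activities by their maximum over the grid.
#' @return data.frame with columns `ros_um`, `activity`.
#' @export
camkii_dose_response <- function(ros_um, params = kinase_params(),
                                 ca4cam = 0.01, ca2cam = 0,
                                 normalize = TRUE) {
  act <- vapply(ros_um, function(r) {
    s <- kinase_steady_state(kinase_drive(Ca4CaM = ca4cam, Ca2CaM = ca2cam,
                                          ROS = r), params, tol = 1e-9)
    active_fraction(s)
  }, numeric(1))
  if (normalize && max(act) > 0) act <- act / max(act)
  data.frame(ros_um = ros_um, activity = act)
}

#' Fit the oxidation parameters to a dose-response table
#'
#' Least-squares fit of the model's steady-state normalized active fraction
#' versus ROS to a measured kinase-activity table, over the two oxidation
#' parameters `k_ox` and `Km_ROS`. Used to re-derive the shipped defaults
#' from activity-versus-ROS data.
#'
#' @param activity_table data.frame (or 2-column matrix) with columns
#'   `ros_um` and `activity_norm`, activities in `[0, 1]`; at least 3 rows
#'   spanning more than one ROS level.
#' @param params kinase parameters supplying everything except the fitted
#'   pair; also the fit's starting values.
#' @param ca4cam,ca2cam the CaM drive at which the assay is modeled.
#' @return list with `k_ox`, `Km_ROS`, `residual` (sum of squares), and
#'   `boundary` (TRUE when k_ox collapsed to ~0, i.e. no oxidation signal).
#' @export
fit_oxidation_params <- function(activity_table, params = kinase_params(),
                                 ca4cam = 0.01, ca2cam = 0) {
  tab <- as.data.frame(activity_table)
  if (ncol(tab) < 2) stop("activity table needs columns (ros_um, activity_norm)")
  names(tab)[1:2] <- c("ros_um", "activity_norm")
  if (nrow(tab) < 3) stop("need at least 3 dose-response rows")
  if (length(unique(tab$ros_um)) < 2)
    stop("degenerate table: all rows share one ROS level")
  if (any(tab$activity_norm < -1e-9 | tab$activity_norm > 1 + 1e-9))
    stop("activities must lie in [0, 1]")

  model_curve <- function(log_kox, log_km) {
    p <- params
    p$k_ox <- exp(log_kox); p$Km_ROS <- exp(log_km)
    camkii_dose_response(tab$ros_um, p, ca4cam, ca2cam,
                         normalize = TRUE)$activity
  }
  resid_fn <- function(theta)
    model_curve(theta[1], theta[2]) - tab$activity_norm
  start <- c(log(params$k_ox), log(params$Km_ROS))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = log(c(1e-9, 1)),
                            upper = log(c(1e-3, 5e3)),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 15, ftol = 1e-10, ptol = 1e-8))
  k_ox <- exp(fit$par[1]); km <- exp(fit$par[2])
  boundary <- k_ox < 1e-12 ||
    max(tab$activity_norm) - min(tab$activity_norm) < 1e-6
  list(k_ox = k_ox, Km_ROS = km, residual = sum(fit$fvec^2),
       boundary = boundary)
}
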