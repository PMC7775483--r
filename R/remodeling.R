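#' Scenario configuration
#'
#' Bundles a model variant, ROS level, clamp specification, pacing
#' schedule and solver settings into a validated configuration object.
#' The presets used throughout are `"wt"`, `"wt_ros"`, `"oe"`, `"oe_ros"`
#' (ROS presets apply 200 uM, the pathophysiological oxidative-stress
#' level; the normal ROS background is ~35 uM).
#'
#' @param variant `"WT"` or `"CaMKII-OE"`.
#' @param ros_um constant ROS concentration, uM, >= 0.
#' @param clamps named list; recognized entries `na_i_mM`, `ca_sr_um`,
#'   `phos_LTCC`, `phos_PLB`, `phos_RyR` (levels; applied by protocols).
#' @param pacing list with `freq_hz` and `duration_s` (protocols may
#'   override with their own schedules).
#' @param solver list with `rtol`, `atol`, `dt_out` (ms), `hmax` (ms).
#' @param seed integer seed recorded for randomized sweeps.
#' @param params optional `cell_params` vector; built from the variant
#'   when NULL.
#' @return list of class `scenario_config` with a resolved `params` entry.
#' @export
scenario_config <- function(variant = c("WT", "CaMKII-OE"), ros_um = 0,
                            clamps = list(), pacing = list(freq_hz = 1,
                                                           duration_s = 300),
                            solver = list(rtol = 1e-7, atol = 1e-9,
                                          dt_out = 0.5, hmax = 1),
                            seed = 1L, params = NULL) {
  variant <- match.arg(variant)
  if (!is.numeric(ros_um) || length(ros_um) != 1 || ros_um < 0)
    stop("ros_um must be a single number >= 0")
  known <- c("na_i_mM", "ca_sr_um", "phos_LTCC", "phos_PLB", "phos_RyR")
  bad <- setdiff(names(clamps), known)
  if (length(bad)) stop("unknown clamp target(s): ", paste(bad, collapse = ", "))
  bounds <- list(na_i_mM = c(4, 30), ca_sr_um = c(50, 2000),
                 phos_LTCC = c(0, 1), phos_PLB = c(0, 1), phos_RyR = c(0, 1))
  for (nm in names(clamps)) {
    b <- bounds[[nm]]
    if (clamps[[nm]] < b[1] || clamps[[nm]] > b[2])
      stop("clamp level for ", nm, " outside bounds [", b[1], ", ", b[2], "]")
  }
  if (is.null(params)) {
    params <- cell_params()
    if (variant == "CaMKII-OE") params <- apply_overexpression(params)
  }
  params <- apply_ros(params, ros_um)
  cfg <- list(variant = variant, ros_um = ros_um, clamps = clamps,
              pacing = pacing, solver = solver, seed = as.integer(seed),
              params = params)
  class(cfg) <- "scenario_config"
  cfg
}

#' Named scenario presets
#'
#' @param name one of `"wt"`, `"wt_ros"`, `"oe"`, `"oe_ros"`; with no
#'   argument, the preset names are returned.
#' @param ... passed on to [scenario_config()].
#' @return A `scenario_config`, or the preset names.
#' @export
scenario_presets <- function(name = NULL, ...) {
  presets <- list(
    wt = list(variant = "WT", ros_um = 0),
    wt_ros = list(variant = "WT", ros_um = 200),
    oe = list(variant = "CaMKII-OE", ros_um = 0),
    oe_ros = list(variant = "CaMKII-OE", ros_um = 200)
  )
  if (is.null(name)) return(names(presets))
  name <- match.arg(name, names(presets))
  do.call(scenario_config, c(presets[[name]], list(...)))
}

#' Apply the CaMKII-overexpression remodeling recipe
#'
#' Exactly five parameter changes relative to wild type: total CaMKII
#' concentration x6 (the cytosolic pool is a fixed ratio of the junctional
#' one, so both scale together), late-Na-current steady-state
#' inactivation midpoint shifted +6.8 mV (toward positive potentials,
#' inactivation only), the transient-outward K current's
#' closed/open-to-inactivated transition rate x5, inward-rectifier maximum
#' conductance x0.6 (-40%), and NCX maximum conductance x1.3 (+30%).
#' Applying the recipe twice is rejected.
#'
#' @param base_params a wild-type `cell_params` vector.
#' @return Modified parameter vector with attribute `remodeled = TRUE`.
#' @export
apply_overexpression <- function(base_params) {
  if (isTRUE(attr(base_params, "remodeled")))
    stop("overexpression recipe already applied to this parameter set")
  p <- base_params
  p["camkii_tot_jn"] <- 6 * p["camkii_tot_jn"]
  p["hL_vshift"] <- p["hL_vshift"] + 6.8
  p["kf_to"] <- 5 * p["kf_to"]
  p["gK1"] <- 0.6 * p["gK1"]
  p["vncx"] <- 1.3 * p["vncx"]
  attr(p, "remodeled") <- TRUE
  p
}

#' Set the ROS level seen by every CaMKII compartment
#'
#' ROS is a constant concentration (no production/scavenging dynamics);
#' zero disables the oxidation pathway exactly.
#'
#' @param params `cell_params` vector or `scenario_config`.
#' @param ros_um concentration, uM, >= 0.
#' @return Same type as `params` with the ROS entry set.
#' @export
apply_ros <- function(params, ros_um) {
  if (!is.numeric(ros_um) || length(ros_um) != 1 || !is.finite(ros_um) ||
      ros_um < 0)
    stop("ros_um must be a single finite number >= 0")
  if (inherits(params, "scenario_config")) {
    params$ros_um <- ros_um
    params$params["ros"] <- ros_um
    return(params)
  }
  params["ros"] <- ros_um
  params
}

#' Enumerate differences between two parameter sets
#'
#' @param a,b `cell_params` vectors.
#' @return data.frame with columns `name`, `a`, `b`, `ratio` for every
#'   entry that differs.
#' @export
params_diff <- function(a, b) {
  stopifnot(identical(names(a), names(b)))
  idx <- which(abs(unclass(a) - unclass(b)) >
                 1e-12 * pmax(abs(unclass(a)), 1e-300))
  data.frame(name = names(a)[idx], a = as.numeric(a[idx]),
             b = as.numeric(b[idx]),
             ratio = as.numeric(b[idx]) / as.numeric(a[idx]),
             row.names = NULL)
}

#' Read / write scenario configurations as JSON
#'
#' Round-trip serialization of a scenario: variant, ROS, clamps, pacing,
#' solver, seed, and any parameter overrides relative to the variant's
#' defaults (so files stay small and readable).
#'
#' @param cfg a `scenario_config`.
#' @param path file path.
#' @return `read_scenario_json` returns a `scenario_config`.
#' @export
write_scenario_json <- function(cfg, path) {
  base <- cell_params()
  if (cfg$variant == "CaMKII-OE") base <- apply_overexpression(base)
  base <- apply_ros(base, cfg$ros_um)
  ov <- params_diff(base, cfg$params)
  obj <- list(variant = cfg$variant, ros_um = cfg$ros_um,
              clamps = cfg$clamps, pacing = cfg$pacing,
              solver = cfg$solver, seed = cfg$seed,
              param_overrides = setNames(as.list(ov$b), ov$name),
              units = list(ros_um = "uM", time = "ms", voltage = "mV",
                           ca = "uM", na_k = "mM", current = "pA/pF"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- scenario_config(variant = obj$variant, ros_um = obj$ros_um,
                         clamps = as.list(obj$clamps),
                         pacing = as.list(obj$pacing),
                         solver = as.list(obj$solver),
                         seed = obj$seed)
  if (length(obj$param_overrides))
    cfg$params[names(obj$param_overrides)] <-
      as.numeric(unlist(obj$param_overrides))
  cfg
}
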