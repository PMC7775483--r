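#' RyR activation-threshold map
#'
#' Runs [ryr_threshold_search()] over a ([Ca]SR x RyR-phosphorylation)
#' grid. The pre-paced 1 Hz state is shared across cells. Cells where the
#' store releases without any probe are flagged ALWAYS_OPEN; per-cell
#' failures are recorded and the map still returned.
#'
#' @param config a `scenario_config`.
#' @param ca_sr_grid SR Ca axis, uM (strictly increasing, within
#'   [200, 800]).
#' @param phos_grid phosphorylation axis, fractions (strictly increasing,
#'   within [0.1, 0.8]).
#' @param init optional shared `protocol_result` from
#'   [pace_to_steady_state()].
#' @param ... passed to [ryr_threshold_search()].
#' @return data.frame of class `ryr_map` in long format with columns
#'   `ca_sr_um`, `phos_ryr`, `threshold_pApF`, `always_open`, `error`.
#' @export
build_threshold_map <- function(config,
                                ca_sr_grid = seq(200, 800, by = 50),
                                phos_grid = seq(0.1, 0.8, by = 0.1),
                                init = NULL, ...) {
  stopifnot(all(diff(ca_sr_grid) > 0), all(diff(phos_grid) > 0))
  if (is.null(init)) init <- pace_to_steady_state(config)
  grid <- expand.grid(ca_sr_um = ca_sr_grid, phos_ryr = phos_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    out <- tryCatch(
      ryr_threshold_search(config, grid$ca_sr_um[i], grid$phos_ryr[i],
                           init = init, ...),
      error = function(e) list(threshold = NA_real_, always_open = FALSE,
                               error = conditionMessage(e)))
    data.frame(ca_sr_um = grid$ca_sr_um[i], phos_ryr = grid$phos_ryr[i],
               threshold_pApF = out$threshold,
               always_open = isTRUE(out$always_open),
               error = if (is.null(out$error)) NA_character_ else out$error)
  })
  map <- do.call(rbind, res)
  class(map) <- c("ryr_map", class(map))
  map
}

#' First-beat release-amplitude map and balance region
#'
#' Runs [release_after_unclamp()] over the ([Ca]SR x phosphorylation)
#' grid and records the first-beat peak SR release flux. Cells whose
#' amplitude exceeds `balance_jrel` uM/ms form the balance region — the
#' domain where the store can release normally. With `n_beats` large the
#' per-cell time-to-stability is also meaningful.
#'
#' @inheritParams build_threshold_map
#' @param n_beats stimuli per cell (1 suffices for the first-beat map).
#' @param balance_jrel balance-region amplitude criterion, uM/ms.
#' @return data.frame of class `ryr_map` with columns `ca_sr_um`,
#'   `phos_ryr`, `jrel_first_uM_ms`, `in_balance`, `t_stab_s`, `error`.
#' @export
build_release_map <- function(config,
                              ca_sr_grid = seq(200, 800, by = 50),
                              phos_grid = seq(0.1, 0.8, by = 0.1),
                              init = NULL, n_beats = 1, balance_jrel = 5) {
  stopifnot(all(diff(ca_sr_grid) > 0), all(diff(phos_grid) > 0))
  if (is.null(init)) init <- pace_to_steady_state(config)
  grid <- expand.grid(ca_sr_um = ca_sr_grid, phos_ryr = phos_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    out <- tryCatch(
      release_after_unclamp(config, grid$ca_sr_um[i], grid$phos_ryr[i],
                            init = init, n_beats = n_beats),
      error = function(e) list(first_jrel = NA_real_, t_stab_s = NA_real_,
                               error = conditionMessage(e)))
    data.frame(ca_sr_um = grid$ca_sr_um[i], phos_ryr = grid$phos_ryr[i],
               jrel_first_uM_ms = out$first_jrel,
               in_balance = isTRUE(out$first_jrel > balance_jrel),
               t_stab_s = out$t_stab_s,
               error = if (is.null(out$error)) NA_character_ else out$error)
  })
  map <- do.call(rbind, res)
  class(map) <- c("ryr_map", class(map))
  map
}
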