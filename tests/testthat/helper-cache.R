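# shared fixtures: expensive protocol runs computed once per test session

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

steady_of <- function(preset, max_beats = 600) {
  cached(paste0("steady_", preset),
         pace_to_steady_state(scenario_presets(preset), max_beats = max_beats))
}

burst_of <- function(preset) {
  cached(paste0("burst_", preset),
         burst_protocol(scenario_presets(preset), init = steady_of(preset)))
}

# random valid kinase state from a fixed-seed stream
random_kinase_state <- function(rng) {
  w <- -log(rng(8))
  kinase_state(Pi = w[1], Pb = w[2], Pt = w[3], Pt2 = w[4], Pa = w[5],
               Pb2 = w[6], Pot = w[7], Po = w[8], normalize = TRUE)
}
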