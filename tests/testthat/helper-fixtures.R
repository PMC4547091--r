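# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_params <- function() model_params()

asymmetric_params <- function() model_params(p_lac = 30, p_tet = 35)

small_config <- function(n = 2000) generator_config(n_events = n)

# Event table with exact channel values (scatter filled with a constant).
manual_events <- function(gfp, rfp, fsc = 1e4, ssc = 3e3) {
  data.frame(fsc_a = rep_len(fsc, length(gfp)),
             ssc_a = rep_len(ssc, length(gfp)),
             gfp = gfp, rfp = rfp)
}

# Reference centroids at (gfp, rfp) = (100, 1) and (1, 100).
unit_refs <- function() {
  state_refs(manual_events(100, 1), manual_events(1, 100))
}

# Reference centroids from clean synthetic control populations.
synthetic_refs <- function() fixture("synthetic_refs", function() {
  cfg <- small_config()
  state_refs(gen_events(cfg, c(high_gfp = 1, high_rfp = 0), seed = 901),
             gen_events(cfg, c(high_gfp = 0, high_rfp = 1), seed = 902))
})

# Phenomenological bundle with known alpha = 1, reused across tests.
phenom_bundle <- function() fixture("phenom_bundle", function() {
  gen_bundle(small_config(), knobs = c(5, 10, 15, 20), true_alpha = 1,
             seed = 401)
})

# Small mechanistic bundle sweeping k_tet toward the upper saddle-node
# edge (~23.1 at defaults), reused across tests.
mech_bundle <- function() fixture("mech_bundle", function() {
  gen_mechanistic_bundle(model_params(), knobs = c(15, 18, 20, 21.5),
                         small_config(), n_cells = 500, seed = 402)
})

# Finite-difference Jacobian oracle (independent of the analytic one).
fd_jacobian <- function(state, params, h = 1e-6) {
  f <- function(s) toggle_rhs(s, params)
  j <- matrix(0, 2, 2)
  for (k in 1:2) {
    e <- c(0, 0); e[k] <- h * max(1, abs(state[k]))
    j[, k] <- (f(state + e) - f(state - e)) / (2 * e[k])
  }
  j
}
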