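#' Reaction propensities of the stochastic toggle switch
#'
#' The stochastic model has four reactions: production of each repressor
#' under Hill repression by the other, and first-order degradation of
#' each. Hill functions are evaluated on the integer counts directly
#' (system size 1: deterministic concentrations identify with molecule
#' counts, so spontaneous basin escapes are observable at counts of order
#' 100).
#'
#' @param counts integer length-2 vector `c(n_lacI, n_tetR)`.
#' @param params a [model_params()] object.
#' @return Named numeric length-4 vector: `prod_lacI`, `deg_lacI`,
#'   `prod_tetR`, `deg_tetR`.
#' @examples
#' propensities(c(0, 0), model_params())   # (50, 0, 50, 0)
#' @export
propensities <- function(counts, params) {
  counts <- check_counts(counts)
  params <- as_model_params(params)
  c(prod_lacI = params$p_tet / (1 + (counts[2] / params$k_tet)^params$hill_n),
    deg_lacI  = params$gamma * counts[1],
    prod_tetR = params$p_lac / (1 + (counts[1] / params$k_lac)^params$hill_n),
    deg_tetR  = params$gamma * counts[2])
}

check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) != 2L || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts)))
    stop("molecule counts must be two non-negative integers (n_lacI, n_tetR)")
  as.integer(round(counts))
}

#' One cell-doubling time in model time units
#'
#' Degradation is dilution by division at rate `gamma`, so the doubling
#' (generation) time is `ln(2)/gamma`.
#'
#' @param params a [model_params()] object.
#' @return generation time (model time units).
#' @export
generation_time <- function(params) log(2) / as_model_params(params)$gamma

#' Simulate one cell with the exact stochastic simulation algorithm
#'
#' Statistically exact SSA path: exponentially distributed waiting times,
#' reaction chosen with probability proportional to its propensity.
#' Randomness is drawn from R's RNG stream, so wrap calls in `set.seed()`
#' (or pass `seed`) for reproducibility.
#'
#' @param counts0 initial `c(n_lacI, n_tetR)`.
#' @param params a [model_params()] object.
#' @param t_end end time (> 0; simulation starts at t = 0).
#' @param snapshot_times optional increasing times at which to record the
#'   state instead of the full path.
#' @param seed optional integer seed.
#' @param max_events cap on stored reaction events for full paths.
#' @return If `snapshot_times` is given, a data.frame `t`, `n_lacI`,
#'   `n_tetR` at those times; otherwise the full event path as the same
#'   data.frame (first row the initial state).
#' @examples
#' path <- simulate_cell(c(98, 2), model_params(), t_end = 5, seed = 1)
#' tail(path, 1)
#' @export
simulate_cell <- function(counts0, params, t_end, snapshot_times = NULL,
                          seed = NULL, max_events = 1e7) {
  counts0 <- check_counts(counts0)
  params <- as_model_params(params)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(snapshot_times)) {
    stopifnot(all(diff(snapshot_times) >= 0), all(snapshot_times >= 0))
    m <- ssa_snapshots_cpp(counts0[1], counts0[2], 0, as.numeric(snapshot_times),
                           params$p_lac, params$p_tet, params$k_lac,
                           params$k_tet, params$gamma, params$hill_n)
    return(data.frame(t = snapshot_times, n_lacI = m[, 1], n_tetR = m[, 2]))
  }
  p <- ssa_path_cpp(counts0[1], counts0[2], 0, t_end,
                    params$p_lac, params$p_tet, params$k_lac, params$k_tet,
                    params$gamma, params$hill_n, as.integer(max_events))
  if (isTRUE(p$truncated))
    warning("SSA path truncated at max_events = ", max_events)
  data.frame(t = p$t, n_lacI = p$n_lacI, n_tetR = p$n_tetR)
}

#' Classify a cell's phenotypic state from molecule counts
#'
#' `high_lac` iff `n_lacI > n_tetR`; ties are labelled `high_tet` (a
#' documented, arbitrary tie rule).
#'
#' @param counts `c(n_lacI, n_tetR)` or a two-column matrix of counts.
#' @return character vector of `"high_lac"` / `"high_tet"`.
#' @export
classify_cell <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    m <- as.matrix(counts)[, 1:2, drop = FALSE]
  } else m <- matrix(check_counts(counts), ncol = 2)
  ifelse(m[, 1] > m[, 2], "high_lac", "high_tet")
}

#' Perturbation protocol for a stochastic ensemble
#'
#' Defines the equilibrate -> perturb -> recover protocol applied to an
#' ensemble of cells: each cell starts at the deterministic high-LacI
#' fixed point (rounded to integers), equilibrates, experiences one model
#' parameter switched to a perturbed value for a fixed duration, then
#' recovers at baseline. Durations are in generations (`ln(2)/gamma`).
#'
#' @param n_cells ensemble size (default 100).
#' @param equilibrate_gens equilibration length in generations (default 10).
#' @param perturbed_field which [model_params()] field is switched
#'   (default `"k_lac"`: raising the LacI dissociation constant
#'   destabilises the high-LacI state).
#' @param perturbed_value value during the perturbation.
#' @param duration_gens perturbation length in generations.
#' @param recover_gens recovery length in generations (default 10).
#' @param seed RNG seed for the ensemble.
#' @return list of class `perturbation_protocol`.
#' @export
perturbation_protocol <- function(n_cells = 100, equilibrate_gens = 10,
                                  perturbed_field = "k_lac",
                                  perturbed_value = 100,
                                  duration_gens = 1, recover_gens = 10,
                                  seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (any(c(equilibrate_gens, duration_gens, recover_gens) < 0))
    stop("protocol durations must be >= 0")
  if (perturbed_value <= 0) stop("perturbed_value must be positive")
  structure(list(n_cells = as.integer(n_cells),
                 equilibrate_gens = equilibrate_gens,
                 perturbed_field = perturbed_field,
                 perturbed_value = perturbed_value,
                 duration_gens = duration_gens,
                 recover_gens = recover_gens, seed = as.integer(seed)),
            class = "perturbation_protocol")
}

# High-LacI stable fixed point of `params`, rounded to integer counts.
high_lac_init <- function(params) {
  fps <- find_fixed_points(params)
  stable <- Filter(function(f) f$stability == "stable", fps)
  if (!length(stable)) stop("no stable fixed point at these parameters")
  st <- stable[[which.max(vapply(stable, function(f) f$state[1], numeric(1)))]]
  if (st$state[1] <= st$state[2])
    stop("no high-LacI stable state at these parameters")
  as.integer(round(unname(st$state)))
}

#' Run an equilibrate-perturb-recover protocol on a stochastic ensemble
#'
#' Each cell is simulated through the three phases with the perturbed
#' parameter switched and restored at exact phase boundaries; the
#' returned fraction is the proportion of cells still classified
#' `high_lac` at the end of the recovery phase.
#'
#' @param params baseline [model_params()].
#' @param protocol a [perturbation_protocol()].
#' @param keep_counts keep the per-cell final counts (default TRUE).
#' @return list of class `ensemble_result`: `fraction_high_lac`, `se`
#'   (binomial), `n_cells`, `final_counts` (matrix), plus per-phase
#'   fraction bookkeeping.
#' @examples
#' pr <- perturbation_protocol(n_cells = 20, duration_gens = 0.5, seed = 7)
#' apply_protocol(model_params(), pr)$fraction_high_lac
#' @export
apply_protocol <- function(params, protocol, keep_counts = TRUE) {
  params <- as_model_params(params)
  stopifnot(inherits(protocol, "perturbation_protocol"))
  pert <- set_param(params, protocol$perturbed_field, protocol$perturbed_value)
  gen <- generation_time(params)
  init <- high_lac_init(params)
  counts <- matrix(rep(init, each = protocol$n_cells), ncol = 2)
  set.seed(protocol$seed)
  run <- function(cts, p, gens) {
    if (gens <= 0) return(cts)
    ssa_ensemble_cpp(cts, gens * gen, p$p_lac, p$p_tet, p$k_lac, p$k_tet,
                     p$gamma, p$hill_n)
  }
  counts <- run(counts, params, protocol$equilibrate_gens)
  counts <- run(counts, pert,   protocol$duration_gens)
  counts <- run(counts, params, protocol$recover_gens)
  f <- mean(classify_cell(counts) == "high_lac")
  structure(list(fraction_high_lac = f,
                 se = sqrt(f * (1 - f) / protocol$n_cells),
                 n_cells = protocol$n_cells,
                 final_counts = if (keep_counts) counts else NULL,
                 protocol = protocol),
            class = "ensemble_result")
}

#' Sweep the perturbation duration
#'
#' Repeats [apply_protocol()] over a set of perturbation durations with
#' independent child seeds derived from the template's seed.
#'
#' @param params baseline [model_params()].
#' @param protocol template [perturbation_protocol()] (its `duration_gens`
#'   is overridden).
#' @param durations numeric vector of durations in generations (>= 2
#'   values).
#' @return data.frame with columns `duration_gens`, `fraction_high_lac`,
#'   `se`, `n_cells`, `seed`.
#' @examples
#' pr <- perturbation_protocol(n_cells = 20, seed = 3)
#' duration_sweep(model_params(), pr, c(0.2, 2))
#' @export
duration_sweep <- function(params, protocol, durations) {
  if (length(durations) < 2L) stop("need at least 2 durations")
  rows <- lapply(seq_along(durations), function(i) {
    pr <- protocol
    pr$duration_gens <- durations[i]
    pr$seed <- derive_seed(protocol$seed, "duration_sweep", i)
    res <- apply_protocol(params, pr, keep_counts = FALSE)
    data.frame(duration_gens = durations[i],
               fraction_high_lac = res$fraction_high_lac,
               se = res$se, n_cells = res$n_cells, seed = pr$seed)
  })
  do.call(rbind, rows)
}
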