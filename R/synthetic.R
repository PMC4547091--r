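#' Configuration of the synthetic cytometry generator
#'
#' The phenomenological generator draws per-cell fluorescence from a
#' two-state lognormal mixture on the log10 scale, multiplied by a
#' per-cell size factor that also drives the scatter channels (the
#' extrinsic-noise component a narrow scatter gate removes), plus an
#' additive autofluorescence floor. The mechanistic mode maps stochastic
#' molecule counts to fluorescence with per-molecule brightnesses `b_g`
#' (GFP per TetR) and `b_r` (RFP per LacI): the GFP reporter reads out
#' the TetR side of the circuit and the RFP reporter the LacI side, as in
#' the history design where disabling LacI yields the high-GFP state.
#'
#' @param states per-state, per-channel log10 mean and SD of
#'   fluorescence.
#' @param size_sd log10-SD of the per-cell size factor (default 0.1).
#' @param scatter log10 means/SDs of the scatter channels (size factor is
#'   added on the log scale).
#' @param autofluor additive floor per fluorescence channel (a.u.).
#' @param noise_sd log10-SD of per-channel measurement noise in
#'   mechanistic mode.
#' @param background_switch switched fraction in unperturbed controls
#'   (default 0.005, the ~0.5% background level).
#' @param n_events events per table (default 10000).
#' @param b_g,b_r fluorescence per molecule for mechanistic mode.
#' @param seed default seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
    states = list(
      high_gfp = list(gfp = c(mu = 2.8, sd = 0.15), rfp = c(mu = 0.8, sd = 0.15)),
      high_rfp = list(gfp = c(mu = 0.8, sd = 0.15), rfp = c(mu = 2.8, sd = 0.15))),
    size_sd = 0.1,
    scatter = list(fsc = c(mu = 4.0, sd = 0.05), ssc = c(mu = 3.5, sd = 0.05)),
    autofluor = c(gfp = 1, rfp = 1),
    noise_sd = 0.05,
    background_switch = 0.005,
    n_events = 10000,
    b_g = 30, b_r = 30,
    seed = 1L) {
  if (size_sd < 0 || noise_sd < 0) stop("SDs must be >= 0")
  if (background_switch < 0 || background_switch >= 1)
    stop("background_switch must lie in [0, 1)")
  if (n_events < 100) stop("n_events must be >= 100")
  structure(list(states = states, size_sd = size_sd, scatter = scatter,
                 autofluor = autofluor, noise_sd = noise_sd,
                 background_switch = background_switch,
                 n_events = as.integer(n_events), b_g = b_g, b_r = b_r,
                 seed = as.integer(seed)),
            class = "generator_config")
}

other_state <- function(state) {
  c(high_gfp = "high_rfp", high_rfp = "high_gfp")[[state]]
}

# Draw scatter + fluorescence for given per-event states, with optional
# log10 displacement (added to gfp, subtracted from rfp for shifts
# toward high_rfp) and SD scaling.
draw_events <- function(config, states, shift_log10 = 0, sd_scale = 1) {
  n <- length(states)
  size <- 10^rnorm(n, 0, config$size_sd)
  draw_channel <- function(chan, sign_shift) {
    mu <- vapply(states, function(s) config$states[[s]][[chan]][["mu"]], numeric(1))
    sdv <- vapply(states, function(s) config$states[[s]][[chan]][["sd"]], numeric(1))
    size * 10^rnorm(n, mu + sign_shift * shift_log10, sdv * sd_scale) +
      config$autofluor[[chan]]
  }
  data.frame(
    fsc_a = 10^(config$scatter$fsc[["mu"]] + log10(size) +
                  rnorm(n, 0, config$scatter$fsc[["sd"]])),
    ssc_a = 10^(config$scatter$ssc[["mu"]] + log10(size) +
                  rnorm(n, 0, config$scatter$ssc[["sd"]])),
    gfp = draw_channel("gfp", +1),
    rfp = draw_channel("rfp", -1),
    true_state = states,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cytometry event table
#'
#' Mixture draw over the two phenotypic states with the statistical
#' structure the analysis assumes: bimodal log-scale fluorescence,
#' size-driven extrinsic noise shared by scatter and fluorescence, an
#' autofluorescence floor, and ground-truth state labels.
#'
#' @param config a [generator_config()].
#' @param state_weights named weights over `high_gfp`/`high_rfp`
#'   (summing to 1).
#' @param n number of events (default `config$n_events`).
#' @param seed RNG seed (default `config$seed`).
#' @return event table with `true_state` labels.
#' @examples
#' tab <- gen_events(generator_config(n_events = 500), seed = 42)
#' table(tab$true_state)
#' @export
gen_events <- function(config,
                       state_weights = c(high_gfp = 1, high_rfp = 0),
                       n = NULL, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (abs(sum(state_weights) - 1) > 1e-9 || any(state_weights < 0))
    stop("state_weights must be non-negative and sum to 1")
  n <- n %||% config$n_events
  set.seed(seed %||% config$seed)
  states <- sample(names(state_weights), n, replace = TRUE,
                   prob = state_weights)
  validate_events(draw_events(config, states))
}

#' The eight perturbations and their default displacement parameters
#'
#' Each perturbation is modelled phenomenologically as a log10-space
#' displacement of the history-state cloud toward the alternative state
#' (`shift`, split symmetrically between the channels) together with a
#' broadening of the per-channel spread (`sd_scale`), producing the
#' intermediate, threshold-straddling distributions seen at the end of a
#' perturbation period. The displacement magnitudes are internal-
#' consistency placeholders, graded from mild to severe.
#'
#' @return data.frame with columns `perturbation_id`, `shift`,
#'   `sd_scale`.
#' @export
default_perturbations <- function() {
  data.frame(
    perturbation_id = c("weak_iptg", "strong_iptg", "heat", "weak_salt",
                        "strong_salt", "weak_ethanol", "strong_ethanol",
                        "glucose"),
    shift = c(0.8, 2.4, 1.6, 1.2, 2.0, 1.0, 2.2, 2.8),
    sd_scale = c(2.4, 2.4, 2.4, 2.4, 2.4, 2.4, 2.4, 2.4),
    stringsAsFactors = FALSE)
}

#' Redraw a perturbed population at the end of its recovery period
#'
#' Applies the generative switching rule: a cell's final state is
#' `high_rfp` when its end-of-perturbation GFP/RFP ratio lies below the
#' ground-truth separatrix intercept `true_alpha` (flipped with
#' probability `flip_noise`), after which its fluorescence is redrawn
#' from the final state's distribution.
#'
#' @param end_perturb event table at the end of the perturbation.
#' @param true_alpha ground-truth ratio threshold.
#' @param config the [generator_config()] used for the redraw.
#' @param history history state of the population.
#' @param flip_noise probability in `[0, 0.5)` of flipping the outcome.
#' @param seed RNG seed.
#' @return end-of-recovery event table with final-state labels.
#' @export
simulate_recovery <- function(end_perturb, true_alpha, config,
                              history = "high_gfp", flip_noise = 0,
                              seed = 1L) {
  if (flip_noise < 0 || flip_noise >= 0.5)
    stop("flip_noise must lie in [0, 0.5)")
  set.seed(seed)
  below <- end_perturb$gfp / end_perturb$rfp < true_alpha
  final <- ifelse(below, "high_rfp", "high_gfp")
  flip <- runif(nrow(end_perturb)) < flip_noise
  final[flip] <- vapply(final[flip], other_state, character(1))
  validate_events(draw_events(config, final))
}

#' Generate one perturbation record (end-perturb + end-recover tables)
#'
#' @param config a [generator_config()].
#' @param perturbation one row of [default_perturbations()] (or a list
#'   with `perturbation_id`, `shift`, `sd_scale`).
#' @param true_alpha ground-truth separatrix intercept.
#' @param history history state (default `"high_gfp"`).
#' @param n events per table (default `config$n_events`).
#' @param flip_noise recovery flip noise (default 0).
#' @param seed RNG seed.
#' @return a [perturbation_record()]; the end-perturb table keeps the
#'   history label in `true_state` (final states are not yet decided).
#' @export
gen_perturbation_record <- function(config, perturbation, true_alpha,
                                    history = "high_gfp", n = NULL,
                                    flip_noise = 0, seed = 1L) {
  n <- n %||% config$n_events
  set.seed(seed)
  # displacement toward the alternative state: sign of the shift on the
  # (gfp, rfp) log pair depends on the history being displaced
  sgn <- if (history == "high_gfp") -1 else 1
  ep <- draw_events(config, rep(history, n),
                    shift_log10 = sgn * perturbation$shift / 2,
                    sd_scale = perturbation$sd_scale)
  ep <- validate_events(ep)
  if (nrow(ep) == 0) stop("displacement produced an empty table")
  er <- simulate_recovery(ep, true_alpha, config, history = history,
                          flip_noise = flip_noise,
                          seed = derive_seed(seed, "recovery"))
  perturbation_record(perturbation$perturbation_id, ep, er)
}
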