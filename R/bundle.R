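#' Generate a phenomenological experiment bundle across a knob sweep
#'
#' A bundle holds, per control-knob value (the inducer proxy), the
#' unperturbed control tables for both histories plus a full set of
#' perturbation records for the probed history, all generated from known
#' ground truth: a per-knob separatrix intercept `true_alpha`, the
#' background switching level, and per-perturbation displacements.
#'
#' @param config a [generator_config()].
#' @param knobs numeric knob values (e.g. dissociation-constant proxies
#'   for an inducer concentration axis).
#' @param true_alpha ground-truth separatrix intercept, length 1 or
#'   `length(knobs)`.
#' @param perturbations data.frame as [default_perturbations()].
#' @param history perturbed history (default `"high_gfp"`).
#' @param n events per table (default `config$n_events`).
#' @param sd_scale per-knob scale factor on the state log10-SDs of the
#'   control tables (length 1 or `length(knobs)`); used to inject
#'   variance inflation near a bifurcation.
#' @param flip_noise recovery flip noise (default 0).
#' @param seed master seed.
#' @return list of class `experiment_bundle` with `knob_data` (named by
#'   knob: `control_high_gfp`, `control_high_rfp`, `records`), `truth`
#'   (generating parameters) and `config`.
#' @export
gen_bundle <- function(config, knobs, true_alpha = 1,
                       perturbations = default_perturbations(),
                       history = "high_gfp", n = NULL, sd_scale = 1,
                       flip_noise = 0, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  n <- n %||% config$n_events
  true_alpha <- rep(true_alpha, length.out = length(knobs))
  sd_scale <- rep(sd_scale, length.out = length(knobs))
  knob_data <- list()
  for (i in seq_along(knobs)) {
    k <- knobs[i]
    sk <- derive_seed(seed, "knob", i)
    bg <- config$background_switch
    ctrl <- function(hist, s) {
      set.seed(s)
      w <- setNames(c(1 - bg, bg), c(hist, other_state(hist)))
      states <- sample(names(w), n, replace = TRUE, prob = w)
      validate_events(draw_events(config, states, sd_scale = sd_scale[i]))
    }
    records <- lapply(seq_len(nrow(perturbations)), function(j)
      gen_perturbation_record(config, perturbations[j, ], true_alpha[i],
                              history = history, n = n,
                              flip_noise = flip_noise,
                              seed = derive_seed(sk, "pert", j)))
    knob_data[[as.character(k)]] <- list(
      control_high_gfp = ctrl("high_gfp", derive_seed(sk, "ctrl_g")),
      control_high_rfp = ctrl("high_rfp", derive_seed(sk, "ctrl_r")),
      records = records)
  }
  structure(list(knob_data = knob_data,
                 truth = list(true_alpha = setNames(true_alpha, knobs),
                              sd_scale = setNames(sd_scale, knobs),
                              history = history, mode = "phenomenological",
                              seed = seed),
                 config = config),
            class = "experiment_bundle")
}

# Map an ensemble of molecule counts to cytometry events: GFP reads the
# TetR count, RFP the LacI count, each scaled by brightness, the shared
# size factor, and lognormal measurement noise, over the
# autofluorescence floor.
counts_to_events <- function(counts, config, seed = 1L) {
  set.seed(seed)
  n <- nrow(counts)
  size <- 10^rnorm(n, 0, config$size_sd)
  gfp <- config$b_g * counts[, 2] * size * 10^rnorm(n, 0, config$noise_sd) +
    config$autofluor[["gfp"]]
  rfp <- config$b_r * counts[, 1] * size * 10^rnorm(n, 0, config$noise_sd) +
    config$autofluor[["rfp"]]
  states <- ifelse(classify_cell(counts) == "high_lac", "high_rfp", "high_gfp")
  validate_events(data.frame(
    fsc_a = 10^(config$scatter$fsc[["mu"]] + log10(size) +
                  rnorm(n, 0, config$scatter$fsc[["sd"]])),
    ssc_a = 10^(config$scatter$ssc[["mu"]] + log10(size) +
                  rnorm(n, 0, config$scatter$ssc[["sd"]])),
    gfp = gfp, rfp = rfp, true_state = states,
    stringsAsFactors = FALSE))
}

# Stable fixed points keyed by fluorescence state. high_gfp = high-TetR.
stable_states_by_history <- function(params) {
  fps <- find_fixed_points(params)
  stable <- Filter(function(f) f$stability == "stable", fps)
  out <- list(high_gfp = NULL, high_rfp = NULL)
  for (fp in stable) {
    key <- if (fp$state[2] > fp$state[1]) "high_gfp" else "high_rfp"
    out[[key]] <- fp
  }
  out$saddle <- Filter(function(f) f$stability == "saddle", fps)
  out
}

#' Default transient perturbations for mechanistic bundles
#'
#' Each perturbation transiently multiplies `k_tet` (weakening TetR
#' repression pushes the circuit toward the high-LacI / high-RFP state,
#' destabilising a high-GFP history) for a fixed number of generations.
#'
#' @return data.frame with `perturbation_id`, `k_mult`, `duration_gens`.
#' @export
default_mechanistic_perturbations <- function() {
  data.frame(
    perturbation_id = c("weak_iptg", "strong_iptg", "heat", "weak_salt",
                        "strong_salt", "weak_ethanol", "strong_ethanol",
                        "glucose"),
    k_mult = c(1.5, 4, 2.5, 2, 5, 1.8, 6, 8),
    duration_gens = 2,
    stringsAsFactors = FALSE)
}

#' Generate a mechanistic (Gillespie-driven) experiment bundle
#'
#' Runs stochastic ensembles of the toggle switch at each knob value
#' (the knob is the `k_tet` dissociation constant, the model proxy for
#' the inducer axis): control populations equilibrate from each stable
#' state; perturbation records additionally pass through a transient
#' parameter shift and a recovery phase. Counts are mapped to
#' fluorescence via [generator_config()] brightnesses, and the full
#' ground truth (generating parameters, per-knob fixed points, true
#' boundary ratio) is kept in `truth`.
#'
#' @param params baseline [model_params()] (its `k_tet` is overridden by
#'   each knob value).
#' @param knobs `k_tet` values to sweep.
#' @param config a [generator_config()].
#' @param n_cells cells per table (default 2000).
#' @param perturbations data.frame as
#'   [default_mechanistic_perturbations()].
#' @param equilibrate_gens,recover_gens phase lengths in generations.
#' @param seed master seed.
#' @return an `experiment_bundle`; knob values where a history state does
#'   not exist carry `NULL` control tables and are flagged in
#'   `truth$extinct`.
#' @export
gen_mechanistic_bundle <- function(params, knobs, config, n_cells = 2000,
                                   perturbations = default_mechanistic_perturbations(),
                                   equilibrate_gens = 10, recover_gens = 10,
                                   seed = 1L) {
  params <- as_model_params(params)
  stopifnot(inherits(config, "generator_config"))
  knob_data <- list(); truth_fp <- list(); extinct <- character(0)
  gen <- generation_time(params)
  for (i in seq_along(knobs)) {
    k <- knobs[i]
    pk <- set_param(params, "k_tet", k)
    ss <- stable_states_by_history(pk)
    sk <- derive_seed(seed, "mech_knob", i)
    run_phase <- function(counts, p, gens) {
      if (gens <= 0) return(counts)
      ssa_ensemble_cpp(counts, gens * gen, p$p_lac, p$p_tet, p$k_lac,
                       p$k_tet, p$gamma, p$hill_n)
    }
    equilibrated <- function(hist, s) {
      fp <- ss[[hist]]
      if (is.null(fp)) return(NULL)
      set.seed(s)
      init <- matrix(rep(as.integer(round(unname(fp$state))),
                         each = n_cells), ncol = 2)
      run_phase(init, pk, equilibrate_gens)
    }
    cg_counts <- equilibrated("high_gfp", derive_seed(sk, "eq_g"))
    cr_counts <- equilibrated("high_rfp", derive_seed(sk, "eq_r"))
    if (is.null(cg_counts)) extinct <- c(extinct, paste0(k, ":high_gfp"))
    if (is.null(cr_counts)) extinct <- c(extinct, paste0(k, ":high_rfp"))
    records <- list()
    if (!is.null(cg_counts)) {
      records <- lapply(seq_len(nrow(perturbations)), function(j) {
        pj <- perturbations[j, ]
        sj <- derive_seed(sk, "mech_pert", j)
        set.seed(sj)
        ppert <- set_param(pk, "k_tet", pk$k_tet * pj$k_mult)
        cts <- equilibrated("high_gfp", derive_seed(sj, "eq"))
        cts_p <- run_phase(cts, ppert, pj$duration_gens)
        ep <- counts_to_events(cts_p, config, derive_seed(sj, "map_p"))
        cts_r <- run_phase(cts_p, pk, recover_gens)
        er <- counts_to_events(cts_r, config, derive_seed(sj, "map_r"))
        perturbation_record(pj$perturbation_id, ep, er)
      })
    }
    knob_data[[as.character(k)]] <- list(
      control_high_gfp = if (is.null(cg_counts)) NULL else
        counts_to_events(cg_counts, config, derive_seed(sk, "map_g")),
      control_high_rfp = if (is.null(cr_counts)) NULL else
        counts_to_events(cr_counts, config, derive_seed(sk, "map_r")),
      records = records)
    truth_fp[[as.character(k)]] <- ss
  }
  structure(list(knob_data = knob_data,
                 truth = list(params = params, fixed_points = truth_fp,
                              extinct = extinct, mode = "mechanistic",
                              config = config, seed = seed),
                 config = config),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("Experiment bundle (%s): %d knob value(s)\n",
              x$truth$mode, length(x$knob_data)))
  for (nm in names(x$knob_data)) {
    kd <- x$knob_data[[nm]]
    cat(sprintf("  knob %s: controls [%s, %s], %d perturbation record(s)\n",
                nm,
                if (is.null(kd$control_high_gfp)) "high_gfp extinct" else "high_gfp",
                if (is.null(kd$control_high_rfp)) "high_rfp extinct" else "high_rfp",
                length(kd$records)))
  }
  invisible(x)
}

#' Write / read an experiment bundle as CSV tables plus a manifest
#'
#' The on-disk layout is a directory of per-condition CSV event tables
#' with a `manifest.csv` (file, knob, history, perturbation_id, phase)
#' and a `truth.yaml` holding every generating parameter needed by
#' downstream tests.
#'
#' @param bundle an `experiment_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (`read_bundle` returns the bundle).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(tab, knob, history, pid, phase) {
    if (is.null(tab)) return()
    fn <- sprintf("knob%s_%s_%s_%s.csv", knob, history, pid, phase)
    write_events(tab, file.path(dir, fn))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = fn, knob = knob, history = history, perturbation_id = pid,
      phase = phase, stringsAsFactors = FALSE)
  }
  for (nm in names(bundle$knob_data)) {
    kd <- bundle$knob_data[[nm]]
    add(kd$control_high_gfp, nm, "high_gfp", "none", "pre")
    add(kd$control_high_rfp, nm, "high_rfp", "none", "pre")
    hist <- bundle$truth$history %||% "high_gfp"
    for (rec in kd$records) {
      add(rec$end_perturb, nm, hist, rec$perturbation_id, "end_perturb")
      add(rec$end_recover, nm, hist, rec$perturbation_id, "end_recover")
    }
  }
  write.csv(do.call(rbind, manifest), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  truth <- bundle$truth
  truth$params <- if (!is.null(truth$params)) unclass(truth$params)
  truth$fixed_points <- NULL   # recomputable from params
  truth$config <- NULL
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(knob = "character"))
  truth <- if (file.exists(file.path(dir, "truth.yaml")))
    yaml::read_yaml(file.path(dir, "truth.yaml")) else list()
  knob_data <- list()
  for (nm in unique(manifest$knob)) {
    m <- manifest[manifest$knob == nm, ]
    get_tab <- function(sel) {
      if (!any(sel)) return(NULL)
      read_events(file.path(dir, m$file[sel][1]))
    }
    pre <- m$phase == "pre"
    pids <- unique(m$perturbation_id[m$phase == "end_perturb"])
    records <- lapply(pids, function(pid)
      perturbation_record(
        pid,
        get_tab(m$perturbation_id == pid & m$phase == "end_perturb"),
        get_tab(m$perturbation_id == pid & m$phase == "end_recover")))
    knob_data[[nm]] <- list(
      control_high_gfp = get_tab(pre & m$history == "high_gfp"),
      control_high_rfp = get_tab(pre & m$history == "high_rfp"),
      records = records)
  }
  structure(list(knob_data = knob_data, truth = truth, config = NULL),
            class = "experiment_bundle")
}

#' Reference centroids from a bundle's extreme knob values
#'
#' Builds [state_refs()] from the unperturbed control tables: the
#' high-GFP reference from the lowest knob value and the high-RFP
#' reference from the highest (mirroring reference distributions taken
#' at the extremes of the inducer axis).
#'
#' @param bundle an `experiment_bundle`.
#' @return a [state_refs()] object.
#' @export
bundle_refs <- function(bundle) {
  ks <- as.numeric(names(bundle$knob_data))
  lo <- names(bundle$knob_data)[which.min(ks)]
  hi <- names(bundle$knob_data)[which.max(ks)]
  tab_g <- bundle$knob_data[[lo]]$control_high_gfp
  tab_r <- bundle$knob_data[[hi]]$control_high_rfp
  if (is.null(tab_g) || is.null(tab_r))
    stop("missing control tables at the extreme knob values")
  state_refs(tab_g, tab_r)
}
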