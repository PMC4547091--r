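#' Validate a run configuration
#'
#' Reads a YAML run configuration, applies defaults, and checks every
#' invariant, reporting all violations at once. Recognised top-level
#' keys: `seed`, `out_dir`, `model` (fields of [model_params()]),
#' `generator` (fields of [generator_config()]), `bundle` (`knobs`,
#'   `true_alpha`, `history`, `n_events`, `sd_scale`), `gate`
#' (`target_count`, `resamples`), `sweep` (`n_cells`, `durations`,
#' `perturbed_field`, `perturbed_value`, `equilibrate_gens`,
#' `recover_gens`), `indicators` (`n_boot`).
#'
#' @param path YAML file path, or a list already parsed.
#' @return validated config (list of class `run_config`), or an error
#'   aggregating every violation.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)
  known <- c("seed", "out_dir", "model", "generator", "bundle", "gate",
             "sweep", "indicators")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    note(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg <- list(
    seed = raw$seed %||% 1L,
    out_dir = raw$out_dir %||% "switchres_results",
    model = raw$model %||% list(),
    generator = raw$generator %||% list(),
    bundle = raw$bundle %||% list(),
    gate = raw$gate %||% list(),
    sweep = raw$sweep %||% list(),
    indicators = raw$indicators %||% list())
  model <- tryCatch(do.call(model_params, cfg$model),
                    error = function(e) { note(conditionMessage(e)); NULL })
  generator <- tryCatch(do.call(generator_config, cfg$generator),
                        error = function(e) { note(conditionMessage(e)); NULL })
  knobs <- cfg$bundle$knobs %||% c(10, 15, 20, 25)
  if (anyDuplicated(knobs)) note("duplicate knob values in bundle$knobs")
  if (any(knobs <= 0)) note("bundle$knobs must be positive")
  if (!is.null(cfg$bundle$true_alpha) && any(cfg$bundle$true_alpha <= 0))
    note("bundle$true_alpha must be positive")
  perts <- cfg$bundle$perturbations %||% "default"
  if (!identical(perts, "default") && !identical(perts, "none"))
    note("bundle$perturbations must be \"default\" or \"none\"")
  gate_rs <- cfg$gate$resamples %||% 3
  gate <- tryCatch(gate_spec(target_count = cfg$gate$target_count %||% 200),
                   error = function(e) { note(conditionMessage(e)); NULL })
  durations <- cfg$sweep$durations %||% c(0.2, 0.5, 1, 2, 5, 10, 20)
  if (length(durations) < 2) note("sweep$durations needs >= 2 values")
  n_boot <- cfg$indicators$n_boot %||% 200
  if (n_boot < 2) note("indicators$n_boot must be >= 2")
  if (length(errs))
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(list(seed = as.integer(cfg$seed), out_dir = cfg$out_dir,
                 model = model, generator = generator,
                 bundle = list(knobs = knobs,
                               true_alpha = cfg$bundle$true_alpha %||% 1,
                               history = cfg$bundle$history %||% "high_gfp",
                               n_events = cfg$bundle$n_events,
                               sd_scale = cfg$bundle$sd_scale %||% 1,
                               perturbations = perts),
                 gate = gate, gate_resamples = gate_rs,
                 sweep = list(
                   n_cells = cfg$sweep$n_cells %||% 100,
                   durations = durations,
                   perturbed_field = cfg$sweep$perturbed_field %||% "k_lac",
                   perturbed_value = cfg$sweep$perturbed_value %||% 100,
                   equilibrate_gens = cfg$sweep$equilibrate_gens %||% 10,
                   recover_gens = cfg$sweep$recover_gens %||% 10),
                 n_boot = n_boot),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Config-driven end-to-end run realising the whole analysis arc:
#' stochastic duration sweep (`sweep.csv`), synthetic bundle generation,
#' gated switched fractions per condition (`fractions.csv`), separatrix
#' fits per knob (`alpha_fits.csv`), the empirical bifurcation diagram
#' (`bifurcation.csv`), early-warning indicators (`indicators.csv`), and
#' a run log with seeds. Deterministic for a fixed config and seed.
#'
#' @param config a [validate_config()] result (or a path to a YAML file).
#' @return the output directory, invisibly; on failure a `FAILED` marker
#'   naming the stage is left in the output directory.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run_log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("switchres run, R ", getRversion() |> as.character(), ", seed ",
      config$seed, "\n", sep = "", file = logf)
  stage <- "init"
  on_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e))
  }
  tryCatch({
    stage <- "gillespie_sweep"
    proto <- perturbation_protocol(
      n_cells = config$sweep$n_cells,
      equilibrate_gens = config$sweep$equilibrate_gens,
      perturbed_field = config$sweep$perturbed_field,
      perturbed_value = config$sweep$perturbed_value,
      recover_gens = config$sweep$recover_gens,
      seed = derive_seed(config$seed, "sweep"))
    sweep <- duration_sweep(config$model, proto, config$sweep$durations)
    write.csv(sweep, file.path(out, "sweep.csv"), row.names = FALSE)
    log_line("sweep: %d durations, n_cells = %d", nrow(sweep),
             config$sweep$n_cells)

    stage <- "synthetic_bundle"
    perts <- if (identical(config$bundle$perturbations, "none"))
      default_perturbations()[0, ] else default_perturbations()
    bundle <- gen_bundle(config$generator, config$bundle$knobs,
                         true_alpha = config$bundle$true_alpha,
                         history = config$bundle$history,
                         perturbations = perts,
                         n = config$bundle$n_events,
                         sd_scale = config$bundle$sd_scale,
                         seed = derive_seed(config$seed, "bundle"))
    refs <- bundle_refs(bundle)
    log_line("bundle: %d knobs, history %s", length(bundle$knob_data),
             config$bundle$history)

    stage <- "fractions"
    frac_rows <- list()
    for (nm in names(bundle$knob_data)) {
      kd <- bundle$knob_data[[nm]]
      for (rec in kd$records) {
        sf <- switch_fraction(rec$end_recover, config$bundle$history, refs,
                              gate = config$gate, r = config$gate_resamples,
                              seed = derive_seed(config$seed, "frac", nm,
                                                 rec$perturbation_id))
        frac_rows[[length(frac_rows) + 1L]] <- data.frame(
          knob = as.numeric(nm), perturbation_id = rec$perturbation_id,
          fraction = sf$fraction, se = sf$se, n_gated = sf$n_gated)
      }
    }
    fractions <- if (length(frac_rows)) do.call(rbind, frac_rows) else
      data.frame(knob = numeric(0), perturbation_id = character(0),
                 fraction = numeric(0), se = numeric(0),
                 n_gated = integer(0))
    write.csv(fractions, file.path(out, "fractions.csv"), row.names = FALSE)

    stage <- "separatrix_fit"
    fit_rows <- list(); fits <- list()
    for (nm in names(bundle$knob_data)) {
      kd <- bundle$knob_data[[nm]]
      if (!length(kd$records)) next
      af <- fit_alpha(kd$records, refs, history = config$bundle$history,
                      gate = config$gate, r = config$gate_resamples,
                      seed = derive_seed(config$seed, "alpha", nm))
      fits[[nm]] <- af
      fit_rows[[nm]] <- data.frame(
        knob = as.numeric(nm), alpha = af$alpha,
        log10_alpha = af$log10_alpha, msd = af$msd,
        alpha_mu = af$alpha_mu, alpha_sigma = af$alpha_sigma)
    }
    if (!length(fit_rows)) {
      log_line("separatrix fit skipped: no bistable knob carries records")
    } else {
      write.csv(do.call(rbind, fit_rows), file.path(out, "alpha_fits.csv"),
                row.names = FALSE)
    }

    stage <- "bifurcation"
    bif <- assemble_bifurcation(bundle$knob_data, refs,
                                history = config$bundle$history)
    write.csv(bif, file.path(out, "bifurcation.csv"), row.names = FALSE)

    stage <- "indicators"
    tabs <- lapply(bundle$knob_data, `[[`,
                   paste0("control_", config$bundle$history))
    ind <- indicator_series(tabs, config$bundle$history, refs,
                            gate = config$gate, n_boot = config$n_boot,
                            seed = derive_seed(config$seed, "ind"))
    write.csv(as.data.frame(ind), file.path(out, "indicators.csv"),
              row.names = FALSE)
    log_line("done")
  }, error = on_fail)
  invisible(out)
}
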