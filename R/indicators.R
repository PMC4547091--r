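#' Subset an event table to unswitched cells
#'
#' Early-warning statistics are computed only on cells that remain in the
#' state they were pre-grown in, so that mixing with the alternative
#' state does not masquerade as rising variability.
#'
#' @param table an event table.
#' @param history `"high_gfp"` or `"high_rfp"`.
#' @param refs [state_refs()].
#' @return the unswitched subset.
#' @export
unswitched_subset <- function(table, history, refs) {
  keep <- !classify_switched(table, history, refs)
  if (!any(keep))
    stop("state extinct at this condition: all cells have switched")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Channel matching the history state: instrument noise is minimised by
# reading the channel that is bright in that state.
history_channel <- function(history) {
  switch(history, high_gfp = "gfp", high_rfp = "rfp",
         stop("unknown history `", history, "`"))
}

#' Coefficient of variation
#'
#' Sample SD divided by sample mean, on linear or log10-transformed
#' values (n-1 SD convention).
#'
#' @param values positive numeric vector (length >= 2).
#' @param transform `"linear"` or `"log10"`.
#' @return the CV.
#' @examples
#' cv(c(1, 2, 3))            # sd 1, mean 2 -> 0.5
#' @export
cv <- function(values, transform = c("linear", "log10")) {
  transform <- match.arg(transform)
  if (length(values) < 2L) stop("need at least 2 values")
  if (transform == "log10") {
    if (any(values <= 0)) stop("log10 transform requires positive values")
    values <- log10(values)
  }
  m <- mean(values)
  if (m <= 0) stop("CV undefined: mean <= 0 after transform")
  sd(values) / m
}

#' Bootstrap standard error of a statistic
#'
#' SD of the statistic over `n_boot` with-replacement resamples.
#'
#' @param values numeric vector.
#' @param statistic function of a numeric vector returning one number.
#' @param n_boot number of resamples (default 200).
#' @param seed RNG seed.
#' @return the bootstrap SE.
#' @export
bootstrap_se <- function(values, statistic = mean, n_boot = 200, seed = 1L) {
  if (n_boot < 2) stop("need n_boot >= 2")
  set.seed(seed)
  n <- length(values)
  reps <- vapply(seq_len(n_boot), function(i)
    as.numeric(statistic(values[sample.int(n, n, replace = TRUE)])),
    numeric(1))
  sd(reps)
}

#' Early-warning indicator series across a control-knob sweep
#'
#' For each knob value, the mean fluorescence and the coefficients of
#' variation (linear and log10) of the history channel are computed on
#' gated, unswitched cells. Uncertainty follows the two conventions of
#' the underlying measurements: the mean's standard error comes from
#' `r_gates` random scatter-gate resamplings (gate placement moves the
#' size-correlated mean, which cell-level resampling cannot see), while
#' the CVs — invariant to the common size factor — carry bootstrap
#' standard errors. Knob values where the history state is extinct are
#' omitted with a warning.
#'
#' @param tables named list of unperturbed event tables; names are the
#'   knob values.
#' @param history `"high_gfp"` or `"high_rfp"`.
#' @param refs [state_refs()].
#' @param gate optional [gate_spec()] applied before the statistics
#'   (densest placement for the point estimates).
#' @param r_gates gate resamples for the mean's SE (default 3).
#' @param n_boot bootstrap resamples for the CV SEs (default 200).
#' @param seed master seed.
#' @return data.frame of class `indicator_series` with columns `knob`,
#'   `mean_fluor`, `se_mean`, `cv_linear`, `se_cv_linear`, `cv_log`,
#'   `se_cv_log`, `n_cells`; per-knob channel values kept in attribute
#'   `values`.
#' @export
indicator_series <- function(tables, history, refs, gate = NULL,
                             r_gates = 3, n_boot = 200, seed = 1L) {
  if (!length(tables) || is.null(names(tables)))
    stop("tables must be a non-empty named list (names = knob values)")
  chan <- history_channel(history)
  rows <- list(); kept_values <- list()
  for (nm in names(tables)) {
    tab0 <- tables[[nm]]
    if (is.null(tab0)) next
    s <- derive_seed(seed, "indicator", nm)
    gated <- if (is.null(gate)) tab0 else {
      g <- gate; g$placement <- "densest"
      apply_gate(tab0, g)
    }
    un <- tryCatch(unswitched_subset(gated, history, refs),
                   error = function(e) NULL)
    if (is.null(un)) {
      warning("knob ", nm, " omitted: ", history, " state extinct")
      next
    }
    v <- un[[chan]]
    gate_se <- function(stat_fn, sub_seed) {
      if (is.null(gate)) return(0)
      rs <- resample_gate_statistic(
        tab0, gate,
        function(g) stat_fn(unswitched_subset(g, history, refs)[[chan]]),
        r = r_gates, seed = derive_seed(s, sub_seed))
      rs$se
    }
    se_mean <- if (is.null(gate))
      bootstrap_se(v, mean, n_boot, derive_seed(s, 1))
    else gate_se(mean, 1)
    rows[[nm]] <- data.frame(
      knob = as.numeric(nm),
      mean_fluor = mean(v),
      se_mean = se_mean,
      cv_linear = cv(v, "linear"),
      se_cv_linear = bootstrap_se(v, function(x) cv(x, "linear"), n_boot,
                                  derive_seed(s, 2)),
      cv_log = cv(v, "log10"),
      se_cv_log = bootstrap_se(v, function(x) cv(x, "log10"), n_boot,
                               derive_seed(s, 3)),
      se_gate_cv_linear = gate_se(function(x) cv(x, "linear"), 4),
      se_gate_cv_log = gate_se(function(x) cv(x, "log10"), 5),
      n_cells = length(v))
    kept_values[[nm]] <- v
  }
  if (!length(rows)) stop("no knob value retained a surviving population")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "values") <- kept_values
  class(out) <- c("indicator_series", class(out))
  out
}

#' Trend of an indicator across the knob sweep
#'
#' Least-squares slope of an indicator against the knob value. The
#' confidence interval comes from a parametric bootstrap that perturbs
#' each knob's point estimate by its total standard error — the
#' gate-resampling SE for the mean; for the CVs the bootstrap SE
#' combined in quadrature with the gate-placement SE, so that the
#' significance call accounts for every measurement noise source — and
#' refits the slope; the trend is significant when the interval excludes
#' 0.
#'
#' @param series an [indicator_series()] result.
#' @param which `"mean_fluor"`, `"cv_linear"` or `"cv_log"`.
#' @param n_boot slope resamples (default 200).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list with `slope`, `ci` (length 2), `significant`.
#' @export
indicator_trend <- function(series, which = c("mean_fluor", "cv_linear",
                                              "cv_log"),
                            n_boot = 200, level = 0.95, seed = 1L) {
  which <- match.arg(which)
  if (nrow(series) < 2L)
    stop("need at least 2 knob values to assess a trend")
  knob <- series$knob
  y <- series[[which]]
  se <- switch(which,
               mean_fluor = series$se_mean,
               cv_linear = sqrt(series$se_cv_linear^2 +
                                  (series$se_gate_cv_linear %||% 0)^2),
               cv_log = sqrt(series$se_cv_log^2 +
                               (series$se_gate_cv_log %||% 0)^2))
  slope_of <- function(yy) unname(coef(lm(yy ~ knob))[2])
  slope <- slope_of(y)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    slope_of(y + rnorm(length(y), 0, se)), numeric(1))
  a <- (1 - level) / 2
  ci <- unname(quantile(boots, c(a, 1 - a)))
  list(slope = slope, ci = ci, significant = ci[1] > 0 || ci[2] < 0)
}
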