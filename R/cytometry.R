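#' Read a cytometry event table from CSV
#'
#' An event table has one row per cell with scatter channels `fsc_a`,
#' `ssc_a` (forward/side scatter area, proxies for cell size) and
#' fluorescence channels `gfp`, `rfp`; an optional `true_state` column
#' carries ground-truth labels for synthetic data. Rows with any
#' non-positive channel value are dropped and counted (attribute
#' `n_dropped`).
#'
#' @param path CSV file path.
#' @return validated event table (data.frame).
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_events(df)
}

#' @rdname read_events
#' @param table an event table.
#' @export
write_events <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Validate an event table
#'
#' @param df data.frame with columns `fsc_a`, `ssc_a`, `gfp`, `rfp`.
#' @return the table with non-positive rows dropped (count in attribute
#'   `n_dropped`).
#' @export
validate_events <- function(df) {
  required <- c("fsc_a", "ssc_a", "gfp", "rfp")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("event table is missing column(s): ", paste(missing, collapse = ", "))
  ok <- rowSums(!is.finite(as.matrix(df[required])) |
                as.matrix(df[required]) <= 0) == 0
  dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("event table has no valid events")
  rownames(df) <- NULL
  attr(df, "n_dropped") <- dropped
  df
}

#' Scatter-gate specification
#'
#' Gates are axis-aligned windows in (log10 FSC-A, log10 SSC-A) space,
#' used to select cells of roughly equal size so that fluorescence
#' variation reflects expression, not cell size. With
#' `window_width = NULL` (default) the gate retains exactly
#' `target_count` events nearest the placement centre (Chebyshev distance
#' in standardised log-scatter coordinates); with a numeric
#' `window_width` it retains events inside a quantile window of that
#' width per axis.
#'
#' @param target_count events to retain (default 200, a narrow gate out
#'   of ~10,000 collected events).
#' @param window_width optional quantile width per scatter axis in (0, 1].
#' @param placement `"densest"` (centre on the 2-D mode of the scatter
#'   density) or `"random"` (centre on a random event).
#' @param seed seed used by random placement.
#' @return list of class `gate_spec`.
#' @export
gate_spec <- function(target_count = 200, window_width = NULL,
                      placement = c("densest", "random"), seed = 1L) {
  placement <- match.arg(placement)
  if (!is.null(window_width) &&
      (window_width <= 0 || window_width > 1))
    stop("window_width must lie in (0, 1]")
  if (target_count < 1) stop("target_count must be >= 1")
  structure(list(target_count = as.integer(target_count),
                 window_width = window_width, placement = placement,
                 seed = as.integer(seed)),
            class = "gate_spec")
}

gate_center <- function(lf, ls, gate) {
  if (gate$placement == "densest") {
    k <- MASS::kde2d(lf, ls, n = 50)
    i <- which(k$z == max(k$z), arr.ind = TRUE)[1, ]
    c(k$x[i[1]], k$y[i[2]])
  } else {
    set.seed(gate$seed)
    i <- sample.int(length(lf), 1L)
    c(lf[i], ls[i])
  }
}

#' Apply a scatter gate to an event table
#'
#' @param table an event table.
#' @param gate a [gate_spec()].
#' @return the gated subset of `table` (channel values unchanged).
#' @examples
#' tab <- gen_events(generator_config(n_events = 2000), seed = 1)
#' nrow(apply_gate(tab, gate_spec(target_count = 200)))
#' @export
apply_gate <- function(table, gate = gate_spec()) {
  stopifnot(inherits(gate, "gate_spec"))
  n <- nrow(table)
  if (gate$target_count > n)
    stop("target_count (", gate$target_count, ") exceeds table size (", n, ")")
  if (!is.null(gate$window_width) && gate$window_width == 1)
    return(table)
  lf <- log10(table$fsc_a); ls <- log10(table$ssc_a)
  ctr <- gate_center(lf, ls, gate)
  if (is.null(gate$window_width)) {
    # exactly target_count nearest events, Chebyshev in standardised logs
    sf <- max(sd(lf), 1e-12); ss <- max(sd(ls), 1e-12)
    d <- pmax(abs(lf - ctr[1]) / sf, abs(ls - ctr[2]) / ss)
    keep <- order(d)[seq_len(gate$target_count)]
  } else {
    qf <- stats::ecdf(lf)(ctr[1]); qs <- stats::ecdf(ls)(ctr[2])
    w <- gate$window_width / 2
    rf <- quantile(lf, c(max(0, qf - w), min(1, qf + w)), names = FALSE)
    rs <- quantile(ls, c(max(0, qs - w), min(1, qs + w)), names = FALSE)
    keep <- which(lf >= rf[1] & lf <= rf[2] & ls >= rs[1] & ls <= rs[2])
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate a statistic on randomly placed gate resamples
#'
#' The gating uncertainty convention: a statistic is evaluated on `r`
#' randomly placed narrow gates and summarised as mean and standard
#' error across the gates (default `r = 3`).
#'
#' @param table an event table.
#' @param gate a [gate_spec()] (placement is forced to `"random"`).
#' @param statistic function of a gated event table returning one number.
#' @param r number of gate resamples (>= 2).
#' @param seed master seed; gate `i` uses a derived child seed.
#' @return list with `mean`, `se` (sd across gates / sqrt(r)), `values`.
#' @export
resample_gate_statistic <- function(table, gate, statistic, r = 3,
                                    seed = 1L) {
  if (r < 2) stop("need r >= 2 gate resamples")
  vals <- vapply(seq_len(r), function(i) {
    g <- gate
    g$placement <- "random"
    g$seed <- derive_seed(seed, "gate_resample", i)
    v <- tryCatch(statistic(apply_gate(table, g)),
                  error = function(e) stop("statistic failed on gate ", i,
                                           ": ", conditionMessage(e)))
    as.numeric(v)
  }, numeric(1))
  list(mean = mean(vals), se = sd(vals) / sqrt(r), values = vals)
}

log_ratio <- function(table) log10(table$gfp / table$rfp)

#' Reference centroids for switched/unswitched classification
#'
#' @param control_high_gfp,control_high_rfp unperturbed control event
#'   tables of cells settled in each state.
#' @return list of class `state_refs` with the two centroids (log10 gfp,
#'   log10 rfp) and the midpoint log-ratio used as the class boundary.
#' @export
state_refs <- function(control_high_gfp, control_high_rfp) {
  c1 <- centroid(control_high_gfp); c2 <- centroid(control_high_rfp)
  r1 <- unname(c1[1] - c1[2]); r2 <- unname(c2[1] - c2[2])
  if (abs(r1 - r2) < 1e-9)
    stop("reference centroids have coincident log-ratios")
  structure(list(high_gfp = c1, high_rfp = c2, midpoint = (r1 + r2) / 2),
            class = "state_refs")
}

#' Classify cells as switched relative to their history state
#'
#' A cell is switched when its log10(GFP/RFP) lies on the far side of the
#' midpoint between the two reference centroids' log-ratios, relative to
#' the state the population was grown in. Being ratio-based, the rule is
#' invariant to common rescaling of both channels, mirroring the slope-1
#' geometry of the separatrix while staying independent of any fitted
#' threshold.
#'
#' @param table an event table.
#' @param history `"high_gfp"` or `"high_rfp"`.
#' @param refs a [state_refs()] object.
#' @return logical vector, TRUE for switched cells.
#' @export
classify_switched <- function(table, history = c("high_gfp", "high_rfp"),
                              refs) {
  history <- match.arg(history)
  stopifnot(inherits(refs, "state_refs"))
  lr <- log_ratio(table)
  if (history == "high_gfp") lr < refs$midpoint else lr > refs$midpoint
}

#' Switched fraction with gate-resampling error
#'
#' @inheritParams classify_switched
#' @param gate a [gate_spec()].
#' @param r gate resamples (default 3).
#' @param seed master seed.
#' @return list of class `switch_fraction`: `fraction` (mean over gates),
#'   `se`, `n_gated`, `n_resamples`.
#' @export
switch_fraction <- function(table, history, refs, gate = gate_spec(),
                            r = 3, seed = 1L) {
  rs <- resample_gate_statistic(table, gate,
                                function(g) mean(classify_switched(g, history, refs)),
                                r = r, seed = seed)
  structure(list(fraction = rs$mean, se = rs$se,
                 n_gated = min(gate$target_count, nrow(table)),
                 n_resamples = r),
            class = "switch_fraction")
}

#' Switching kinetics across timepoints
#'
#' Computes the fraction of cells remaining in their history state over a
#' time course and a convexity statistic of the log-survival curve: the
#' mean second divided difference (times 2) of log(fraction remaining).
#' First-order (exponential) switching gives a straight log-survival
#' line, hence convexity 0; mixtures of fast and slow switchers give
#' positive convexity.
#'
#' @param tables list of event tables, one per timepoint.
#' @param times numeric timepoints (same length, >= 3).
#' @param history,refs as in [classify_switched()].
#' @return list with `times`, `surviving` (fraction remaining),
#'   `convexity`, and `truncated` flag (TRUE when survival hit 0 and the
#'   series was truncated for the log).
#' @export
switch_kinetics <- function(tables, times, history, refs) {
  if (length(tables) < 3L || length(times) != length(tables))
    stop("need >= 3 timepoints with one table each")
  surv <- vapply(tables, function(tb)
    1 - mean(classify_switched(tb, history, refs)), numeric(1))
  keep <- surv > 0
  truncated <- FALSE
  if (!all(keep)) {
    first0 <- which(!keep)[1]
    if (first0 <= 3L) {
      warning("survival reaches 0 too early for a convexity statistic")
      return(list(times = times, surviving = surv, convexity = NA_real_,
                  truncated = TRUE))
    }
    truncated <- TRUE
    warning("survival reached 0; log-survival truncated at timepoint ",
            first0 - 1L)
    times_u <- times[seq_len(first0 - 1L)]
    ls <- log(surv[seq_len(first0 - 1L)])
  } else {
    times_u <- times
    ls <- log(surv)
  }
  # second divided differences: 2 * f[t_{i-1}, t_i, t_{i+1}]
  n <- length(ls)
  sdd <- vapply(2:(n - 1L), function(i) {
    d1 <- (ls[i] - ls[i - 1]) / (times_u[i] - times_u[i - 1])
    d2 <- (ls[i + 1] - ls[i]) / (times_u[i + 1] - times_u[i])
    2 * (d2 - d1) / (times_u[i + 1] - times_u[i - 1])
  }, numeric(1))
  list(times = times, surviving = surv, convexity = mean(sdd),
       truncated = truncated)
}

#' Logarithmically binned histogram of a fluorescence channel
#'
#' @param table an event table.
#' @param channel `"gfp"`, `"rfp"`, `"fsc_a"` or `"ssc_a"`.
#' @param bins number of log10-spaced bins (>= 2).
#' @return list with `breaks` (bin edges, length `bins + 1`), `mids`
#'   (geometric bin centres) and `counts` (summing to `nrow(table)`).
#' @export
log_histogram <- function(table, channel = "gfp", bins = 50) {
  if (bins < 2) stop("need at least 2 bins")
  x <- table[[channel]]
  if (is.null(x)) stop("no channel `", channel, "` in table")
  lx <- log10(x)
  edges <- seq(min(lx), max(lx), length.out = bins + 1L)
  edges[1] <- edges[1] - 1e-9; edges[bins + 1L] <- edges[bins + 1L] + 1e-9
  counts <- tabulate(findInterval(lx, edges, rightmost.closed = TRUE),
                     nbins = bins)
  list(breaks = 10^edges, mids = 10^((edges[-1] + edges[-(bins + 1L)]) / 2),
       counts = counts)
}

# Count local maxima of a (smoothed) histogram; used by tests for
# bimodality checks.
histogram_modes <- function(h, smooth = 3) {
  cts <- as.numeric(stats::filter(h$counts, rep(1 / smooth, smooth),
                                  sides = 2))
  cts[is.na(cts)] <- h$counts[is.na(cts)]
  n <- length(cts)
  sum(vapply(2:(n - 1L), function(i)
    cts[i] > cts[i - 1] && cts[i] >= cts[i + 1] &&
      cts[i] > 0.05 * max(cts), logical(1)))
}
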