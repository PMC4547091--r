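#' Fraction of cells predicted to switch for a given ratio threshold
#'
#' Cells are assumed to switch phenotypes when the ratio of GFP to RFP
#' expression falls below the threshold `alpha` (equivalently, when they
#' lie below a slope-1 line with intercept `log10(alpha)` on a log-log
#' plot of the two channels).
#'
#' @param table an event table (end-of-perturbation distribution).
#' @param alpha positive ratio threshold.
#' @return proportion of events with `gfp/rfp < alpha`.
#' @export
predicted_fraction <- function(table, alpha) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  if (is.null(table$gfp) || nrow(table) == 0) stop("empty event table")
  mean(table$gfp / table$rfp < alpha)
}

#' Bundle one perturbation's end-of-perturbation and end-of-recovery
#' tables
#'
#' @param perturbation_id name of the perturbation (e.g. `"strong_salt"`).
#' @param end_perturb event table at the end of the perturbation period.
#' @param end_recover event table at the end of the recovery period.
#' @return list of class `perturbation_record`.
#' @export
perturbation_record <- function(perturbation_id, end_perturb, end_recover) {
  if (nrow(end_perturb) == 0 || nrow(end_recover) == 0)
    stop("perturbation record tables must be non-empty")
  structure(list(perturbation_id = perturbation_id,
                 end_perturb = end_perturb, end_recover = end_recover),
            class = "perturbation_record")
}

# Piecewise-constant MSD objective and its exhaustive candidate set:
# breakpoints are the pooled unique observed ratios; each constant piece
# is probed at the geometric midpoint of its bounding breakpoints, with
# half-decade sentinels beyond the extremes.
alpha_candidates <- function(ratios) {
  r <- sort(unique(ratios))
  c(r[1] / sqrt(10), sqrt(r[-1] * r[-length(r)]), r[length(r)] * sqrt(10))
}

alpha_msd <- function(alpha, end_perturb_list, measured) {
  pred <- vapply(end_perturb_list, predicted_fraction, numeric(1),
                 alpha = alpha)
  mean((pred - measured)^2)
}

#' Fit the separatrix intercept alpha from perturbation records
#'
#' For each perturbation, the distribution at the end of the perturbation
#' predicts a switched fraction as a function of the ratio threshold
#' `alpha`; the measured fraction is obtained from the end-of-recovery
#' table with the midpoint classifier (never with `alpha` itself, which
#' would be circular). `alpha` is chosen to minimise the mean-squared
#' deviation between predicted and measured fractions. The objective is
#' piecewise constant in `alpha` with breakpoints at the pooled observed
#' ratios, so the exact global minimum is found by enumerating one
#' candidate per piece; the returned `alpha` is the geometric midpoint of
#' the full minimising plateau.
#'
#' @param records list of [perturbation_record()]s (>= 1).
#' @param refs [state_refs()] used to measure switched fractions.
#' @param history history state of the perturbed populations (default
#'   `"high_gfp"`).
#' @param gate optional [gate_spec()]; when given, fractions are measured
#'   on gated events and the fit is additionally repeated on `r` random
#'   gate placements to give `alpha_mu`/`alpha_sigma`.
#' @param r number of gate resamples for the uncertainty (default 3).
#' @param seed master seed for gate placement.
#' @return list of class `alpha_fit`: `alpha`, `log10_alpha`, `msd`,
#'   `per_perturbation` (data.frame id/predicted/measured), `plateau`
#'   (bounding ratios), `alpha_mu`, `alpha_sigma` (NA without a gate).
#' @export
fit_alpha <- function(records, refs, history = "high_gfp", gate = NULL,
                      r = 3, seed = 1L) {
  if (!length(records)) stop("need at least one perturbation record")
  fit_once <- function(recs) {
    ep <- lapply(recs, `[[`, "end_perturb")
    measured <- vapply(recs, function(rec)
      mean(classify_switched(rec$end_recover, history, refs)), numeric(1))
    ratios <- sort(unique(unlist(lapply(ep, function(tb) tb$gfp / tb$rfp))))
    cand <- alpha_candidates(ratios)
    msds <- vapply(cand, alpha_msd, numeric(1),
                   end_perturb_list = ep, measured = measured)
    best <- msds <= min(msds) + 1e-15
    # plateau: contiguous run of minimising pieces containing the argmin
    runs <- rle(best)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    k <- which(runs$values & starts <= which.min(msds) &
                 ends >= which.min(msds))
    lo_i <- starts[k]; hi_i <- ends[k]
    # bounding breakpoints of the plateau (sentinel edges fall back to the
    # candidate itself)
    lo <- if (lo_i == 1L) cand[1] else ratios[lo_i - 1L]
    hi <- if (hi_i == length(cand)) cand[length(cand)] else ratios[hi_i]
    alpha <- sqrt(lo * hi)
    pred <- vapply(ep, predicted_fraction, numeric(1), alpha = alpha)
    list(alpha = alpha, msd = min(msds),
         per_perturbation = data.frame(
           perturbation_id = vapply(recs, `[[`, character(1), "perturbation_id"),
           predicted = pred, measured = measured),
         plateau = c(lo, hi))
  }
  if (is.null(gate)) {
    main <- fit_once(records)
    mu <- sig <- NA_real_
  } else {
    gate_records <- function(g) lapply(records, function(rec)
      perturbation_record(rec$perturbation_id,
                          apply_gate(rec$end_perturb, g),
                          apply_gate(rec$end_recover, g)))
    g0 <- gate; g0$placement <- "densest"
    main <- fit_once(gate_records(g0))
    alphas <- vapply(seq_len(r), function(i) {
      g <- gate
      g$placement <- "random"
      g$seed <- derive_seed(seed, "alpha_gate", i)
      fit_once(gate_records(g))$alpha
    }, numeric(1))
    mu <- mean(log10(alphas)); sig <- sd(log10(alphas))
  }
  structure(c(main, list(log10_alpha = log10(main$alpha),
                         alpha_mu = mu, alpha_sigma = sig)),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("Separatrix fit: alpha = %.4g (log10 = %.3f), MSD = %.4g\n",
              x$alpha, x$log10_alpha, x$msd))
  if (!is.na(x$alpha_mu))
    cat(sprintf("  over gate resamples: log10 alpha = %.3f +/- %.3f\n",
                x$alpha_mu, x$alpha_sigma))
  print(x$per_perturbation, row.names = FALSE)
  invisible(x)
}

#' Centroid of an event table in log-fluorescence space
#'
#' @param table a non-empty event table.
#' @return named numeric `c(log10_gfp, log10_rfp)` (arithmetic means of
#'   the log10 channel values).
#' @export
centroid <- function(table) {
  if (is.null(table$gfp) || nrow(table) == 0) stop("empty event table")
  c(log10_gfp = mean(log10(table$gfp)), log10_rfp = mean(log10(table$rfp)))
}

#' Estimate the unstable fixed point from the separatrix and centroid
#' line
#'
#' Cell switching paths approximately follow the log-space line
#' connecting the two stable-state centroids; the unstable fixed point is
#' estimated as the intersection of that line with the slope-1 separatrix
#' `log10(gfp) = log10(rfp) + log10(alpha)`.
#'
#' @param alpha fitted ratio threshold.
#' @param c_high_gfp,c_high_rfp centroids from [centroid()].
#' @return named numeric `c(gfp, rfp)` (linear units).
#' @export
estimate_unstable_fp <- function(alpha, c_high_gfp, c_high_rfp) {
  u1 <- c_high_gfp[["log10_gfp"]]; v1 <- c_high_gfp[["log10_rfp"]]
  u2 <- c_high_rfp[["log10_gfp"]]; v2 <- c_high_rfp[["log10_rfp"]]
  la <- log10(alpha)
  du <- u2 - u1; dv <- v2 - v1
  if (abs(du) < 1e-12 && abs(dv) < 1e-12)
    stop("degenerate geometry: centroids coincide")
  # line: (u, v) = (u1, v1) + t (du, dv); separatrix: u = v + la
  denom <- du - dv
  if (abs(denom) < 1e-9)
    stop("degenerate geometry: centroid line parallel to the separatrix")
  t <- (v1 + la - u1) / denom
  c(gfp = 10^(u1 + t * du), rfp = 10^(v1 + t * dv))
}

#' Assemble an empirical bifurcation diagram from per-knob records
#'
#' For each value of the control knob (the inducer proxy), the stable
#' branches are the centroids of the unswitched subpopulations of each
#' history, and at bistable knob values the unstable branch is estimated
#' from that knob's fitted separatrix intersected with the centroid line.
#'
#' @param knob_data named list (one element per knob value) of lists with
#'   components `control_high_gfp`, `control_high_rfp` (unperturbed event
#'   tables; either may be NULL when that state is extinct) and
#'   optionally `records` (perturbation records for the alpha fit).
#' @param refs [state_refs()] built from control tables at extreme knob
#'   values.
#' @param history history whose perturbation records are used (default
#'   `"high_gfp"`).
#' @return data.frame of class `bifurcation_data` with columns `knob`,
#'   `branch` (`stable_high_gfp`, `stable_high_rfp`, `unstable`), `gfp`,
#'   `rfp`, `bistable`, `alpha` (NA except on unstable rows).
#' @export
assemble_bifurcation <- function(knob_data, refs, history = "high_gfp") {
  if (!length(knob_data) || is.null(names(knob_data)))
    stop("knob_data must be a non-empty named list")
  rows <- list()
  for (nm in names(knob_data)) {
    kd <- knob_data[[nm]]
    knob <- as.numeric(nm)
    branch_centroid <- function(tab, hist) {
      if (is.null(tab)) return(NULL)
      un <- tab[!classify_switched(tab, hist, refs), , drop = FALSE]
      if (nrow(un) == 0) return(NULL)
      centroid(un)
    }
    cg <- branch_centroid(kd$control_high_gfp, "high_gfp")
    cr <- branch_centroid(kd$control_high_rfp, "high_rfp")
    bistable <- !is.null(cg) && !is.null(cr)
    if (!is.null(cg))
      rows[[length(rows) + 1L]] <- data.frame(
        knob = knob, branch = "stable_high_gfp", gfp = 10^cg[["log10_gfp"]],
        rfp = 10^cg[["log10_rfp"]], bistable = bistable, alpha = NA_real_)
    if (!is.null(cr))
      rows[[length(rows) + 1L]] <- data.frame(
        knob = knob, branch = "stable_high_rfp", gfp = 10^cr[["log10_gfp"]],
        rfp = 10^cr[["log10_rfp"]], bistable = bistable, alpha = NA_real_)
    if (bistable && !is.null(kd$records) && length(kd$records)) {
      af <- fit_alpha(kd$records, refs, history = history)
      up <- estimate_unstable_fp(af$alpha, cg, cr)
      rows[[length(rows) + 1L]] <- data.frame(
        knob = knob, branch = "unstable", gfp = up[["gfp"]],
        rfp = up[["rfp"]], bistable = TRUE, alpha = af$alpha)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bifurcation_data", class(out))
  out
}
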