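#' Parameters of the two-repressor toggle switch
#'
#' The circuit couples two repressors, LacI and TetR, each transcribed from
#' a promoter repressed by the other. `p_lac` is the strength of the
#' LacI-repressed promoter (it drives TetR production) and `p_tet` the
#' strength of the TetR-repressed promoter (driving LacI); `k_lac` and
#' `k_tet` are the repression dissociation constants, `gamma` the shared
#' dilution/degradation rate set by cell division, and `hill_n` the Hill
#' exponent of the repression function (2 for cooperative dimer binding).
#'
#' Defaults are the equal-promoter parameter set used throughout the
#' deterministic and stochastic analyses: P = 50, K = 15, gamma = 0.5.
#'
#' @param p_lac,p_tet promoter strengths (production rate units), > 0.
#' @param k_lac,k_tet repression dissociation constants (concentration
#'   units), > 0.
#' @param gamma dilution/degradation rate (1/time), > 0.
#' @param hill_n Hill exponent, >= 1.
#' @return An object of class `model_params`.
#' @examples
#' model_params()                       # equal promoters, P = 50
#' model_params(p_lac = 30, p_tet = 35) # asymmetric promoter set
#' @export
model_params <- function(p_lac = 50, p_tet = 50, k_lac = 15, k_tet = 15,
                         gamma = 0.5, hill_n = 2) {
  p <- list(p_lac = p_lac, p_tet = p_tet, k_lac = k_lac, k_tet = k_tet,
            gamma = gamma, hill_n = hill_n)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("model_params: `", nm, "` must be a single non-negative finite number")
    # promoters may be 0 (deleted promoter, the frozen-repressor limit);
    # rate constants must be strictly positive
    if (v == 0 && !nm %in% c("p_lac", "p_tet"))
      stop("model_params: `", nm, "` must be strictly positive")
  }
  if (hill_n < 1) stop("model_params: `hill_n` must be >= 1")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Toggle-switch parameters:\n")
  cat(sprintf("  P_Lac = %g, P_Tet = %g (promoter strengths)\n", x$p_lac, x$p_tet))
  cat(sprintf("  K_Lac = %g, K_Tet = %g (dissociation constants)\n", x$k_lac, x$k_tet))
  cat(sprintf("  gamma = %g (dilution rate), Hill n = %g\n", x$gamma, x$hill_n))
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  do.call(model_params, as.list(x))
}

# Modify one field, revalidating.
set_param <- function(params, field, value) {
  if (!field %in% names(params))
    stop("unknown model parameter `", field, "`")
  p <- unclass(params)
  p[[field]] <- value
  do.call(model_params, p)
}

check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)) ||
      any(state < 0))
    stop("circuit state must be two finite non-negative numbers (lacI, tetR)")
  as.numeric(state)
}
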