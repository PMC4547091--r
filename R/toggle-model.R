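#' Right-hand side of the toggle-switch rate equations
#'
#' The deterministic model of the mutual-repression circuit:
#' \deqn{d[LacI]/dt = P_{Tet}/(1 + ([TetR]/K_{Tet})^n) - \gamma [LacI]}
#' \deqn{d[TetR]/dt = P_{Lac}/(1 + ([LacI]/K_{Lac})^n) - \gamma [TetR]}
#'
#' @param state numeric length-2 vector `c(lacI, tetR)`, non-negative.
#' @param params a [model_params()] object.
#' @return numeric length-2 vector `c(dlacI, dtetR)`.
#' @examples
#' toggle_rhs(c(0, 0), model_params())  # (50, 50): no repression, no decay
#' @export
toggle_rhs <- function(state, params) {
  state <- check_state(state)
  params <- as_model_params(params)
  lac <- state[1]; tet <- state[2]
  c(params$p_tet / (1 + (tet / params$k_tet)^params$hill_n) - params$gamma * lac,
    params$p_lac / (1 + (lac / params$k_lac)^params$hill_n) - params$gamma * tet)
}

# Analytic 2x2 Jacobian of toggle_rhs.
toggle_jacobian <- function(state, params) {
  lac <- state[1]; tet <- state[2]
  n <- params$hill_n
  dprod <- function(p, u, k) {
    # d/du [ p / (1 + (u/k)^n) ]
    -p * n * u^(n - 1) / k^n / (1 + (u / k)^n)^2
  }
  matrix(c(-params$gamma,                 dprod(params$p_tet, tet, params$k_tet),
           dprod(params$p_lac, lac, params$k_lac), -params$gamma),
         nrow = 2, byrow = TRUE)
}

# Steady-state tetR as a function of lacI, and the scalar residual whose
# roots are the lacI coordinates of fixed points. Substituting the tetR
# nullcline into the lacI nullcline reduces the 2-D steady state to one
# scalar equation, whose roots all lie in (0, p_tet/gamma].
ss_tet_of_lac <- function(lac, params) {
  params$p_lac / params$gamma / (1 + (lac / params$k_lac)^params$hill_n)
}

ss_residual <- function(lac, params) {
  tet <- ss_tet_of_lac(lac, params)
  lac - params$p_tet / params$gamma / (1 + (tet / params$k_tet)^params$hill_n)
}

#' Locate all fixed points of the toggle switch
#'
#' Reduces the steady state to a scalar equation in the LacI coordinate,
#' brackets every sign change on a log-spaced grid over the provable
#' containment box `[0, P_Tet/gamma]`, and refines each bracket by
#' bisection. Each root is polished, classified by the eigenvalues of the
#' analytic Jacobian, and deduplicated.
#'
#' @param params a [model_params()] object.
#' @param n_grid number of log-spaced bracketing points (default 2000).
#' @param lower lower end of the search bracket (default 1e-6).
#' @param tol residual tolerance passed to the bisection refinement.
#' @return A list of fixed points, each a list with `state` (named lacI,
#'   tetR), `eigenvalues`, and `stability` (`"stable"`, `"saddle"` or
#'   `"unstable"`), ordered by increasing lacI. Class `fixed_point_list`.
#' @examples
#' fps <- find_fixed_points(model_params())
#' length(fps)                 # 3: two stable states and a saddle
#' sapply(fps, `[[`, "stability")
#' @export
find_fixed_points <- function(params, n_grid = 2000, lower = 1e-6,
                              tol = 1e-12) {
  params <- as_model_params(params)
  if (params$p_lac <= 0 || params$p_tet <= 0)
    stop("fixed-point search needs strictly positive promoter strengths")
  upper <- params$p_tet / params$gamma
  if (lower <= 0 || lower >= upper)
    stop("search bracket must lie inside (0, P_Tet/gamma]; fixed points ",
         "provably lie in this box")
  grid <- exp(seq(log(lower), log(upper * (1 + 1e-9)), length.out = n_grid))
  res <- vapply(grid, ss_residual, numeric(1), params = params)
  sgn <- sign(res)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1L)) {
    if (sgn[i] == 0) roots <- c(roots, grid[i])
    else if (sgn[i] * sgn[i + 1L] < 0) {
      r <- stats::uniroot(ss_residual, c(grid[i], grid[i + 1L]),
                          params = params, tol = tol)
      roots <- c(roots, r$root)
    }
  }
  if (sgn[n_grid] == 0) roots <- c(roots, grid[n_grid])
  roots <- sort(roots)
  # deduplicate (relative tolerance on lacI)
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) / upper > 1e-9)]
  lapply_fp <- lapply(roots, function(lac) {
    st <- c(lacI = lac, tetR = ss_tet_of_lac(lac, params))
    classify_stability(st, params)
  })
  structure(lapply_fp, class = "fixed_point_list")
}

#' @export
print.fixed_point_list <- function(x, ...) {
  cat(length(x), "fixed point(s):\n")
  for (fp in x)
    cat(sprintf("  (lacI = %.4f, tetR = %.4f)  %s  [Re(eig) = %.4f, %.4f]\n",
                fp$state[1], fp$state[2], fp$stability,
                Re(fp$eigenvalues)[1], Re(fp$eigenvalues)[2]))
  invisible(x)
}

#' Classify the linear stability of a fixed point
#'
#' Evaluates the analytic Jacobian of the rate equations (diagonal
#' `-gamma`; off-diagonals the Hill-repression derivatives) at a candidate
#' fixed point and labels it by the signs of the eigenvalue real parts.
#'
#' @param fp numeric length-2 state at (or extremely near) a fixed point.
#' @param params a [model_params()] object.
#' @param residual_tol residual norm above which `fp` is rejected as not a
#'   fixed point; default `1e-8 * P_Tet / gamma`.
#' @param eig_tol eigenvalues with `|Re| <` this are marginal (error):
#'   stability cannot be decided linearly at a saddle-node.
#' @return list with `state`, `eigenvalues`, `stability`.
#' @export
classify_stability <- function(fp, params, residual_tol = NULL,
                               eig_tol = 1e-10) {
  params <- as_model_params(params)
  fp <- check_state(fp)
  scale <- max(params$p_lac, params$p_tet) / params$gamma
  residual_tol <- residual_tol %||% (1e-8 * scale)
  resid <- sqrt(sum(toggle_rhs(fp, params)^2))
  if (resid > residual_tol)
    stop(sprintf("not a fixed point: residual %.3g exceeds tolerance %.3g",
                 resid, residual_tol))
  ev <- eigen(toggle_jacobian(fp, params), only.values = TRUE)$values
  re <- Re(ev)
  if (any(abs(re) < eig_tol))
    stop("marginal fixed point: an eigenvalue real part lies within ",
         eig_tol, " of zero (saddle-node vicinity)")
  stability <- if (all(re < 0)) "stable" else if (all(re > 0)) "unstable"
               else "saddle"
  list(state = c(lacI = fp[1], tetR = fp[2]), eigenvalues = ev,
       stability = stability)
}

#' Integrate the deterministic toggle switch
#'
#' Solves the rate equations with `deSolve::ode` (lsoda).
#'
#' @param state0 initial `c(lacI, tetR)`.
#' @param params a [model_params()] object.
#' @param t_end final time (> 0).
#' @param n_steps number of output times (default 200).
#' @param tol relative and absolute tolerance for the integrator.
#' @return data.frame with columns `time`, `lacI`, `tetR`.
#' @examples
#' tr <- integrate_toggle(c(100, 0), model_params(), t_end = 50)
#' tail(tr, 1)  # converged to the high-LacI attractor near (97.7, 2.3)
#' @export
integrate_toggle <- function(state0, params, t_end, n_steps = 200,
                             tol = 1e-8) {
  state0 <- check_state(state0)
  params <- as_model_params(params)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive")
  f <- function(t, y, p) list(toggle_rhs(y, p))
  times <- seq(0, t_end, length.out = n_steps + 1L)
  out <- deSolve::ode(y = c(lacI = state0[1], tetR = state0[2]), times = times,
                      func = f, parms = params, rtol = tol, atol = tol)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("ODE integration failed (lsoda istate ", diagn[1], ")")
  out <- as.data.frame(out)
  if (any(!is.finite(as.matrix(out))))
    stop("ODE integration produced non-finite values")
  out
}

# Vectorized RK4 step for a whole matrix of states (rows = trajectories).
rk4_step_all <- function(L, T, dt, params) {
  n <- params$hill_n; g <- params$gamma
  fl <- function(L, T) params$p_tet / (1 + (T / params$k_tet)^n) - g * L
  ft <- function(L, T) params$p_lac / (1 + (L / params$k_lac)^n) - g * T
  k1l <- fl(L, T);                   k1t <- ft(L, T)
  k2l <- fl(L + dt/2 * k1l, T + dt/2 * k1t); k2t <- ft(L + dt/2 * k1l, T + dt/2 * k1t)
  k3l <- fl(L + dt/2 * k2l, T + dt/2 * k2t); k3t <- ft(L + dt/2 * k2l, T + dt/2 * k2t)
  k4l <- fl(L + dt * k3l, T + dt * k3t);     k4t <- ft(L + dt * k3l, T + dt * k3t)
  list(L = pmax(L + dt / 6 * (k1l + 2*k2l + 2*k3l + k4l), 0),
       T = pmax(T + dt / 6 * (k1t + 2*k2t + 2*k3t + k4t), 0))
}

#' Grid specification for basin mapping
#'
#' @param params a [model_params()] object (sets default bounds
#'   `[1e-2, 1.2 P/gamma]` per axis).
#' @param n points per axis (default 101).
#' @param lac_range,tet_range numeric length-2 bounds overriding defaults.
#' @param log logical; log-spaced axes (default TRUE).
#' @return list with `lac`, `tet` axis vectors and `log` flag.
#' @export
basin_grid <- function(params, n = 101, lac_range = NULL, tet_range = NULL,
                       log = TRUE) {
  params <- as_model_params(params)
  lac_range <- lac_range %||% c(1e-2, 1.2 * params$p_tet / params$gamma)
  tet_range <- tet_range %||% c(1e-2, 1.2 * params$p_lac / params$gamma)
  ax <- function(r) if (log) 10^seq(log10(r[1]), log10(r[2]), length.out = n)
                    else seq(r[1], r[2], length.out = n)
  list(lac = ax(lac_range), tet = ax(tet_range), log = log)
}

#' Map the basins of attraction of the toggle switch
#'
#' Labels every node of a grid of initial conditions by the stable fixed
#' point its trajectory reaches. All trajectories are advanced together
#' with a fixed-step RK4 scheme (step `0.1/gamma`), removing nodes as they
#' converge; nodes not within tolerance of any attractor by `t_max` are
#' marked unresolved (an error if more than 1% of nodes are).
#'
#' @param params a [model_params()] object.
#' @param grid a [basin_grid()] specification.
#' @param t_max maximum integration time (default `200/gamma`).
#' @param tol attractor-capture radius, relative to `P/gamma`
#'   (default 1e-3).
#' @return Object of class `basin_map`: list with `grid`, `labels` (an
#'   n-by-n integer matrix, rows indexing `lac`), and `attractors` (the
#'   stable fixed points, in `find_fixed_points` order). Nodes whose
#'   trajectories run into the saddle — initial conditions on the
#'   separatrix itself — are labelled `NA` and counted in attribute
#'   `n_on_boundary`.
#' @examples
#' bm <- basin_map(model_params(), basin_grid(model_params(), n = 21))
#' table(bm$labels)
#' @export
basin_map <- function(params, grid = basin_grid(params), t_max = NULL,
                      tol = 1e-3) {
  params <- as_model_params(params)
  t_max <- t_max %||% (200 / params$gamma)
  fps <- find_fixed_points(params)
  stable <- Filter(function(fp) fp$stability == "stable", fps)
  saddles <- Filter(function(fp) fp$stability == "saddle", fps)
  nl <- length(grid$lac); nt <- length(grid$tet)
  labels <- matrix(NA_integer_, nl, nt)
  res <- structure(list(grid = grid, labels = labels, attractors = stable),
                   class = "basin_map")
  if (length(stable) == 1L) {            # monostable: single-label map
    res$labels[] <- 1L
    attr(res, "n_on_boundary") <- 0L
    return(res)
  }
  # targets: stable attractors first, then saddles (captured nodes sit on
  # the separatrix and stay NA)
  A <- t(vapply(c(stable, saddles), function(fp) unname(fp$state),
                numeric(2)))
  n_stable <- length(stable)
  scale <- max(params$p_lac, params$p_tet) / params$gamma
  capture <- tol * scale
  init <- expand.grid(lac = grid$lac, tet = grid$tet)  # lac varies fastest
  L <- init$lac; T <- init$tet
  active <- seq_along(L)
  lab <- rep(NA_integer_, length(L))
  dt <- 0.1 / params$gamma
  n_steps <- ceiling(t_max / dt)
  check_every <- 25L
  for (s in seq_len(n_steps)) {
    st <- rk4_step_all(L[active], T[active], dt, params)
    L[active] <- st$L; T[active] <- st$T
    if (s %% check_every == 0L || s == n_steps) {
      d <- vapply(seq_len(nrow(A)),
                  function(a) sqrt((L[active] - A[a, 1])^2 +
                                   (T[active] - A[a, 2])^2),
                  numeric(length(active)))
      d <- matrix(d, ncol = nrow(A))
      hit <- apply(d, 1L, which.min)
      captured <- d[cbind(seq_along(hit), hit)] < capture
      lab[active[captured]] <- ifelse(hit[captured] <= n_stable,
                                      hit[captured], -1L)  # -1 = saddle
      active <- active[!captured]
      if (!length(active)) break
    }
  }
  n_unres <- length(active)
  if (n_unres > 0.01 * length(L))
    stop(n_unres, " of ", length(L),
         " basin trajectories unresolved at t_max (> 1%)")
  attr(res, "n_on_boundary") <- sum(lab == -1L, na.rm = TRUE)
  lab[!is.na(lab) & lab == -1L] <- NA_integer_
  res$labels <- matrix(lab, nl, nt)   # [i, j] = (lac_i, tet_j)
  res
}

#' Extract basin-boundary points from a basin map
#'
#' Scans grid lines in both directions for label changes between
#' adjacent resolved nodes, emitting the midpoint (geometric for log
#' grids); unresolved nodes sandwiched between the two basins sit on the
#' separatrix itself (their trajectories approach the saddle) and are
#' emitted at their own coordinates.
#'
#' Away from the attractors the separatrix bends toward horizontal /
#' vertical asymptotes (in log coordinates), so the straight-line
#' approximation is a statement about the region between the two stable
#' states — where perturbed cells actually lie; `trim_to_attractors`
#' restricts the returned points to the bounding box spanned by the two
#' attractors for that purpose.
#'
#' @param map a [basin_map()] result with exactly two basins.
#' @param trim_to_attractors keep only points inside the attractor
#'   bounding box (default FALSE).
#' @return data.frame with columns `lacI`, `tetR`.
#' @export
extract_boundary <- function(map, trim_to_attractors = FALSE) {
  stopifnot(inherits(map, "basin_map"))
  labs <- unique(stats::na.omit(as.vector(map$labels)))
  if (length(labs) < 2L) stop("no boundary: basin map has fewer than 2 basins")
  mid <- function(a, b) if (map$grid$log) sqrt(a * b) else (a + b) / 2
  scan_line <- function(lab, x) {
    idx <- which(!is.na(lab))
    out <- numeric(0)
    if (length(idx) < 2L) return(out)
    for (t in seq_len(length(idx) - 1L)) {
      i <- idx[t]; j <- idx[t + 1L]
      if (lab[i] == lab[j]) next
      out <- c(out, if (j == i + 1L) mid(x[i], x[j]) else x[(i + 1L):(j - 1L)])
    }
    out
  }
  lac <- map$grid$lac; tet <- map$grid$tet
  L <- map$labels
  pts_l <- pts_t <- numeric(0)
  for (j in seq_along(tet)) {                 # along the lac axis
    b <- scan_line(L[, j], lac)
    pts_l <- c(pts_l, b); pts_t <- c(pts_t, rep(tet[j], length(b)))
  }
  for (i in seq_along(lac)) {                 # along the tet axis
    b <- scan_line(L[i, ], tet)
    pts_l <- c(pts_l, rep(lac[i], length(b))); pts_t <- c(pts_t, b)
  }
  if (!length(pts_l)) stop("no boundary: basins not adjacent on this grid")
  out <- data.frame(lacI = pts_l, tetR = pts_t)
  if (trim_to_attractors) {
    A <- t(vapply(map$attractors, function(f) unname(f$state), numeric(2)))
    out <- out[out$lacI >= min(A[, 1]) & out$lacI <= max(A[, 1]) &
                 out$tetR >= min(A[, 2]) & out$tetR <= max(A[, 2]), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Fit a line to basin-boundary points
#'
#' Least-squares fit of `tetR` on `lacI`, by default in log10-log10 space
#' where the separatrix of the (near-)symmetric toggle switch is close to
#' a straight line; a linear-space fit is available for diagnostics.
#'
#' @param points data.frame from [extract_boundary()].
#' @param space `"log10"` (default) or `"linear"`.
#' @return Object of class `boundary_line`: list with `slope`, `intercept`,
#'   `r_squared`, `space`, `points`.
#' @export
fit_boundary_line <- function(points, space = c("log10", "linear")) {
  space <- match.arg(space)
  if (nrow(points) < 2L) stop("need at least 2 boundary points to fit a line")
  x <- points$lacI; y <- points$tetR
  if (space == "log10") { x <- log10(x); y <- log10(y) }
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 space = space, points = points),
            class = "boundary_line")
}

#' @export
print.boundary_line <- function(x, ...) {
  cat(sprintf("Basin-boundary line (%s space): slope %.4f, intercept %.4f, R^2 %.4f (%d points)\n",
              x$space, x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Scan a control parameter for bistability
#'
#' Recomputes fixed points and their stability over a sweep of one model
#' parameter (typically a dissociation constant, the model proxy for an
#' inducer concentration). The bistable window is the maximal contiguous
#' run of sweep values with three fixed points; at its edges the saddle
#' collides with one stable branch (saddle-node bifurcation).
#'
#' @param params baseline [model_params()].
#' @param control name of the swept field (e.g. `"k_tet"`).
#' @param values sorted positive sweep values.
#' @return Object of class `bifurcation_scan`: list with `control`,
#'   `values`, `fixed_points` (list of `fixed_point_list`s) and
#'   `bistable_window` (`c(low, high)` or `NULL`).
#' @examples
#' sc <- bifurcation_scan(model_params(), "k_tet", c(1, 5, 15, 50, 150))
#' sc$bistable_window
#' @export
bifurcation_scan <- function(params, control, values) {
  params <- as_model_params(params)
  if (!length(values)) stop("empty sweep: `values` must be non-empty")
  if (is.unsorted(values) || any(values <= 0))
    stop("`values` must be sorted and positive")
  fps <- lapply(values, function(v)
    find_fixed_points(set_param(params, control, v)))
  counts <- vapply(fps, length, integer(1))
  window <- NULL
  r <- rle(counts == 3L)
  if (any(r$values)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    window <- c(low = values[starts[best]], high = values[ends[best]])
  }
  structure(list(control = control, values = values, fixed_points = fps,
                 bistable_window = window),
            class = "bifurcation_scan")
}

#' Tabulate a bifurcation scan
#'
#' @param x a `bifurcation_scan`.
#' @param ... unused.
#' @return data.frame with columns `control_value`, `lacI`, `tetR`,
#'   `stability`.
#' @export
as.data.frame.bifurcation_scan <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$values), function(i) {
    fps <- x$fixed_points[[i]]
    data.frame(control_value = x$values[i],
               lacI = vapply(fps, function(f) unname(f$state[1]), numeric(1)),
               tetR = vapply(fps, function(f) unname(f$state[2]), numeric(1)),
               stability = vapply(fps, `[[`, character(1), "stability"))
  }))
}

#' Write a basin map to CSV
#'
#' @param map a `basin_map`.
#' @param path output CSV path (columns `lac_init`, `tet_init`, `label`).
#' @export
write_basin_map <- function(map, path) {
  df <- expand.grid(lac_init = map$grid$lac, tet_init = map$grid$tet)
  df$label <- as.vector(map$labels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
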