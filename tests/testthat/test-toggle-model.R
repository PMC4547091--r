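# Deterministic toggle-switch model: rate equations, fixed points,
# stability, basins, boundary fits, bifurcation scans.

test_that("rate equations match hand values and respect the circuit symmetry", {
  p <- default_params()
  expect_equal(toggle_rhs(c(0, 0), p), c(50, 50))
  # fixed-point-iteration oracle value, frozen: L <- (P/g)/(1+(T/K)^2)
  expect_equal(toggle_rhs(c(97.69696007, 2.30303993), p), c(0, 0),
               tolerance = 1e-6)
  # swapping coordinates under symmetric parameters swaps the derivatives
  s <- c(12.3, 45.6)
  expect_equal(toggle_rhs(rev(s), p), rev(toggle_rhs(s, p)))
  expect_error(toggle_rhs(c(NA, 1), p), "finite")
})

test_that("fixed points at default parameters match the independent oracles", {
  fps <- find_fixed_points(default_params())
  expect_length(fps, 3L)
  expect_equal(vapply(fps, `[[`, character(1), "stability"),
               c("stable", "saddle", "stable"))
  # symmetric saddle: positive root of x^3 + 225 x - 22500 (uniroot oracle)
  saddle <- fps[[2]]
  expect_equal(unname(saddle$state), rep(25.583004647, 2), tolerance = 1e-8)
  # outer stable point from fixed-point iteration oracle
  expect_equal(unname(fps[[3]]$state), c(97.69696007, 2.30303993),
               tolerance = 1e-8)
  expect_equal(unname(fps[[1]]$state), c(2.30303993, 97.69696007),
               tolerance = 1e-8)
})

test_that("monostable parameters yield a single high-TetR fixed point", {
  fps <- find_fixed_points(model_params(k_lac = 100))
  expect_length(fps, 1L)
  expect_gt(fps[[1]]$state[2], fps[[1]]$state[1])
  expect_equal(fps[[1]]$stability, "stable")
})

test_that("the search bracket must sit inside the containment box", {
  expect_error(find_fixed_points(default_params(), lower = 200),
               "provably lie")
})

test_that("stability labels agree with a finite-difference Jacobian oracle", {
  for (p in list(default_params(), asymmetric_params(),
                 model_params(k_lac = 25, k_tet = 10))) {
    for (fp in find_fixed_points(p)) {
      ev_fd <- eigen(fd_jacobian(unname(fp$state), p), only.values = TRUE)$values
      expect_equal(sort(Re(fp$eigenvalues)), sort(Re(ev_fd)),
                   tolerance = 1e-6)
      stab_fd <- if (all(Re(ev_fd) < 0)) "stable" else
        if (all(Re(ev_fd) > 0)) "unstable" else "saddle"
      expect_identical(fp$stability, stab_fd)
    }
  }
})

test_that("saddle eigenvalues at defaults are -gamma +/- b with b ~ 0.744", {
  fp <- find_fixed_points(default_params())[[2]]
  expect_equal(sort(Re(fp$eigenvalues)),
               c(-0.5 - 0.74416995, -0.5 + 0.74416995), tolerance = 1e-6)
})

test_that("vanishing repression leaves pure decay (both eigenvalues -gamma)", {
  p <- model_params(k_lac = 1e9, k_tet = 1e9)
  fps <- find_fixed_points(p)
  expect_length(fps, 1L)
  expect_equal(Re(fps[[1]]$eigenvalues), c(-0.5, -0.5), tolerance = 1e-4)
  expect_equal(fps[[1]]$stability, "stable")
})

test_that("classify_stability rejects points that are not fixed points", {
  expect_error(classify_stability(c(50, 50), default_params()),
               "not a fixed point")
})

test_that("trajectories settle on the attractors", {
  p <- default_params()
  fp <- c(97.69696007, 2.30303993)
  tr <- integrate_toggle(fp, p, t_end = 20)
  expect_equal(unname(unlist(tr[nrow(tr), c("lacI", "tetR")])), fp,
               tolerance = 1e-5)
  tr2 <- integrate_toggle(c(100, 0), p, t_end = 60)
  expect_equal(unname(unlist(tr2[nrow(tr2), c("lacI", "tetR")])), fp,
               tolerance = 1e-4)
  # mirror start converges to the mirror attractor
  tr3 <- integrate_toggle(c(0, 100), p, t_end = 60)
  expect_equal(unname(unlist(tr3[nrow(tr3), c("lacI", "tetR")])), rev(fp),
               tolerance = 1e-4)
  expect_error(integrate_toggle(c(1, 1), p, t_end = -1), "positive")
})

test_that("all fixed points lie in the provable box with count in {1,2,3}", {
  set.seed(71)
  for (i in 1:12) {
    p <- model_params(p_lac = runif(1, 5, 80), p_tet = runif(1, 5, 80),
                      k_lac = runif(1, 2, 60), k_tet = runif(1, 2, 60),
                      gamma = runif(1, 0.2, 2))
    fps <- find_fixed_points(p)
    expect_true(length(fps) %in% c(1L, 3L) ||
                  length(fps) == 2L)  # 2 only exactly at a saddle-node
    for (fp in fps) {
      expect_true(fp$state[1] >= 0 && fp$state[1] <= p$p_tet / p$gamma + 1e-6)
      expect_true(fp$state[2] >= 0 && fp$state[2] <= p$p_lac / p$gamma + 1e-6)
      expect_lt(sqrt(sum(toggle_rhs(unname(fp$state), p)^2)), 1e-6)
    }
    # symmetric parameter sets give a swap-invariant fixed-point set
    ps <- model_params(p_lac = p$p_lac, p_tet = p$p_lac, k_lac = p$k_lac,
                       k_tet = p$k_lac, gamma = p$gamma)
    fps_s <- find_fixed_points(ps)
    states <- t(vapply(fps_s, function(f) unname(f$state), numeric(2)))
    swapped <- states[, 2:1, drop = FALSE]
    for (r in seq_len(nrow(states)))
      expect_true(any(rowSums(abs(swapped - matrix(states[r, ],
                                                   nrow(states), 2,
                                                   byrow = TRUE))) < 1e-5))
  }
})

test_that("symmetric basin map is swap-invariant and boundary is the diagonal", {
  p <- default_params()
  bm <- basin_map(p, basin_grid(p, n = 41))
  # same axes, so transposing and exchanging the two labels must agree
  lab <- bm$labels
  swapped <- t(lab)
  ok <- is.na(lab) | is.na(swapped) | (lab != swapped)
  expect_true(all(ok))
  fit <- fit_boundary_line(extract_boundary(bm))
  expect_equal(fit$slope, 1, tolerance = 0.02)
  expect_equal(fit$intercept, 0, tolerance = 0.05)
})

test_that("monostable parameters give a single-label map and no boundary", {
  p <- model_params(k_lac = 100)
  bm <- basin_map(p, basin_grid(p, n = 21))
  expect_length(bm$attractors, 1L)
  expect_true(all(bm$labels == 1L))
  expect_error(extract_boundary(bm), "no boundary")
})

test_that("asymmetric promoters displace the boundary off the diagonal", {
  p <- asymmetric_params()
  bm <- basin_map(p, basin_grid(p, n = 41))
  expect_length(bm$attractors, 2L)
  b <- extract_boundary(bm, trim_to_attractors = TRUE)
  fit <- fit_boundary_line(b)
  expect_gte(fit$r_squared, 0.95)
  expect_gt(abs(fit$intercept), 0.1)    # off the diagonal
})

test_that("vectorised basin integrator agrees with lsoda on sample nodes", {
  p <- asymmetric_params()
  bm <- basin_map(p, basin_grid(p, n = 21))
  A <- t(vapply(bm$attractors, function(f) unname(f$state), numeric(2)))
  set.seed(5)
  idx <- cbind(sample(21, 6), sample(21, 6))
  for (r in seq_len(nrow(idx))) {
    lab <- bm$labels[idx[r, 1], idx[r, 2]]
    if (is.na(lab)) next
    y0 <- c(bm$grid$lac[idx[r, 1]], bm$grid$tet[idx[r, 2]])
    tr <- integrate_toggle(y0, p, t_end = 400, n_steps = 50)
    fin <- unlist(tr[nrow(tr), c("lacI", "tetR")])
    d <- sqrt(rowSums((A - matrix(fin, nrow(A), 2, byrow = TRUE))^2))
    expect_identical(unname(which.min(d)), as.integer(lab))
  }
})

test_that("bifurcation scan brackets the bistable window on k_tet", {
  sc <- bifurcation_scan(default_params(), "k_tet",
                         10^seq(0, log10(200), length.out = 31))
  counts <- vapply(sc$fixed_points, length, integer(1))
  v <- sc$values
  expect_identical(counts[which.min(abs(v - 15))], 3L)
  expect_identical(counts[which.min(abs(v - 1))], 1L)
  expect_identical(counts[which.min(abs(v - 100))], 1L)
  expect_false(is.null(sc$bistable_window))
  # saddle-to-nearer-stable distance shrinks toward each window edge
  inside <- which(counts == 3L)
  gap <- vapply(inside, function(i) {
    fps <- sc$fixed_points[[i]]
    st <- t(vapply(fps, function(f) unname(f$state), numeric(2)))
    sad <- st[2, ]
    min(sqrt(rowSums((st[c(1, 3), , drop = FALSE] -
                        matrix(sad, 2, 2, byrow = TRUE))^2)))
  }, numeric(1))
  peak <- which.max(gap)
  expect_true(all(diff(gap[seq_len(peak)]) >= -1e-9) ||
                peak == 1L)
  expect_true(all(diff(gap[peak:length(gap)]) <= 1e-9) ||
                peak == length(gap))
})

test_that("k_lac and k_tet windows map onto each other under the swap", {
  vals <- 10^seq(0.5, 1.6, length.out = 15)
  sc_t <- bifurcation_scan(default_params(), "k_tet", vals)
  sc_l <- bifurcation_scan(default_params(), "k_lac", vals)
  expect_equal(sc_t$bistable_window, sc_l$bistable_window)
})

test_that("scan input validation", {
  expect_error(bifurcation_scan(default_params(), "k_tet", numeric(0)),
               "empty")
  sc <- bifurcation_scan(model_params(k_lac = 100), "k_tet", 15)
  expect_null(sc$bistable_window)
})
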