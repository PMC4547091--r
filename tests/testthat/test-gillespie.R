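# Stochastic simulation of the toggle switch and the
# equilibrate-perturb-recover protocol.

test_that("propensities follow the Hill production and linear decay terms", {
  p <- default_params()
  expect_equal(unname(propensities(c(0, 0), p)), c(50, 0, 50, 0))
  # counts at K halve production
  expect_equal(unname(propensities(c(15, 15), p))[c(1, 3)], c(25, 25))
  expect_equal(unname(propensities(c(98, 2), p))[c(2, 4)], c(49, 1))
  expect_error(propensities(c(-1, 0), p), "non-negative")
})

test_that("SSA paths are reproducible under a fixed seed", {
  p <- default_params()
  a <- simulate_cell(c(98, 2), p, t_end = 3, seed = 10)
  b <- simulate_cell(c(98, 2), p, t_end = 3, seed = 10)
  expect_identical(a, b)
  # counts never negative, time non-decreasing
  expect_true(all(a$n_lacI >= 0 & a$n_tetR >= 0))
  expect_true(all(diff(a$t) >= 0))
})

test_that("frozen-repressor limit matches the Poisson stationary law", {
  # p_lac = 0 keeps n_tetR at 0 forever; n_lacI is a linear birth-death
  # process with stationary mean = variance = P_Tet / gamma = 100
  p <- model_params(p_lac = 0)
  snap <- simulate_cell(c(100, 0), p, t_end = 1e5,
                        snapshot_times = seq(10, 1e5, by = 10), seed = 21)
  expect_true(all(snap$n_tetR == 0))
  x <- snap$n_lacI
  n <- length(x)                     # 10,000 near-independent samples
  se_mean <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 100), 3 * se_mean)
  se_var <- stats::var(x) * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(x) - 100), 3 * se_var)
})

test_that("a deep-basin cell stays high-LacI over ten generations", {
  p <- default_params()
  gen <- generation_time(p)
  set.seed(31)
  finals <- ssa_ensemble_cpp(matrix(rep(c(98L, 2L), each = 40), ncol = 2),
                             10 * gen, p$p_lac, p$p_tet, p$k_lac, p$k_tet,
                             p$gamma, p$hill_n)
  expect_gte(mean(classify_cell(finals) == "high_lac"), 0.9)
})

test_that("within-basin SSA ensemble mean matches the deterministic fixed point", {
  p <- default_params()
  gen <- generation_time(p)
  set.seed(32)
  finals <- ssa_ensemble_cpp(matrix(rep(c(98L, 2L), each = 200), ncol = 2),
                             10 * gen, p$p_lac, p$p_tet, p$k_lac, p$k_tet,
                             p$gamma, p$hill_n)
  keep <- classify_cell(finals) == "high_lac"
  for (k in 1:2) {
    x <- finals[keep, k]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - c(97.69696, 2.30304)[k]), 3 * se + 0.5)
  }
})

test_that("volume scaling reduces relative fluctuations like sqrt(Omega)", {
  # Omega = 10: production rates and dissociation constants (and the
  # initial counts) scale by 10; within-basin relative SD drops ~ sqrt(10)
  p1 <- default_params()
  p10 <- model_params(p_lac = 500, p_tet = 500, k_lac = 150, k_tet = 150)
  relsd <- function(p, init, seed) {
    snap <- simulate_cell(init, p, t_end = 2000,
                          snapshot_times = seq(20, 2000, by = 2), seed = seed)
    keep <- snap$n_lacI > snap$n_tetR   # stay within the high-Lac basin
    sd(snap$n_lacI[keep]) / mean(snap$n_lacI[keep])
  }
  r1 <- relsd(p1, c(98, 2), 41)
  r10 <- relsd(p10, c(977, 23), 42)
  expect_equal(r1 / r10, sqrt(10), tolerance = 0.3)
})

test_that("cell classification uses the count comparison with a tie rule", {
  expect_identical(classify_cell(c(98, 2)), "high_lac")
  expect_identical(classify_cell(c(2, 98)), "high_tet")
  expect_identical(classify_cell(c(5, 5)), "high_tet")
  m <- rbind(c(10, 1), c(1, 10))
  expect_identical(classify_cell(m), c("high_lac", "high_tet"))
})

test_that("protocol validation catches bad inputs", {
  expect_error(perturbation_protocol(duration_gens = -1), ">= 0")
  expect_error(perturbation_protocol(n_cells = 0), ">= 1")
  pr <- perturbation_protocol(n_cells = 5, seed = 1)
  expect_error(apply_protocol(default_params(),
                              structure(unclass(pr), class = "list")))
})

test_that("destabilising and stabilising K perturbations behave as expected", {
  p <- default_params()
  # raising K_Lac to 100 for 20 generations: monostable high-TetR during
  # the perturbation, 20 generations >> relaxation time -> all switch
  res_hi <- apply_protocol(p, perturbation_protocol(
    n_cells = 60, perturbed_value = 100, duration_gens = 20, seed = 51))
  expect_lte(res_hi$fraction_high_lac, 0.05)
  # lowering K_Lac to 1 stabilises the high-Lac state: no switching
  res_lo <- apply_protocol(p, perturbation_protocol(
    n_cells = 60, perturbed_value = 1, duration_gens = 10, seed = 52))
  expect_gte(res_lo$fraction_high_lac, 0.95)
  # zero-duration control: only background stochastic switching
  res_ctrl <- apply_protocol(p, perturbation_protocol(
    n_cells = 60, perturbed_value = 100, duration_gens = 0, seed = 53))
  expect_gte(res_ctrl$fraction_high_lac, 0.95)
})

test_that("switching increases with perturbation duration, for K and for P", {
  p <- default_params()
  durs <- c(0.2, 1, 2, 5, 20)
  check_monotone <- function(sw) {
    for (i in seq_len(nrow(sw) - 1L)) {
      slack <- 2 * sqrt(sw$se[i]^2 + sw$se[i + 1]^2) + 1e-9
      expect_lte(sw$fraction_high_lac[i + 1], sw$fraction_high_lac[i] + slack)
    }
  }
  sw_k <- duration_sweep(p, perturbation_protocol(
    n_cells = 60, perturbed_field = "k_lac", perturbed_value = 100,
    seed = 61), durs)
  check_monotone(sw_k)
  expect_gt(sw_k$fraction_high_lac[1] - sw_k$fraction_high_lac[nrow(sw_k)],
            0.5)
  # promoter-strength route: raising P_Lac floods the cell with TetR
  sw_p <- duration_sweep(p, perturbation_protocol(
    n_cells = 60, perturbed_field = "p_lac", perturbed_value = 500,
    seed = 62), durs)
  check_monotone(sw_p)
  expect_gt(sw_p$fraction_high_lac[1] - sw_p$fraction_high_lac[nrow(sw_p)],
            0.5)
  # a no-op "perturbation" stays flat at the control level
  sw_0 <- duration_sweep(p, perturbation_protocol(
    n_cells = 40, perturbed_field = "k_lac", perturbed_value = 15,
    seed = 63), c(0.2, 20))
  expect_true(all(sw_0$fraction_high_lac >= 0.95))
})

test_that("identical protocol seeds give identical ensemble results", {
  pr <- perturbation_protocol(n_cells = 20, duration_gens = 1, seed = 77)
  a <- apply_protocol(default_params(), pr)
  b <- apply_protocol(default_params(), pr)
  expect_identical(a$fraction_high_lac, b$fraction_high_lac)
  expect_identical(a$final_counts, b$final_counts)
})
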