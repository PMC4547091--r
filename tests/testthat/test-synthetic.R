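# Ground-truthed synthetic cytometry generator, phenomenological and
# mechanistic (Gillespie-driven) modes, and bundle round-trips.

test_that("single-state draws match the configured distribution", {
  cfg <- small_config(4000)
  tab <- gen_events(cfg, c(high_gfp = 1, high_rfp = 0), seed = 31)
  expect_true(all(tab$true_state == "high_gfp"))
  mu <- cfg$states$high_gfp$gfp[["mu"]]
  # log10 mean within 3 MC SEs (size and state SDs add in quadrature)
  s_tot <- sqrt(cfg$states$high_gfp$gfp[["sd"]]^2 + cfg$size_sd^2)
  expect_lt(abs(mean(log10(tab$gfp)) - mu), 3 * s_tot / sqrt(nrow(tab)) + 0.01)
  expect_error(gen_events(cfg, c(high_gfp = 0.6, high_rfp = 0.6)), "sum to 1")
})

test_that("control tables carry the ~0.5% background switched fraction", {
  cfg <- small_config(10000)
  tab <- gen_events(cfg, c(high_gfp = 0.995, high_rfp = 0.005), seed = 32)
  f <- mean(tab$true_state == "high_rfp")
  se <- sqrt(0.005 * 0.995 / nrow(tab))
  expect_lt(abs(f - 0.005), 3 * se)
})

test_that("recovery redraw applies the threshold rule exactly", {
  cfg <- small_config()
  ep <- manual_events(gfp = c(0.1, 1, 10), rfp = c(1, 1, 1))
  er <- simulate_recovery(ep, true_alpha = 0.5, cfg, seed = 33)
  expect_identical(er$true_state, c("high_rfp", "high_gfp", "high_gfp"))
  # all ratios above threshold: nothing switches
  er2 <- simulate_recovery(manual_events(gfp = c(5, 50), rfp = c(1, 1)),
                           true_alpha = 0.5, cfg, seed = 34)
  expect_true(all(er2$true_state == "high_gfp"))
  expect_error(simulate_recovery(ep, 0.5, cfg, flip_noise = 0.7), "0.5")
})

test_that("flip noise mixes outcomes toward one half in expectation", {
  cfg <- small_config()
  n <- 4000
  ep <- manual_events(gfp = rep(c(0.1, 10), each = n / 2), rfp = rep(1, n))
  er <- simulate_recovery(ep, true_alpha = 1, cfg, flip_noise = 0.1,
                          seed = 35)
  f <- mean(er$true_state == "high_rfp")
  # ideal fraction 0.5 is its own mixture fixed point here; probe the arms
  f_low <- mean(er$true_state[1:(n / 2)] == "high_rfp")     # ideal 1
  f_high <- mean(er$true_state[(n / 2 + 1):n] == "high_rfp") # ideal 0
  se <- sqrt(0.9 * 0.1 / (n / 2))
  expect_lt(abs(f_low - 0.9), 3 * se)
  expect_lt(abs(f_high - 0.1), 3 * se)
  expect_lt(abs(f - 0.5), 3 * se)
})

test_that("perturbation records grade with displacement and stay on one alpha", {
  cfg <- small_config()
  refs <- synthetic_refs()
  # zero-displacement control: essentially no switching at recovery
  ctrl <- gen_perturbation_record(
    cfg, list(perturbation_id = "ctrl", shift = 0, sd_scale = 1),
    true_alpha = 1, n = 2000, seed = 41)
  expect_lt(mean(classify_switched(ctrl$end_recover, "high_gfp", refs)),
            0.01)
  # displacement far past the threshold: everything switches
  deep <- gen_perturbation_record(
    cfg, list(perturbation_id = "deep", shift = 6, sd_scale = 1),
    true_alpha = 1, n = 2000, seed = 42)
  expect_gt(mean(classify_switched(deep$end_recover, "high_gfp", refs)),
            0.99)
  # graded displacements give graded measured fractions
  perts <- default_perturbations()
  fr <- vapply(order(perts$shift), function(j) {
    rec <- gen_perturbation_record(cfg, perts[j, ], true_alpha = 1,
                                   n = 2000, seed = 43 + j)
    mean(classify_switched(rec$end_recover, "high_gfp", refs))
  }, numeric(1))
  expect_true(all(diff(fr) > -0.05))
  expect_gt(fr[length(fr)] - fr[1], 0.5)
})

test_that("bundles round-trip through the CSV + manifest directory layout", {
  bun <- gen_bundle(small_config(300), knobs = c(5, 20), true_alpha = 1.5,
                    seed = 44)
  dir <- withr::local_tempdir()
  write_bundle(bun, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_bundle(dir)
  expect_identical(names(back$knob_data), names(bun$knob_data))
  expect_equal(back$knob_data[["5"]]$control_high_gfp$gfp,
               bun$knob_data[["5"]]$control_high_gfp$gfp, tolerance = 1e-9)
  expect_identical(length(back$knob_data[["20"]]$records), 8L)
  expect_equal(unname(unlist(back$truth$true_alpha)), c(1.5, 1.5))
})

test_that("every generated table passes cytometry validation with labels", {
  bun <- phenom_bundle()
  for (kd in bun$knob_data) {
    for (tab in c(list(kd$control_high_gfp, kd$control_high_rfp),
                  lapply(kd$records, `[[`, "end_perturb"),
                  lapply(kd$records, `[[`, "end_recover"))) {
      expect_silent(validate_events(tab))
      expect_true(!is.null(tab$true_state))
    }
  }
})

test_that("mechanistic monostable knob loses the high-GFP history", {
  cfg <- small_config()
  bun <- gen_mechanistic_bundle(model_params(), knobs = 100, cfg,
                                n_cells = 150, seed = 45)
  kd <- bun$knob_data[["100"]]
  expect_null(kd$control_high_gfp)
  expect_match(bun$truth$extinct, "100:high_gfp")
  # the surviving history converges to high RFP
  expect_gt(mean(kd$control_high_rfp$rfp > kd$control_high_rfp$gfp), 0.99)
})

test_that("mechanistic bistable knob shows bimodality and state memory", {
  bun <- mech_bundle()
  kd <- bun$knob_data[["15"]]
  expect_gt(mean(kd$control_high_gfp$true_state == "high_gfp"), 0.95)
  expect_gt(mean(kd$control_high_rfp$true_state == "high_rfp"), 0.95)
  pooled <- rbind(kd$control_high_gfp, kd$control_high_rfp)
  expect_gte(switchres:::histogram_modes(log_histogram(pooled, "gfp", 40)), 2)
})

test_that("mechanistic centroids track the deterministic fixed points", {
  bun <- mech_bundle()
  cfg <- bun$config
  for (nm in names(bun$knob_data)) {
    ss <- bun$truth$fixed_points[[nm]]
    tab <- bun$knob_data[[nm]]$control_high_gfp
    keep <- tab$true_state == "high_gfp"
    lg <- log10(tab$gfp[keep])
    se <- sd(lg) / sqrt(sum(keep))
    target <- log10(cfg$b_g * ss$high_gfp$state[["tetR"]])
    expect_lt(abs(mean(lg) - target), 3 * se + 0.02)
  }
})

test_that("bundle generation is reproducible from spec and seed", {
  a <- gen_bundle(small_config(300), knobs = c(5, 15), seed = 46)
  b <- gen_bundle(small_config(300), knobs = c(5, 15), seed = 46)
  expect_identical(a$knob_data, b$knob_data)
  m1 <- gen_mechanistic_bundle(model_params(), 15, small_config(),
                               n_cells = 60, seed = 47)
  m2 <- gen_mechanistic_bundle(model_params(), 15, small_config(),
                               n_cells = 60, seed = 47)
  expect_identical(m1$knob_data, m2$knob_data)
})
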