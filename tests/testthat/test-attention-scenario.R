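test_that("occupancy weighting is normalized, ordered by depth, and concentrates as tau -> 0", {
  baby <- analyze_landscape(model_parameters(T = 4, T0 = 5))
  p <- occupancy_probabilities(baby, tau = 0.3)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p[c("alert_protection", "trust_explore")]),
               c(0.5, 0.5), tolerance = 1e-12)

  zen <- analyze_landscape(model_parameters(T = 6, T0 = 5))
  expect_equal(as.numeric(occupancy_probabilities(zen, 0.1)), 1)

  # worked catastrophizing landscape: F(phi_ap) ~ -0.0385 below neutral
  cat <- analyze_landscape(model_parameters(h_int = 1, T = 5.1, T0 = 5))
  pc <- occupancy_probabilities(cat, tau = 0.01)
  expect_equal(unname(pc["alert_protection"]),
               1 / (1 + exp(-0.038531 / 0.01)), tolerance = 1e-3)
  expect_gt(pc["alert_protection"], pc["neutral"])

  # deeper wells are never less probable, and tau -> 0 concentrates
  draws <- sample_random_parameters(seed = 606, n = 50)
  for (pp in draws) {
    an <- analyze_landscape(pp)
    for (tau in c(1, 0.05)) {
      pr <- occupancy_probabilities(an, tau)
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      f <- an$wells$F_value[order(an$wells$F_value)]
      expect_true(all(diff(pr[order(vapply(names(pr), function(r)
        switch(r, alert_protection = an$alert_protection$F_value,
               neutral = an$neutral$F_value,
               trust_explore = an$trust_explore$F_value), numeric(1)))]) <= 1e-12))
    }
    tiny <- occupancy_probabilities(an, 1e-5)
    expect_gt(max(tiny), 1 - 1e-6)
  }
})

test_that("automatic attention takes the global minimum with documented tie policy", {
  cat <- analyze_landscape(model_parameters(h_int = 1, T = 5.1, T0 = 5))
  expect_equal(automatic_attention(cat)$phi, cat$alert_protection$phi)

  tie <- analyze_landscape(model_parameters(h_int = 3, T = 7, T0 = 5))
  expect_equal(automatic_attention(tie)$phi, 0)   # default favours liveliness
  expect_equal(automatic_attention(tie, "alert_protection")$phi, -2,
               tolerance = 1e-7)
  expect_equal(automatic_attention(tie, "keep_previous", previous = -1.5)$phi,
               -2, tolerance = 1e-7)
  expect_error(automatic_attention(tie, "keep_previous"), "previous")

  zen <- analyze_landscape(model_parameters(T = 6, T0 = 5))
  expect_equal(automatic_attention(zen)$phi, 0)
})

test_that("conscious attention reaches any existing extremum and names missing ones", {
  hyp <- analyze_landscape(model_parameters(h_int = 3, T = 4, T0 = 5))
  te <- conscious_attention(hyp, "trust_explore")
  expect_gt(te$phi, 0)
  expect_gt(te$F_value, min(hyp$wells$F_value))  # metastable is allowed
  expect_equal(conscious_attention(hyp, "maximum")$nature, "maximum")

  cat <- analyze_landscape(model_parameters(h_int = 1, T = 5.1, T0 = 5))
  expect_error(conscious_attention(cat, "trust_explore"),
               "alert_protection")
  baby <- analyze_landscape(model_parameters(T = 4, T0 = 5))
  expect_equal(conscious_attention(baby, "alert_protection")$phi, -1,
               tolerance = 1e-9)
})

test_that("the packaged neckache scenario reproduces the learning/unlearning regime sequence", {
  cfg <- load_config(system.file("extdata", "neckache_scenario.yaml",
                                 package = "sensescape"))
  traj <- run_scenario(do.call(model_parameters, cfg$parameters),
                       lapply(cfg$scenario$steps,
                              function(st) do.call(scenario_step, st)))
  expect_equal(traj$summary$regime,
               c("ZEN", "UNCERTAINTY_PESSIMISTIC", "CATASTROPHIZING",
                 "HYPERVIGILANCE_BIAS", "CATASTROPHIZING",
                 "HYPERVIGILANCE_BIAS", "HYPERVIGILANCE_BIAS",
                 "COMMUNICATIVE", "COMMUNICATIVE"))
  # nocebo message locks the organism into alert-protection; NBE alone does
  # not free it (hysteresis); belief revision does
  expect_equal(traj$summary$role[5:7], rep("alert_protection", 3))
  expect_equal(traj$summary$role[8:9], rep("trust_explore", 2))
  expect_true(traj$summary$jump[5])
})

test_that("an empty scenario equals a single landscape analysis", {
  p <- model_parameters(h_int = 1, T = 5.1, T0 = 5)
  traj <- run_scenario(p)
  expect_equal(nrow(traj$summary), 1)
  expect_equal(traj$records[[1]]$analysis$regime,
               analyze_landscape(p)$regime)
  expect_error(
    run_scenario(p, list(scenario_step("starve senses", delta_T = -99))),
    "step 1")
  expect_error(scenario_step("noop"), "at least one parameter")
})

test_that("parameter cycles are path independent without a spinodal crossing and dependent with one", {
  p <- par_a(1, h_int = 3)
  sp <- spinodal_fields(p)   # h_down ~ -0.0887

  steps_to <- function(h_seq) lapply(seq_along(h_seq), function(i)
    scenario_step(sprintf("h step %d", i), h_ext = h_seq[i]))

  # cycle truncated before h_down: returns to the starting basin
  shallow <- seq(0, sp$h_down + 0.02, length.out = 21)
  tr1 <- run_scenario(p, steps_to(c(shallow, rev(shallow)[-1])),
                      initial_state = "neutral")
  s1 <- tr1$summary
  expect_equal(s1$phi[nrow(s1)], s1$phi[1], tolerance = 1e-9)
  expect_false(any(s1$jump))
  expect_false(detect_hysteretic_cycle(tr1)$found)

  # cycle crossing h_down: ends in the other basin despite identical
  # parameters
  deep <- seq(0, sp$h_down - 0.05, length.out = 41)
  tr2 <- run_scenario(p, steps_to(c(deep, rev(deep)[-1])),
                      initial_state = "neutral")
  s2 <- tr2$summary
  expect_true(any(s2$jump))
  expect_equal(s2$role[1], "neutral")
  expect_equal(s2$role[nrow(s2)], "alert_protection")
  expect_gt(abs(s2$phi[nrow(s2)] - s2$phi[1]), 1)
})

test_that("a full nocebo/NBE cycle across both spinodals is a biopsychosocial loop", {
  p <- par_a(1, h_int = 3)
  sp <- spinodal_fields(p)
  h_min <- sp$h_down - 0.15; h_max <- sp$h_up + 0.15
  grid <- seq(h_min, h_max, length.out = 400)
  h0 <- min(grid[grid > 0.005])             # shared grid => exact revisits
  start <- par_a(1, h_int = 3, h_ext = h0)
  leg1 <- rev(grid[grid <= h0])[-1]         # h0 down to h_min
  leg2 <- grid[-1]                          # up to h_max
  leg3 <- rev(grid[grid >= h0])[-1]         # back down to h0 (closed)
  steps <- lapply(c(leg1, leg2, leg3), function(h)
    scenario_step("expert field", h_ext = h))
  traj <- run_scenario(start, steps, initial_state = "trust_explore")
  rep <- detect_hysteretic_cycle(traj)
  expect_true(rep$found)
  loop <- hysteresis_loop(p, h_min, h_max, n_points = 400)
  expect_lt(abs(abs(rep$signed_area) - loop$area) / loop$area, 0.05)

  # a monostable trajectory has no cycle despite parameter cycling
  mono <- run_scenario(par_a(1), lapply(c(0.5, -0.5, 0), function(h)
    scenario_step("wiggle", h_ext = h)))
  expect_false(detect_hysteretic_cycle(mono)$found)
})

test_that("the random parameter sampler is deterministic and respects ranges", {
  a <- sample_random_parameters(seed = 7, n = 5)
  b <- sample_random_parameters(seed = 7, n = 5)
  expect_identical(a, b)
  expect_identical(sample_random_parameters(seed = 7, n = 0), list())
  draws <- sample_random_parameters(seed = 9, n = 40,
                                    ranges = list(T = c(0, 1), b = c(2, 3)))
  for (p in draws) {
    expect_s3_class(validate_parameters(p), "model_parameters")
    expect_true(p$T <= 1 && p$b >= 2 && p$b <= 3)
  }
  expect_error(sample_random_parameters(1, 2, ranges = list(zz = c(0, 1))),
               "unknown")
  expect_error(sample_random_parameters(1, 2, ranges = list(b = c(-1, 1))),
               "b > 0")
})
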