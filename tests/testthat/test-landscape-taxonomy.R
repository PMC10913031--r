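test_that("critical context follows the closed form and its symmetries", {
  expect_equal(critical_context(model_parameters(h_int = 0, T = 1, T0 = 5)), 5)
  expect_equal(critical_context(
    model_parameters(h_int = 3, a0 = 1, b = 1, T = 1, T0 = 5)), 7)
  expect_equal(critical_context(
    model_parameters(h_int = -3, a0 = 1, b = 1, T = 1, T0 = 5)), 7)
  expect_error(critical_context(model_parameters(h_ext = 0.1)),
               "degeneracy_context_numeric")
})

test_that("numeric degeneracy search agrees with the closed form and the 2-D scan oracle", {
  p <- model_parameters(h_int = 3, a0 = 1, b = 1, T = 6, T0 = 5)
  expect_equal(degeneracy_context_numeric(p), 7, tolerance = 1e-6)
  p0 <- model_parameters(h_int = 0, a0 = 1, b = 1, T = 4, T0 = 5)
  expect_equal(degeneracy_context_numeric(p0), 5, tolerance = 1e-6)
  # frozen oracle: brute-force 2-D (T, phi) scan located the tilted
  # degeneracy at T = 6.95 for h_ext = 0.05
  pt <- model_parameters(h_ext = 0.05, h_int = 3, a0 = 1, b = 1,
                         T = 6, T0 = 5)
  Tdeg <- degeneracy_context_numeric(pt)
  expect_equal(Tdeg, 6.95, tolerance = 1e-6)
  expect_lt(Tdeg, 7)
  # family that is monostable for every admissible T has nothing to find
  expect_error(degeneracy_context_numeric(
    model_parameters(h_int = 0, T = 8, T0 = 0, b = 5)),
    class = "sensescape_not_found")
})

test_that("closed-form and numeric critical contexts agree over random untilted draws", {
  draws <- sample_random_parameters(seed = 303, n = 100,
                                    ranges = list(h_ext = c(0, 0),
                                                  h_int = c(-4, 4)))
  for (p in draws) {
    expect_equal(degeneracy_context_numeric(p), critical_context(p),
                 tolerance = 1e-6)
  }
})

test_that("worked landscapes get the documented structure and regime", {
  # balanced double well: zero perception and sense-making biases
  baby <- analyze_landscape(model_parameters(T = 4, T0 = 5))
  expect_equal(baby$regime, "BABY")
  expect_equal(sort(baby$wells$phi), c(-1, 1), tolerance = 1e-9)
  expect_equal(baby$delta_phi, 0, tolerance = 1e-12)
  expect_equal(baby$delta_F, 0, tolerance = 1e-12)

  # single neutral minimum
  zen <- analyze_landscape(model_parameters(T = 6, T0 = 5))
  expect_equal(zen$regime, "ZEN")
  expect_equal(nrow(zen$wells), 1)
  expect_equal(zen$wells$phi, 0)

  # global alert-protection minimum with marginal neutral well
  cat <- analyze_landscape(model_parameters(h_int = 1, T = 5.1, T0 = 5))
  expect_equal(cat$regime, "CATASTROPHIZING")
  expect_equal(cat$alert_protection$phi, (-1 - sqrt(0.6)) / 2,
               tolerance = 1e-9)
  expect_equal(cat$alert_protection$F_value, -0.038531, tolerance = 1e-4)
  expect_equal(grid_minima(cat$params)$F[1], cat$alert_protection$F_value,
               tolerance = 1e-6)
  expect_equal(cat$neutral$F_value, 0)
  expect_equal(cat$curiosity_value, 0)     # neutral stands in: no curiosity
  expect_null(cat$trust_explore)
  expect_true(is.na(cat$delta_phi) && is.na(cat$delta_F))

  # degenerate first-order point: uncertainty with survival bias
  up <- analyze_landscape(model_parameters(h_int = 3, T = 7, T0 = 5))
  expect_equal(up$regime, "UNCERTAINTY_PESSIMISTIC")
  expect_equal(sort(up$wells$phi), c(-2, 0), tolerance = 1e-7)
  expect_lt(max(abs(up$wells$F_value)), 1e-12)

  # mirrored history gives the communicative landscape
  com <- analyze_landscape(model_parameters(h_int = -1, T = 5.1, T0 = 5))
  expect_equal(com$regime, "COMMUNICATIVE")

  # below the innate critical context with alarming history: mixed state
  hyp <- analyze_landscape(model_parameters(h_int = 3, T = 4, T0 = 5))
  expect_equal(hyp$regime, "HYPERVIGILANCE_BIAS")
  expect_lt(hyp$delta_F, 0)
  expect_lt(hyp$delta_phi, 0)
  cur <- analyze_landscape(model_parameters(h_int = -3, T = 4, T0 = 5))
  expect_equal(cur$regime, "CURIOSITY_BIAS")

  # exact second-order critical point
  unc <- analyze_landscape(model_parameters(T = 5, T0 = 5))
  expect_equal(unc$regime, "UNCERTAINTY")
})

test_that("regime classification is mirror-symmetric under (h, phi) negation", {
  mirror_of <- c(ZEN = "ZEN", UNCERTAINTY = "UNCERTAINTY", BABY = "BABY",
                 UNCERTAINTY_PESSIMISTIC = "UNCERTAINTY_OPTIMISTIC",
                 UNCERTAINTY_OPTIMISTIC = "UNCERTAINTY_PESSIMISTIC",
                 CATASTROPHIZING = "COMMUNICATIVE",
                 COMMUNICATIVE = "CATASTROPHIZING",
                 HYPERVIGILANCE_BIAS = "CURIOSITY_BIAS",
                 CURIOSITY_BIAS = "HYPERVIGILANCE_BIAS")
  draws <- sample_random_parameters(seed = 404, n = 100)
  for (p in draws) {
    r <- analyze_landscape(p)$regime
    rm <- analyze_landscape(mirror_params(p))$regime
    expect_equal(rm, unname(mirror_of[r]))
  }
})

test_that("T* is nondecreasing in |h_int| and equals T0 iff h_int = 0", {
  hs <- seq(0, 4, by = 0.25)
  Ts <- vapply(hs, function(h) critical_context(
    model_parameters(h_int = h, a0 = 0.7, b = 2, T = 1, T0 = 3)), numeric(1))
  expect_true(all(diff(Ts) >= 0))
  expect_equal(Ts[1], 3)
  expect_true(all(Ts[-1] > 3))
})

test_that("untilted regime labels agree with the T vs T0, T* bands", {
  a0 <- 1; b <- 1; T0 <- 5; h <- 2
  Tstar <- critical_context(model_parameters(h_int = h, a0 = a0, b = b,
                                             T = 1, T0 = T0))
  lab <- function(T) analyze_landscape(
    model_parameters(h_int = h, a0 = a0, b = b, T = T, T0 = T0))$regime
  expect_equal(lab(Tstar + 0.4), "ZEN")
  expect_equal(lab(Tstar), "UNCERTAINTY_PESSIMISTIC")
  expect_equal(lab((T0 + Tstar) / 2), "CATASTROPHIZING")
  expect_equal(lab(T0 - 1), "HYPERVIGILANCE_BIAS")
})

test_that("alert state deepens monotonically as context falls below T* (Phoenix ordering)", {
  h <- 2.5
  Ts <- seq(6, 3, by = -0.25)   # T* = 5 + 2*2.5^2/9 ~ 6.39
  depth <- vapply(Ts, function(T) {
    an <- analyze_landscape(model_parameters(h_int = h, T = T, T0 = 5))
    abs(an$alert_protection$phi)
  }, numeric(1))
  expect_true(all(diff(depth) > 0))
  # hence catastrophizing sits closer to neutral than hypervigilance bias
  cat <- analyze_landscape(model_parameters(h_int = h, T = 5.5, T0 = 5))
  hyp <- analyze_landscape(model_parameters(h_int = h, T = 4, T0 = 5))
  expect_lt(abs(cat$alert_protection$phi), abs(hyp$alert_protection$phi))
})

test_that("default-mode states follow the saturated closed forms", {
  expect_equal(default_mode_states(model_parameters(a0 = 1, b = 1, T = 3, T0 = 1)),
               c(alert_protection = -1, trust_explore = 1), tolerance = 1e-9)
  expect_equal(default_mode_states(model_parameters(a0 = 4, b = 1, T = 3, T0 = 1)),
               c(alert_protection = -2, trust_explore = 2), tolerance = 1e-9)
  dm <- default_mode_states(model_parameters(h_int = 3, a0 = 1, b = 1,
                                             T = 3, T0 = 1))
  expect_gt(abs(dm[["alert_protection"]]), abs(dm[["trust_explore"]]))
  gm <- grid_minima(model_parameters(h_int = 3, a0 = 1, b = 1, T = 0, T0 = 1))
  expect_equal(unname(dm), c(min(gm$phi), max(gm$phi)), tolerance = 1e-4)
  expect_message(
    out <- default_mode_states(model_parameters(T = 1, T0 = 0)),
    "no default-mode states")
  expect_true(all(is.na(out)))
})
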