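# A small, fast calibration scenario: short sweep, tension anchors read off
# a known "true" model, optimizer started from perturbed stiffnesses.
recovery_scenario <- function(seed, bands = c("TNL", "TSL"),
                              perturb = 1.2, n_steps = 6L) {
  m_true <- generate_anatomy(anatomy_params(jitter_scale = 0.0008,
                                            seed = seed))
  m_true$ligaments$prestrain[] <- 0.04   # keep every band engaged
  proto <- protocol_config(er_end = n_steps, n_steps = n_steps)
  tr <- run_per_protocol(m_true, proto)
  steps <- c(2L, 4L, n_steps)
  tg <- calibration_targets(
    quantity = "tension",
    ligament = rep(bands, each = length(steps)),
    step = rep(steps, length(bands)),
    value = unlist(lapply(bands, function(b) tr[[b]][steps + 1])))
  m_start <- m_true
  for (b in bands) {
    i <- which(m_start$ligaments$name == b)
    m_start$ligaments$stiffness[i] <- m_start$ligaments$stiffness[i] * perturb
  }
  list(truth = m_true, start = m_start, targets = tg, protocol = proto)
}

test_that("calibration recovers known stiffnesses from simulated anchors", {
  sc <- recovery_scenario(seed = 42)
  pars <- calibration_parameters(c("TNL", "TSL"), stiffness = TRUE,
                                 prestrain = FALSE)
  fit <- calibrate(sc$start, sc$targets, pars, protocol = sc$protocol,
                   maxiter = 25)
  for (b in c("TNL", "TSL")) {
    k_fit <- fit$model$ligaments$stiffness[fit$model$ligaments$name == b]
    k_true <- sc$truth$ligaments$stiffness[sc$truth$ligaments$name == b]
    expect_lt(abs(k_fit / k_true - 1), 0.02)
  }
  expect_lt(max(abs(fit$residuals$residual)), 0.5)
})

test_that("calibration started at the optimum stays there", {
  sc <- recovery_scenario(seed = 7, perturb = 1)   # start == truth
  pars <- calibration_parameters(c("TNL", "TSL"), stiffness = TRUE,
                                 prestrain = FALSE)
  fit <- calibrate(sc$start, sc$targets, pars, protocol = sc$protocol,
                   maxiter = 10)
  expect_lt(fit$objective, 1e-10)
  expect_equal(fit$parameters$fitted, fit$parameters$start, tolerance = 1e-4)
})

test_that("target evaluation computes every quantity from the trace", {
  m <- generate_anatomy()
  tr <- run_per_protocol(m, protocol_config(er_end = 8, n_steps = 8L))
  tg <- calibration_targets(
    quantity = c("tension", "tension_sum", "tension_delta", "pronation",
                 "dorsiflexion", "rise_onset"),
    ligament = c("TNL", "IOL", "TNL", NA, NA, "TNL"),
    step = c(4L, 4L, 8L, 4L, 0L, NA),
    step2 = c(NA, NA, 2L, NA, NA, NA),
    value = 0)
  ev <- evaluate_targets(tr, tg)
  expect_equal(ev$achieved[1], tr$TNL[5])
  expect_equal(ev$achieved[2], sum(tr[5, c("IOL_1", "IOL_2", "IOL_3")]))
  expect_equal(ev$achieved[3], tr$TNL[9] - tr$TNL[3])
  expect_equal(ev$achieved[4], tr$pronation_deg[5])
  expect_equal(ev$achieved[5], tr$df_deg[1])
})

test_that("calibration artifacts expose tidy and glance views", {
  sc <- recovery_scenario(seed = 3, bands = "TNL", n_steps = 4L)
  pars <- calibration_parameters("TNL", stiffness = TRUE, prestrain = FALSE)
  fit <- calibrate(sc$start, sc$targets, pars, protocol = sc$protocol,
                   maxiter = 5)
  td <- tidy(fit)
  expect_true(all(c("quantity", "ligament", "value", "achieved",
                    "residual") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(is.finite(gl$objective))
})

test_that("degenerate calibration inputs error cleanly", {
  m <- generate_anatomy()
  tg <- calibration_targets(quantity = "rise_onset", ligament = "TNL",
                            value = 5)
  pars <- calibration_parameters("TNL")
  expect_error(calibrate(m, tg, pars), "smooth")
  expect_error(calibration_targets(quantity = "nope", value = 1), "quantity")
})
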