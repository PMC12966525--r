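test_that("a state already at equilibrium is returned unchanged", {
  # slack band, no joints, no regularization: zero coords are stationary
  lig <- toy_ligament(slack_length = 0.12)   # longer than the chord
  m <- toy_model(lig)
  cfg <- solver_config(rotation_regularization = 0,
                       driver_rotation_guidance = 0,
                       translation_regularization = 0)
  sol <- solve_step(m, 0, cfg = cfg)
  expect_true(sol$converged)
  expect_identical(sol$iterations, 0L)
  expect_identical(unname(sol$coords), numeric(length(coord_names(m))))
  expect_identical(sol$residual_norm, 0)
})

test_that("1-DOF hinge equilibrium matches a brute-force energy scan", {
  lig <- dplyr::bind_rows(
    toy_ligament("a", origin_point = c(0.05, 0.02, 0),
                 insertion_point = c(0.07, -0.05, 0),
                 slack_length = 0.07, stiffness = 900, prestrain = 0.05),
    toy_ligament("b", origin_point = c(-0.04, 0.03, 0.01),
                 insertion_point = c(-0.06, -0.04, 0.01),
                 slack_length = 0.072, stiffness = 700, prestrain = 0.04))
  m <- toy_model(lig)
  cfg <- freeze_except(m, "tibia_df")
  for (er in c(0, 8)) {
    sol <- solve_step(m, er, cfg = cfg)
    expect_true(sol$converged)
    oracle <- grid_search_df(m, er, cfg)
    expect_lt(abs(sol$coords[["tibia_df"]] - oracle) * 180 / pi, 1e-4)
  }
})

test_that("converged solutions are local minima under perturbation", {
  m <- generate_anatomy()
  cfg <- solver_config()
  sol <- solve_step(m, 10, cfg = cfg)
  expect_true(sol$converged)
  e0 <- sol$energy
  for (j in seq_along(sol$coords)) {
    for (s in c(-1, 1)) {
      q <- sol$coords
      q[j] <- q[j] + s * 1e-3
      e <- total_energy(m, build_state(m, q, 10), cfg)
      expect_gt(e, e0)
    }
  }
})

test_that("continuation matches per-step solves and handles edge schedules", {
  # degenerate one-entry schedule equals a single solve
  m <- generate_anatomy()
  run <- continuation_run(m, 0)
  one <- solve_step(m, 0)
  expect_length(run, 1L)
  expect_equal(run[[1]]$coords, one$coords, tolerance = 1e-12)

  # force-free model: all residuals zero, coordinates never move
  m0 <- toy_model(toy_ligament(stiffness = 0))
  runs <- continuation_run(m0, 0:10)
  expect_true(all(vapply(runs, function(s) s$residual_norm, 1) == 0))
  expect_true(all(vapply(runs, function(s) all(s$coords == 0), NA)))
})

test_that("warm-started continuation agrees with cold starts on the toy", {
  lig <- toy_ligament("a", origin_point = c(0.05, 0.02, 0),
                      insertion_point = c(0.07, -0.05, 0),
                      slack_length = 0.07, stiffness = 900, prestrain = 0.05)
  m <- toy_model(lig)
  cfg <- freeze_except(m, "tibia_df")
  sched <- seq(0, 10, by = 1)
  warm <- continuation_run(m, sched, cfg)
  for (i in seq_along(sched)) {
    cold <- solve_step(m, sched[i], cfg = cfg)
    expect_lt(abs(warm[[i]]$coords[["tibia_df"]] -
                    cold$coords[["tibia_df"]]), 1e-6)
  }
})

test_that("identical runs are deterministic", {
  m <- generate_anatomy()
  s1 <- solve_step(m, 17)
  s2 <- solve_step(m, 17)
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$residual_norm, s2$residual_norm)
})

test_that("non-convergence is flagged, never silent", {
  m <- generate_anatomy()
  cfg <- solver_config(max_iterations = 1L, gradient_tolerance = 1e-12)
  sol <- solve_step(m, 30, cfg = cfg)
  expect_false(sol$converged)
  expect_gt(sol$residual_norm, 1e-12)
})
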