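short_protocol <- function(n = 5L, ...) {
  protocol_config(er_end = n, n_steps = n, solver = solver_config(...))
}

test_that("trace has the configured shape and invariants", {
  m <- generate_anatomy()
  cfg <- short_protocol(6L)
  tr <- run_per_protocol(m, cfg)
  expect_s3_class(tr, "tension_trace")
  expect_identical(nrow(tr), 7L)
  expect_identical(tr$step, 0:6)
  expect_true(all(diff(tr$er_deg) > 0))
  expect_true(all(names(m$ligaments$name) %in% character(0)) ||
                all(m$ligaments$name %in% names(tr)))
  ten <- as.matrix(tr[, m$ligaments$name])
  expect_true(all(ten >= 0))
  expect_true(all(tr$converged))
  # re-running with the same config reproduces the trace exactly
  expect_identical(as.data.frame(run_per_protocol(m, cfg)),
                   as.data.frame(tr))
})

test_that("a force-free model produces an all-zero tension trace", {
  m <- generate_anatomy()
  m$ligaments$stiffness[] <- 0
  m$joints$capsule_stiffness <- replicate(3, c(0, 0, 0), simplify = FALSE)
  tr <- run_per_protocol(m, short_protocol(5L))
  expect_true(all(as.matrix(tr[, m$ligaments$name]) == 0))
})

test_that("trace equals independent per-step solve plus ligament evaluation", {
  lig <- dplyr::bind_rows(
    toy_ligament("a", origin_point = c(0.05, 0.02, 0),
                 insertion_point = c(0.07, -0.05, 0),
                 slack_length = 0.07, stiffness = 900, prestrain = 0.05),
    toy_ligament("b", origin_point = c(-0.04, 0.03, 0.01),
                 insertion_point = c(-0.06, -0.04, 0.01),
                 slack_length = 0.072, stiffness = 700, prestrain = 0.04))
  m <- toy_model(lig)
  scfg <- solver_config()
  tr <- run_per_protocol(m, protocol_config(er_end = 5, n_steps = 5L,
                                            solver = scfg))
  q <- zero_coords(m)
  for (i in 0:5) {
    sol <- solve_step(m, i, initial_coords = q, cfg = scfg)
    q <- sol$coords
    st <- build_state(m, q, i)
    ls <- ligament_states(m, st)
    expect_equal(unname(unlist(tr[i + 1, c("a", "b")])), ls$tension,
                 tolerance = 1e-8)
  }
})

test_that("plateau detection follows its definition", {
  expect_equal(detect_plateau(rep(50, 21)),
               list(onset_step = 0, plateau_value = 50))
  # saturating curve: compare against a direct scan of the definition
  v <- 100 * (1 - exp(-(0:50) / 5))
  got <- detect_plateau(v, slope_threshold = 1, sustain = 5)
  oracle_onset <- NA_integer_
  d <- diff(v)
  for (s in 0:(50 - 5)) {
    if (all(d[(s + 1):(s + 5)] < 1)) { oracle_onset <- s; break }
  }
  expect_identical(got$onset_step, oracle_onset)
  expect_equal(got$plateau_value, mean(v[(oracle_onset + 1):51]))
  # a steadily climbing curve has no plateau
  expect_true(is.na(detect_plateau(seq(0, 100, length.out = 51))$onset_step))
})

test_that("rise-onset detection follows its definition", {
  expect_true(is.na(detect_rise_onset(rep(0, 40))))
  s <- c(rep(0, 28), seq(2, 50, length.out = 12))   # zero through step 27
  expect_identical(detect_rise_onset(s), 28L)
  expect_identical(detect_rise_onset(c(5, rep(0, 20))), 0L)
  expect_identical(detect_rise_onset(c(0.5, 0.9, 3, 8)), 2L)
})

test_that("curve_stats summarises every ligament plus the summed IOL", {
  m <- generate_anatomy()
  tr <- run_per_protocol(m, short_protocol(6L))
  cs <- curve_stats(tr)
  expect_setequal(cs$ligament, c(m$ligaments$name, "IOL"))
  iol <- cs[cs$ligament == "IOL", ]
  expect_equal(iol$initial_tension,
               sum(tr[1, c("IOL_1", "IOL_2", "IOL_3")]))
})

test_that("joint reactions vanish in an unloaded state and balance a taut band", {
  m <- generate_anatomy()
  m$ligaments$stiffness[] <- 0
  st <- build_state(m, zero_coords(m), 0)
  jr <- joint_reaction_forces(m, st)
  expect_identical(nrow(jr), 3L)
  expect_true(all(jr$magnitude == 0))

  # single taut band from tibia to ground, tibia anchored by the talocrural
  # penalty: at equilibrium the joint reaction balances the band pull
  m1 <- generate_anatomy()
  m1$ligaments$stiffness[] <- 0
  i <- which(m1$ligaments$name == "TCL")
  m1$ligaments$stiffness[i] <- 2000
  m1$ligaments$prestrain[i] <- 0.08
  cfg <- solver_config(rotation_regularization = 5)
  sol <- solve_step(m1, 0, cfg = cfg)
  expect_true(sol$converged)
  st <- build_state(m1, sol$coords, 0)
  ls <- ligament_states(m1, st)
  f_band <- -ls$tension[i] * ls$direction[[i]]   # force on the tibia origin
  jr <- joint_reaction_forces(m1, st)
  f_tc <- -unlist(jr[jr$joint == "talocrural", c("fx", "fy", "fz")])
  # translation equilibrium of the tibia: band + joint + regularization = 0
  f_reg <- -cfg$translation_regularization *
    sol$coords[c("tibia_tx", "tibia_ty", "tibia_tz")]
  expect_lt(max(abs(f_band + f_tc + f_reg)), 1e-3)
})

test_that("global force and moment balance holds at equilibrium", {
  # capsule-free configuration so every internal action is a point force
  m <- generate_anatomy()
  m$joints$capsule_stiffness <- replicate(3, c(0, 0, 0), simplify = FALSE)
  cfg <- solver_config()
  sol <- solve_step(m, 12, cfg = cfg)
  expect_true(sol$converged)
  bal <- force_balance(m, sol$coords, 12, cfg)
  expect_lt(bal$force_norm, 1e-3)
  expect_lt(bal$moment_norm, 1e-4)
})

test_that("trace CSV writing is deterministic and round-trips", {
  m <- generate_anatomy()
  tr <- run_per_protocol(m, short_protocol(5L))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f1)
  write_trace_csv(tr, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_trace_csv(f1)
  expect_identical(nrow(back), nrow(tr))
  expect_equal(back$TNL, tr$TNL, tolerance = 1e-7)
  expect_identical(attr(back, "ligaments"), m$ligaments$name)
})
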