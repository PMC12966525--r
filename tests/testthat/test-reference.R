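# Properties of the packaged calibrated reference model. The full PER trace
# is computed once and shared across the blocks.

ref_trace_cache <- new.env()
ref_trace <- function() {
  if (is.null(ref_trace_cache$tr)) {
    ref_trace_cache$m <- reference_model()
    ref_trace_cache$tr <- run_per_protocol(ref_trace_cache$m,
                                           protocol_config())
  }
  ref_trace_cache
}

test_that("the packaged reference model is valid and fully documented", {
  m <- reference_model()
  expect_identical(nrow(validate_model(m)), 0L)
  expect_identical(nrow(m$ligaments), 14L)
  expect_true(!is.null(m$metadata$calibration))
})

test_that("simulating the reference model reproduces the packaged trace", {
  rc <- ref_trace()
  packaged <- read_trace_csv(system.file("extdata", "reference-trace.csv",
                                         package = "perankle",
                                         mustWork = TRUE))
  expect_identical(nrow(packaged), nrow(rc$tr))
  for (col in setdiff(names(packaged), "converged")) {
    expect_equal(packaged[[col]], rc$tr[[col]], tolerance = 1e-8,
                 label = paste("column", col))
  }
})

test_that("every step of the reference run converges to tolerance", {
  rc <- ref_trace()
  expect_true(all(rc$tr$converged))
  expect_true(all(rc$tr$residual <=
                    protocol_config()$solver$gradient_tolerance))
})

test_that("the reference step-0 state sits near the configured posture", {
  # the settled pre-tensioned web is allowed a few degrees of flexion
  # settle relative to the nominal 20-degree posture; pronation starts
  # near zero and external rotation exactly at zero
  rc <- ref_trace()
  expect_lt(abs(rc$tr$df_deg[1] - 20), 4)
  expect_lt(abs(rc$tr$pronation_deg[1]), 2)
  expect_equal(rc$tr$er_deg[1], 0)
})

test_that("anterior structures load monotonically on the reference model", {
  rc <- ref_trace()
  for (lig in c("TNL", "dATTL", "AITFL")) {
    expect_true(all(diff(rc$tr[[lig]]) >= -1e-6),
                label = paste(lig, "nondecreasing"))
  }
})

test_that("posterior structures stay slack through early rotation", {
  rc <- ref_trace()
  for (lig in c("dPTTL", "PITFL")) {
    expect_true(all(rc$tr[[lig]][2:21] <= rc$tr[[lig]][1] + 1e-6),
                label = paste(lig, "early slack"))
  }
})

test_that("reference tension curves are smooth across steps", {
  rc <- ref_trace()
  for (lig in attr(rc$tr, "ligaments")) {
    expect_lt(max(abs(diff(rc$tr[[lig]]))), 60)
  }
})

test_that("the stored calibration residuals match a fresh evaluation", {
  rc <- ref_trace()
  stored <- rc$m$metadata$calibration$anchors
  ev <- evaluate_targets(rc$tr, reference_targets())
  for (i in seq_len(nrow(ev))) {
    key <- paste(ev$quantity[i], ev$ligament[i], ev$step[i], sep = "/")
    expect_equal(ev$achieved[i], stored$achieved[[i]], tolerance = 1e-6,
                 label = key)
  }
})
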