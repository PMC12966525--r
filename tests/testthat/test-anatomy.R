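test_that("generation is deterministic for a fixed seed", {
  p <- anatomy_params(jitter_scale = 0.002, seed = 1L)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_ankle_model(generate_anatomy(p), f1)
  write_ankle_model(generate_anatomy(p), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed moves the attachments
  m1 <- generate_anatomy(p)
  m2 <- generate_anatomy(anatomy_params(jitter_scale = 0.002, seed = 2L))
  expect_false(identical(m1$ligaments$origin_point,
                         m2$ligaments$origin_point))
})

test_that("generated geometry honours the anterior/posterior contract", {
  for (seed in 1:10) {
    m <- generate_anatomy(anatomy_params(jitter_scale = 0.001, seed = seed))
    lig <- m$ligaments
    pt <- function(name, col) lig[[col]][[which(lig$name == name)]]
    for (l in c("dPTTL", "PITFL")) {
      expect_lt(pt(l, "origin_point")[1], 0)
      expect_lt(pt(l, "insertion_point")[1], 0)
    }
    for (l in c("TNL", "dATTL", "AITFL")) {
      expect_gt(pt(l, "origin_point")[1], 0)
      expect_gt(pt(l, "insertion_point")[1], 0)
    }
  }
})

test_that("degenerate or misplaced geometry is rejected", {
  att <- perankle:::nominal_attachments(anatomy_params())
  ok <- perankle:::check_attachment_geometry(att)
  expect_length(ok, nrow(att))

  bad <- att
  bad$insertion_point[[1]] <- bad$origin_point[[1]] + 1e-4
  expect_error(perankle:::check_attachment_geometry(bad), "degenerate")

  flipped <- att
  i <- which(flipped$name == "dPTTL")
  p <- flipped$origin_point[[i]]; p[1] <- abs(p[1])
  flipped$origin_point[[i]] <- p
  expect_error(perankle:::check_attachment_geometry(flipped),
               "posterior placement")
})

test_that("attachment-distance curves follow pure rigid rotation", {
  m <- generate_anatomy()
  ers <- seq(0, 30, by = 5)
  # identity at zero rotation
  i <- which(m$ligaments$name == "TNL")
  d0 <- sqrt(sum((m$ligaments$origin_point[[i]] -
                    m$ligaments$insertion_point[[i]])^2))
  expect_equal(insertion_distance_curve(m, "TNL", 0), d0)
  # independent endpoint-rotation oracle
  for (lig in c("TNL", "dPTTL", "TCL")) {
    i <- which(m$ligaments$name == lig)
    oracle <- vapply(ers, function(er) {
      R <- perankle:::rot_y(er * pi / 180)
      wo <- as.numeric(R %*% m$ligaments$origin_point[[i]])
      sqrt(sum((wo - m$ligaments$insertion_point[[i]])^2))
    }, numeric(1))
    expect_equal(insertion_distance_curve(m, lig, ers), oracle,
                 tolerance = 1e-12)
  }
  expect_error(insertion_distance_curve(m, "nonesuch", 0), "unknown ligament")
})

test_that("a band collinear with the rotation axis keeps constant length", {
  lig <- toy_ligament(origin_point = c(0, 0.05, 0),
                      insertion_point = c(0, -0.03, 0))
  m <- toy_model(lig)
  d <- insertion_distance_curve(m, "band", seq(0, 50, by = 10))
  expect_true(all(abs(d - d[1]) < 1e-15))
})

test_that("posterior structures slacken and anterior structures tighten early", {
  m <- reference_model()
  ers <- 0:15
  for (lig in c("dPTTL", "PITFL")) {
    d <- insertion_distance_curve(m, lig, ers)
    expect_true(all(diff(d) < 0), label = paste(lig, "decreasing"))
  }
  for (lig in c("TNL", "dATTL", "AITFL")) {
    d <- insertion_distance_curve(m, lig, ers)
    expect_true(all(diff(d) > 0), label = paste(lig, "increasing"))
  }
})
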