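test_that("tension-only force law matches its closed forms", {
  # slack ligaments carry no load
  expect_identical(ligament_tension(-0.05, k = 1000, eps_t = 0.03), 0)
  # both branches meet at eps = 2 eps_t with F = k eps_t
  expect_equal(ligament_tension(0.06, k = 1000, eps_t = 0.03), 30)
  # linear branch k (eps - eps_t)
  expect_equal(ligament_tension(0.10, k = 1000, eps_t = 0.03), 70)
})

test_that("force law is nonnegative, monotone and C1 at the junctions", {
  eps <- seq(-0.5, 0.5, by = 1e-3)
  f <- ligament_tension(eps, k = 1500, eps_t = 0.04)
  expect_true(all(f >= 0))
  expect_true(all(f[eps <= 0] == 0))
  expect_true(all(diff(f) >= 0))
  h <- 1e-7
  for (e0 in c(0, 0.08)) {   # junctions for eps_t = 0.04
    jump <- abs(ligament_tension(e0 + h, 1500, 0.04) -
                  ligament_tension(e0 - h, 1500, 0.04))
    expect_lt(jump, 1e-3)
    slope_r <- (ligament_tension(e0 + 2 * h, 1500, 0.04) -
                  ligament_tension(e0 + h, 1500, 0.04)) / h
    slope_l <- (ligament_tension(e0 - h, 1500, 0.04) -
                  ligament_tension(e0 - 2 * h, 1500, 0.04)) / h
    expect_lt(abs(slope_r - slope_l), 1e-2 * 1500)
  }
})

test_that("strain energy integrates the force law (quadrature oracle)", {
  k <- 1200; et <- 0.03; L0 <- 0.04
  for (eps in c(0.02, 0.10)) {      # one toe-branch, one linear-branch value
    oracle <- stats::integrate(function(e) {
      ligament_tension(e, k, et) * L0
    }, lower = 0, upper = eps, rel.tol = 1e-10)$value
    expect_equal(strain_energy(eps, k, et, L0), oracle, tolerance = 1e-8)
  }
  expect_identical(strain_energy(-0.1, k, et, L0), 0)
})

test_that("ligament lengths follow the transformed endpoints", {
  lig <- toy_ligament(origin_point = c(0, 0.04, 0),
                      insertion_point = c(0, 0, 0), slack_length = 0.04)
  m <- toy_model(lig)
  st <- build_state(m, zero_coords(m), 0)
  expect_equal(ligament_length(st, m$ligaments[1, ]), 0.04)

  # translate the origin segment 1 cm along the band line
  q <- zero_coords(m)
  q[["tibia_ty"]] <- 0.01
  st <- build_state(m, q, 0)
  expect_equal(ligament_length(st, m$ligaments[1, ]), 0.05)

  # arbitrary pose: equals an independent endpoint-transform computation
  set.seed(3)
  for (i in 1:10) {
    q <- random_coords(m, sd_rot = 0.2, sd_trans = 0.01)
    st <- build_state(m, q, 25)
    wo <- transform_point(st$poses$tibia, lig$origin_point[[1]])
    wi <- lig$insertion_point[[1]]
    expect_equal(ligament_length(st, m$ligaments[1, ]),
                 sqrt(sum((wo - wi)^2)), tolerance = 1e-12)
  }
})

test_that("total energy equals the independent term-by-term sum", {
  m <- generate_anatomy()
  cfg <- solver_config()
  set.seed(21)
  for (i in 1:5) {
    q <- random_coords(m)
    st <- build_state(m, q, 12)
    ls <- ligament_states(m, st)
    e_lig <- sum(strain_energy(ls$strain, m$ligaments$stiffness,
                               m$ligaments$toe_strain,
                               m$ligaments$slack_length))
    e_jnt <- 0; e_cap <- 0
    for (j in seq_len(nrow(m$joints))) {
      wp <- transform_point(st$poses[[m$joints$parent[j]]],
                            m$joints$parent_point[[j]])
      wc <- transform_point(st$poses[[m$joints$child[j]]],
                            m$joints$child_point[[j]])
      e_jnt <- e_jnt + 0.5 * m$joints$penalty_stiffness[j] *
        sum((wp - wc)^2)
      ang <- function(seg, slot) {
        if (seg == "hindfoot") return(0)
        if (seg == "tibia" && slot == 3) return(12 * pi / 180)
        q[[paste0(seg, c("_df", "_ev", "_er")[slot])]]
      }
      Fr <- m$joints$capsule_frame[[j]]
      Cm <- Fr %*% diag(m$joints$capsule_stiffness[[j]]) %*% t(Fr)
      d3 <- vapply(1:3, function(slot) {
        ang(m$joints$parent[j], slot) - ang(m$joints$child[j], slot)
      }, numeric(1))
      e_cap <- e_cap + 0.5 * sum(d3 * (Cm %*% d3))
    }
    e_reg <- sum(0.5 * cfg$translation_regularization *
                   q[grepl("^tibia_t", names(q))]^2) +
      sum(0.5 * cfg$driver_rotation_guidance *
            q[c("tibia_df", "tibia_ev")]^2) +
      sum(0.5 * cfg$rotation_regularization *
            q[grepl("^(talus|fibula)_(df|ev|er)$", names(q))]^2)
    expect_equal(total_energy(m, st, cfg), e_lig + e_jnt + e_cap + e_reg,
                 tolerance = 1e-9)
  }
})

test_that("analytic gradient matches central finite differences", {
  m <- generate_anatomy()
  cfg <- solver_config()
  set.seed(5)
  h <- 1e-7
  for (i in 1:10) {
    q <- random_coords(m)
    g <- energy_gradient(m, q, 15, cfg)
    fd <- vapply(seq_along(q), function(j) {
      qp <- q; qm <- q
      qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
      (total_energy(m, build_state(m, qp, 15), cfg) -
         total_energy(m, build_state(m, qm, 15), cfg)) / (2 * h)
    }, numeric(1))
    expect_lt(sqrt(sum((g - fd)^2)) / max(sqrt(sum(g^2)), 1e-10), 1e-5)
  }
})

test_that("energy gradient of the hinge toy matches the hand-derived form", {
  # one band from the rotating tibia to ground, only tibia_df free:
  # dE/d(df) = F(eps) * u . (dRz/d(df) p)
  lig <- toy_ligament(origin_point = c(0.05, 0.02, 0),
                      insertion_point = c(0.08, -0.04, 0),
                      slack_length = 0.06, stiffness = 800, prestrain = 0.02)
  m <- toy_model(lig)
  cfg <- solver_config(rotation_regularization = 0,
                       driver_rotation_guidance = 0,
                       translation_regularization = 0)
  for (df in c(-0.2, 0.1, 0.3)) {
    q <- zero_coords(m); q[["tibia_df"]] <- df
    p <- lig$origin_point[[1]]
    Rz <- perankle:::rot_z(df)
    dRz <- matrix(c(-sin(df), cos(df), 0, -cos(df), -sin(df), 0, 0, 0, 0),
                  3, 3)
    wo <- as.numeric(Rz %*% p)
    d <- wo - lig$insertion_point[[1]]
    L <- sqrt(sum(d^2))
    eps <- (L - lig$slack_length) / lig$slack_length + lig$prestrain
    Ften <- ligament_tension(eps, lig$stiffness, lig$toe_strain)
    expected <- Ften * sum((d / L) * as.numeric(dRz %*% p))
    g <- energy_gradient(m, q, 0, cfg)
    expect_equal(unname(g[["tibia_df"]]), expected, tolerance = 1e-10)
  }
})
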