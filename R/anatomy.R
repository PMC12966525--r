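#' Synthetic ankle anatomy parameters
#'
#' Controls the generated stand-in geometry for the four-segment passive
#' ankle model. All coordinates are metres in the world frame of the initial
#' protocol posture (right ankle, X anterior, Y superior along the tibial
#' long axis through the talocrural centre, Z lateral; origin at the
#' talocrural centre). Attachment sites are placed from cylindrical
#' landmarks (azimuth about the long axis measured from anterior toward
#' lateral, radius, height) so that anterior structures lengthen and
#' posterior structures slacken under early external rotation of the foot
#' (implemented as internal rotation of the leg over the fixed foot).
#'
#' @param mortise_width medial-to-lateral malleolar span, metres.
#' @param plafond_height vertical offset added to the tibial-side distal
#'   attachment heights, metres.
#' @param medial_malleolus_drop,lateral_malleolus_drop how far each
#'   malleolar tip reaches below the plafond, metres.
#' @param jitter_scale standard deviation (m) of seeded Gaussian jitter
#'   added to every attachment site; 0 gives the deterministic nominal
#'   geometry.
#' @param seed RNG seed for the jitter.
#' @return list of class `anatomy_params`.
#' @export
anatomy_params <- function(mortise_width = 0.072,
                           plafond_height = 0,
                           medial_malleolus_drop = 0.008,
                           lateral_malleolus_drop = 0.016,
                           jitter_scale = 0,
                           seed = 1L) {
  stopifnot(mortise_width > 0.02, mortise_width < 0.3,
            jitter_scale >= 0, jitter_scale < 0.01)
  structure(list(mortise_width = mortise_width,
                 plafond_height = plafond_height,
                 medial_malleolus_drop = medial_malleolus_drop,
                 lateral_malleolus_drop = lateral_malleolus_drop,
                 jitter_scale = jitter_scale,
                 seed = as.integer(seed)),
            class = "anatomy_params")
}

# placement contract (posterior bands behind the long axis, anterior bands
# in front) and degeneracy screen; returns the reference lengths
check_attachment_geometry <- function(att) {
  x_of <- function(lig, col) att[[col]][[which(att$name == lig)]][1]
  for (lig in intersect(c("dPTTL", "PITFL"), att$name)) {
    if (x_of(lig, "origin_point") >= 0 || x_of(lig, "insertion_point") >= 0) {
      stop("generated geometry violates posterior placement for ", lig,
           call. = FALSE)
    }
  }
  for (lig in intersect(c("TNL", "dATTL", "AITFL"), att$name)) {
    if (x_of(lig, "origin_point") <= 0 || x_of(lig, "insertion_point") <= 0) {
      stop("generated geometry violates anterior placement for ", lig,
           call. = FALSE)
    }
  }
  ref_len <- purrr::map2_dbl(att$origin_point, att$insertion_point,
                             function(a, b) sqrt(sum((a - b)^2)))
  if (any(ref_len < 0.004)) {
    stop("degenerate geometry: near-coincident attachments for ",
         paste(att$name[ref_len < 0.004], collapse = ", "), call. = FALSE)
  }
  ref_len
}

# cylindrical landmark -> cartesian local point
cyl_point <- function(az_deg, r, y) {
  a <- deg2rad(az_deg)
  c(r * cos(a), y, r * sin(a))
}

# Nominal attachment landmark table. Azimuth 0 = anterior, 90 = lateral,
# 180 = posterior, 270 = medial. Radii of the malleolar attachments scale
# with the mortise half-width.
nominal_attachments <- function(p) {
  hw <- p$mortise_width / 2          # 0.036 by default
  ph <- p$plafond_height
  mm <- -p$medial_malleolus_drop     # medial malleolus tip height
  lm <- -p$lateral_malleolus_drop    # lateral malleolus tip height
  A <- function(lig, oseg, oaz, or_, oy, iseg, iaz, ir, iy) {
    tibble::tibble(name = lig, origin_segment = oseg,
                   origin_point = list(cyl_point(oaz, or_, oy)),
                   insertion_segment = iseg,
                   insertion_point = list(cyl_point(iaz, ir, iy)))
  }
  dplyr::bind_rows(
    # deltoid complex: tibial side on the medial malleolus
    A("TNL",   "tibia", 288, hw * 1.03, mm + 0.002 + ph,
      "hindfoot", 341, 0.048, -0.018),
    A("TSL",   "tibia", 283, hw * 1.00, mm + ph,
      "hindfoot", 308, 0.037, -0.025),
    A("TCL",   "tibia", 276, hw * 0.97, mm - 0.002 + ph,
      "hindfoot", 282, 0.021, -0.038),
    A("dATTL", "tibia", 282, hw * 0.83, mm + 0.004 + ph,
      "talus",    330, 0.022, -0.006),
    A("dPTTL", "tibia", 258, 0.022, mm + 0.002 + ph,
      "talus",    243, 0.018, mm - 0.005 + ph),
    # distal tibiofibular syndesmosis
    A("AITFL", "tibia",  48, 0.030,  0.006 + ph, "fibula",  80, 0.037, -0.004),
    A("PITFL", "tibia", 132, 0.029,  0.006 + ph, "fibula", 100, 0.036, -0.004),
    # interosseous ligament/membrane: three fibers from just above the
    # syndesmosis toward the proximal third of the fibular shaft
    A("IOL_1", "tibia",  80, 0.026, 0.030, "fibula", 82, 0.034, 0.026),
    A("IOL_2", "tibia",  80, 0.026, 0.070, "fibula", 82, 0.034, 0.066),
    A("IOL_3", "tibia",  80, 0.026, 0.110, "fibula", 82, 0.034, 0.106),
    # lateral complex and posterior talocalcaneal
    A("ATFL",  "fibula", 60, hw * 1.00, lm + 0.002,
      "talus",  35, 0.026, -0.006),
    A("CFL",   "fibula", 95, hw * 0.97, lm - 0.002,
      "hindfoot", 110, 0.032, -0.048),
    A("PTFL",  "fibula", 115, hw * 0.92, lm + 0.004,
      "talus", 160, 0.023, -0.008),
    A("PTCL",  "talus", 185, 0.024, -0.012, "hindfoot", 182, 0.032, -0.038))
}

# default material parameters (starting point for calibration):
# stiffness k in N at unit strain, prestrain dimensionless
nominal_materials <- function() {
  tibble::tribble(
    ~name,    ~stiffness, ~prestrain,
    "TNL",     450,  0.00,
    "TSL",     400,  0.00,
    "TCL",    2400,  0.00,
    "dATTL",   330,  0.00,
    "dPTTL", 10000, -0.005,
    "AITFL",   700,  0.00,
    "PITFL",  1200,  0.00,
    "IOL_1",    25,  0.00,
    "IOL_2",    25,  0.00,
    "IOL_3",    25,  0.00,
    "ATFL",   1200,  0.00,
    "CFL",    1500,  0.00,
    "PTFL",   1500,  0.00,
    "PTCL",   2000,  0.00)
}

#' Generate a synthetic passive ankle model
#'
#' Builds a validated [ankle_model()] with four segments (fixed hindfoot,
#' driven tibia, free talus and fibula), three penalty joints (talocrural,
#' subtalar, proximal tibiofibular) and all fourteen ligament elements
#' (eleven named bands plus three interosseous fibers). Slack lengths are
#' set to the reference-posture lengths, so the prestrain field alone
#' controls initial tension. Identical parameters (including seed) give an
#' identical model; jittered variants that violate the anterior/posterior
#' placement contract or produce degenerate (near-coincident) attachments
#' are rejected.
#'
#' @param params an [anatomy_params()].
#' @param joint_penalty_stiffness penalty stiffness (N/m) for the anatomical
#'   joints.
#' @param capsule_stiffness rotational restraint (N m/rad) on each
#'   anatomical joint, standing in for the joint capsule and articular
#'   congruence that the discrete ligament set does not represent: a list of
#'   three 3-vectors (talocrural, subtalar, proximal tibiofibular), each
#'   giving stiffness about the dorsiflexion, eversion and axial-rotation
#'   axes. Congruence strongly resists tilt (df/ev) but leaves axial
#'   rotation ligament-dominated.
#' @param toe_strain toe-region parameter shared by all ligaments.
#' @return a validated `ankle_model`.
#' @export
generate_anatomy <- function(params = anatomy_params(),
                             joint_penalty_stiffness = 1e7,
                             capsule_stiffness = list(c(40, 140, 4),
                                                      c(120, 120, 500),
                                                      c(5, 5, 2)),
                             toe_strain = 0.03) {
  att <- nominal_attachments(params)
  if (params$jitter_scale > 0) {
    rng <- local({
      set.seed(params$seed)
      matrix(stats::rnorm(nrow(att) * 6, sd = params$jitter_scale),
             nrow(att), 6)
    })
    att$origin_point <- purrr::map2(att$origin_point,
                                    seq_len(nrow(att)),
                                    function(p, i) p + rng[i, 1:3])
    att$insertion_point <- purrr::map2(att$insertion_point,
                                       seq_len(nrow(att)),
                                       function(p, i) p + rng[i, 4:6])
  }

  ref_len <- check_attachment_geometry(att)

  mat <- nominal_materials()
  lig <- dplyr::left_join(att, mat, by = "name")
  lig$slack_length <- ref_len
  lig$toe_strain <- toe_strain
  lig <- lig[, c("name", "origin_segment", "insertion_segment",
                 "origin_point", "insertion_point", "slack_length",
                 "stiffness", "toe_strain", "prestrain")]

  segments <- tibble::tibble(
    name = c("hindfoot", "tibia", "talus", "fibula"),
    fixed = c(TRUE, FALSE, FALSE, FALSE))

  jp <- function(az, r, y) list(cyl_point(az, r, y))
  # Talocrural capsule frame in Euler-difference space (df, ev, er).
  # The loaded ankle couples external rotation to eversion: with the
  # hindfoot welded to ground the subtalar eversion excursion is
  # unavailable, so the equivalent oblique compliance is modelled at the
  # talocrural capsule. Its soft axis mixes eversion and external rotation
  # (inclination comparable to the anatomical subtalar axis); the two
  # perpendicular directions are the stiff flexion guide and the stiff
  # coupling direction that enforces the eversion/rotation ratio.
  soft_axis <- c(0, 0.45, 0.89)            # (df, ev, er) components
  soft_axis <- soft_axis / sqrt(sum(soft_axis^2))
  u2 <- c(0, -soft_axis[3], soft_axis[2])  # perpendicular, in the ev-er plane
  tc_frame <- cbind(c(1, 0, 0), u2, soft_axis)
  joints <- tibble::tibble(
    name = c("talocrural", "subtalar", "prox_tibiofibular"),
    parent = c("tibia", "talus", "tibia"),
    child = c("talus", "hindfoot", "fibula"),
    parent_point = c(list(c(0, 0, 0)), jp(320, 0.012, -0.022),
                     jp(105, 0.046, 0.34)),
    child_point = c(list(c(0, 0, 0)), jp(320, 0.012, -0.022),
                    jp(105, 0.046, 0.34)),
    penalty_stiffness = joint_penalty_stiffness,
    capsule_stiffness = lapply(capsule_stiffness, function(x) rep_len(x, 3L)),
    capsule_frame = list(tc_frame, diag(3), diag(3)))

  model <- ankle_model(segments, joints, lig,
                       metadata = list(
                         name = "synthetic-ankle",
                         generator = "perankle::generate_anatomy",
                         seed = params$seed,
                         jitter_scale = params$jitter_scale,
                         mortise_width = params$mortise_width,
                         posture_dorsiflexion_deg = 20))
  assert_valid_model(model)
  model
}

#' Attachment-distance curve under pure external rotation
#'
#' Distance between a ligament's attachment points when the leg is rotated
#' rigidly about the long axis over the fixed foot, with no equilibrium
#' solve — the geometric screen for which structures slacken early under
#' external rotation. By default only the driver segment (tibia) rotates;
#' the distal fibula is treated as anchored to the foot by the lateral
#' ligaments, and the talus moves with the foot.
#'
#' @param model an [ankle_model()].
#' @param ligament ligament name.
#' @param er_values external-rotation angles, degrees.
#' @param rotate_segments segments rotated rigidly with the leg.
#' @return numeric vector of distances (metres), one per `er_values` entry.
#' @export
insertion_distance_curve <- function(model, ligament, er_values,
                                     rotate_segments = model$driver_segment) {
  i <- which(model$ligaments$name == ligament)
  if (length(i) != 1) {
    stop("unknown ligament: ", ligament, call. = FALSE)
  }
  l <- model$ligaments[i, ]
  pt <- function(seg, p, er) {
    if (seg %in% rotate_segments) as.numeric(rot_y(deg2rad(er)) %*% p) else p
  }
  vapply(er_values, function(er) {
    wo <- pt(l$origin_segment, l$origin_point[[1]], er)
    wi <- pt(l$insertion_segment, l$insertion_point[[1]], er)
    sqrt(sum((wo - wi)^2))
  }, numeric(1))
}

#' Re-express a model's geometry in a settled posture
#'
#' Solves the step-0 equilibrium (driver at `er`) and rewrites every
#' attachment and joint point in the settled world pose, so that zero
#' generalized coordinates correspond exactly to the loaded initial posture.
#' Slack lengths and prestrains are untouched (the physical state is
#' unchanged; only the parametrization moves), so ligament strains are
#' identical before and after. Iterated a few times because the settle
#' itself changes slightly as the geometry is rebased.
#'
#' @param model an [ankle_model()].
#' @param cfg a [solver_config()].
#' @param er driver angle (degrees) defining the posture; default 0.
#' @param iterations fixed-point sweeps; default 3.
#' @return list: `model` (rebased), `residual_norm` of the final settle,
#'   `settle_deg` (max rotational settle, degrees, of the last sweep).
#' @export
settle_reference <- function(model, cfg = solver_config(), er = 0,
                             iterations = 3L) {
  settle_deg <- NA_real_
  sol <- NULL
  for (it in seq_len(iterations)) {
    sol <- solve_step(model, er, cfg = cfg)
    st <- build_state(model, sol$coords, er)
    rot <- grep("_(df|ev|er)$", names(sol$coords))
    settle_deg <- max(abs(rad2deg(sol$coords[rot])))
    world <- function(seg, p) transform_point(st$poses[[seg]], p)
    lig <- model$ligaments
    for (i in seq_len(nrow(lig))) {
      lig$origin_point[[i]] <- world(lig$origin_segment[i],
                                     lig$origin_point[[i]])
      lig$insertion_point[[i]] <- world(lig$insertion_segment[i],
                                        lig$insertion_point[[i]])
    }
    jnt <- model$joints
    for (i in seq_len(nrow(jnt))) {
      jnt$parent_point[[i]] <- world(jnt$parent[i], jnt$parent_point[[i]])
      jnt$child_point[[i]] <- world(jnt$child[i], jnt$child_point[[i]])
    }
    model$ligaments <- lig
    model$joints <- jnt
    if (settle_deg < 1e-8) break
  }
  list(model = model, residual_norm = sol$residual_norm,
       settle_deg = settle_deg)
}
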