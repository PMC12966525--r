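#' Generalized coordinates of an ankle model
#'
#' Free coordinates are, for every non-fixed segment in model order:
#' rotations `df` (about lateral Z), `ev` (about anterior X), `er` (about the
#' long axis; omitted for the driver segment, whose external rotation is
#' prescribed) in radians, then translations `tx`, `ty`, `tz` in metres.
#' For the canonical model (fixed hindfoot; driven tibia; free talus and
#' fibula) this gives 17 unknowns.
#'
#' @param model an [ankle_model()].
#' @return character vector of coordinate names, in order.
#' @export
coord_names <- function(model) {
  out <- character()
  for (i in seq_len(nrow(model$segments))) {
    s <- model$segments$name[i]
    if (model$segments$fixed[i]) next
    rots <- c("df", "ev", "er")
    if (identical(s, model$driver_segment)) rots <- c("df", "ev")
    out <- c(out, paste(s, c(rots, "tx", "ty", "tz"), sep = "_"))
  }
  out
}

#' @rdname coord_names
#' @export
zero_coords <- function(model) {
  nm <- coord_names(model)
  stats::setNames(numeric(length(nm)), nm)
}

# Internal: compile a model into plain arrays for the C++ energy kernel.
# Reference poses are folded into the local points, so segment poses reduce
# to world = R(angles) %*% p + t.
compile_model <- function(model) {
  assert_valid_model(model)
  seg <- model$segments
  nseg <- nrow(seg)
  seg_id <- stats::setNames(seq_len(nseg) - 1L, seg$name)

  # coordinate layout: nseg x 6 matrix of 0-based indices into the coord
  # vector; -1 = identically zero (fixed segment), -2 = the prescribed driver
  # external-rotation angle.
  layout <- matrix(-1L, nseg, 6L)
  idx <- 0L
  for (i in seq_len(nseg)) {
    if (seg$fixed[i]) next
    driven <- identical(seg$name[i], model$driver_segment)
    for (j in 1:6) {
      if (j == 3L && driven) {
        layout[i, 3L] <- -2L
      } else {
        layout[i, j] <- idx
        idx <- idx + 1L
      }
    }
  }

  fold <- function(segment, p) {
    i <- seg_id[[segment]] + 1L
    as.numeric(seg$ref_rotation[[i]] %*% p + seg$ref_translation[[i]])
  }
  lig <- model$ligaments
  nl <- nrow(lig)
  lig_o_pts <- matrix(0, 3, max(nl, 1))
  lig_i_pts <- matrix(0, 3, max(nl, 1))
  for (i in seq_len(nl)) {
    lig_o_pts[, i] <- fold(lig$origin_segment[i], lig$origin_point[[i]])
    lig_i_pts[, i] <- fold(lig$insertion_segment[i], lig$insertion_point[[i]])
  }
  jnt <- model$joints
  nj <- nrow(jnt)
  jnt_p_pts <- matrix(0, 3, max(nj, 1))
  jnt_c_pts <- matrix(0, 3, max(nj, 1))
  for (i in seq_len(nj)) {
    jnt_p_pts[, i] <- fold(jnt$parent[i], jnt$parent_point[[i]])
    jnt_c_pts[, i] <- fold(jnt$child[i], jnt$child_point[[i]])
  }

  list(
    nseg = nseg,
    ncoord = idx,
    layout = layout,
    driver_seg = unname(seg_id[[model$driver_segment]]),
    lig_oseg = if (nl) unname(seg_id[lig$origin_segment]) else integer(),
    lig_iseg = if (nl) unname(seg_id[lig$insertion_segment]) else integer(),
    lig_opts = lig_o_pts, lig_ipts = lig_i_pts,
    lig_L0 = as.numeric(lig$slack_length),
    lig_k = as.numeric(lig$stiffness),
    lig_eps_t = as.numeric(lig$toe_strain),
    lig_eps0 = as.numeric(lig$prestrain),
    nlig = nl,
    jnt_pseg = if (nj) unname(seg_id[jnt$parent]) else integer(),
    jnt_cseg = if (nj) unname(seg_id[jnt$child]) else integer(),
    jnt_ppts = jnt_p_pts, jnt_cpts = jnt_c_pts,
    jnt_k = as.numeric(jnt$penalty_stiffness),
    jnt_c = if (nj) vapply(seq_len(nj), function(i) {
      Fm <- jnt$capsule_frame[[i]]
      as.numeric(Fm %*% diag(rep_len(jnt$capsule_stiffness[[i]], 3L)) %*%
                   t(Fm))
    }, numeric(9)) else matrix(0, 9, 0),
    njnt = nj)
}

# Internal: per-coordinate quadratic regularization vector for a solver
# config: translation_regularization on the driver segment's penalized
# translations, rotation_regularization (rig/soft-tissue guidance) on every
# free rotation coordinate.
reg_vector <- function(compiled, cfg) {
  reg <- numeric(compiled$ncoord)
  lay <- compiled$layout[compiled$driver_seg + 1L, 4:6]
  reg[lay[lay >= 0L] + 1L] <- cfg$translation_regularization
  rr <- cfg$rotation_regularization %||% 0
  if (rr > 0) {
    rot <- compiled$layout[, 1:3]
    reg[rot[rot >= 0L] + 1L] <- rr
  }
  dg <- rep_len(cfg$driver_rotation_guidance %||% 0, 2L)
  rot <- compiled$layout[compiled$driver_seg + 1L, 1:2]  # df, ev slots
  for (j in 1:2) {
    if (dg[j] > 0 && rot[j] >= 0L) reg[rot[j] + 1L] <- dg[j]
  }
  reg
}

#' Build the full kinematic state at given coordinates and driver angle
#'
#' Pure function of `(model, coords, driver_er)`: populates a world-frame
#' [pose()] for every segment. The external-rotation Euler component of the
#' driver segment's rotation relative to a fixed segment equals `driver_er`
#' by construction.
#'
#' @param model an [ankle_model()].
#' @param coords numeric vector as in [coord_names()] (radians / metres).
#' @param driver_er prescribed external rotation, degrees.
#' @return object of class `ankle_state`: list with `coords`, `driver_er`,
#'   and `poses` (named list of poses).
#' @export
build_state <- function(model, coords, driver_er) {
  nm <- coord_names(model)
  if (length(coords) != length(nm)) {
    stop("coords has length ", length(coords), ", model needs ",
         length(nm), call. = FALSE)
  }
  stopifnot(is.finite(driver_er))
  coords <- stats::setNames(as.numeric(coords), nm)
  er_rad <- deg2rad(driver_er)
  poses <- list()
  for (i in seq_len(nrow(model$segments))) {
    s <- model$segments$name[i]
    ref <- pose(model$segments$ref_translation[[i]],
                model$segments$ref_rotation[[i]])
    if (model$segments$fixed[i]) {
      poses[[s]] <- ref
      next
    }
    driven <- identical(s, model$driver_segment)
    a <- coords[[paste0(s, "_df")]]
    b <- coords[[paste0(s, "_ev")]]
    c <- if (driven) er_rad else coords[[paste0(s, "_er")]]
    t <- c(coords[[paste0(s, "_tx")]], coords[[paste0(s, "_ty")]],
           coords[[paste0(s, "_tz")]])
    Rq <- rot_z(a) %*% rot_x(b) %*% rot_y(c)
    poses[[s]] <- pose_compose(pose(t, Rq), ref)
  }
  structure(list(coords = coords, driver_er = driver_er, poses = poses),
            class = "ankle_state")
}

#' Clinical joint angles between two segments
#'
#' Decomposes the rotation of `child` relative to `parent` with the intrinsic
#' Euler sequence dorsiflexion (Z) -> eversion (X) -> external rotation
#' (about -Y); see [clinical_angles()].
#'
#' @param state an `ankle_state` from [build_state()].
#' @param parent,child segment names.
#' @return named numeric of three angles in degrees.
#' @export
joint_angles <- function(state, parent, child) {
  if (is.null(state$poses[[parent]]) || is.null(state$poses[[child]])) {
    stop("unknown segment in joint_angles: ", parent, " / ", child,
         call. = FALSE)
  }
  Rrel <- crossprod(state$poses[[parent]]$R, state$poses[[child]]$R)
  clinical_angles(Rrel)
}
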