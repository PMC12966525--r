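#' PER protocol configuration
#'
#' Defaults reproduce the reference experiment: talocrural joint starting in
#' 20 degrees dorsiflexion, external rotation swept from 0 to 50 degrees in
#' 1-degree steps (so step 33 is 33 degrees of external rotation), foot
#' fixed to the ground, displacement-controlled with no axial preload.
#'
#' @param initial_dorsiflexion starting dorsiflexion, degrees. The packaged
#'   geometry is expressed in this posture; the trace's dorsiflexion column
#'   reports `initial_dorsiflexion` plus the emergent change.
#' @param er_start,er_end external-rotation sweep bounds, degrees.
#' @param n_steps number of driver increments (trace has `n_steps + 1` rows
#'   including the settled step-0 state).
#' @param solver a [solver_config()].
#' @return list of class `protocol_config`.
#' @export
protocol_config <- function(initial_dorsiflexion = 20, er_start = 0,
                            er_end = 50, n_steps = 50L,
                            solver = solver_config()) {
  stopifnot(er_end > er_start, n_steps >= 1)
  structure(list(initial_dorsiflexion = initial_dorsiflexion,
                 er_start = er_start, er_end = er_end,
                 n_steps = as.integer(n_steps), solver = solver),
            class = "protocol_config")
}

#' Run the pronation-external-rotation protocol
#'
#' Sweeps the prescribed external rotation across the configured schedule,
#' solving a static equilibrium at each step (warm-started continuation) and
#' recording the tension in every ligament element plus the emergent joint
#' kinematics.
#'
#' @param model an [ankle_model()] (validated).
#' @param cfg a [protocol_config()].
#' @return a `tension_trace`: tibble with one row per step and columns
#'   `step`, `er_deg`, `df_deg` (dorsiflexion), `pronation_deg` (eversion of
#'   the foot relative to the tibia), `residual`, `converged`, then one
#'   tension column (newtons) per ligament in model definition order. The
#'   per-step solver solutions are attached as attribute `"solutions"`.
#' @export
run_per_protocol <- function(model, cfg = protocol_config()) {
  assert_valid_model(model)
  compiled <- compile_model(model)
  nm <- coord_names(model)
  schedule <- cfg$er_start +
    (0:cfg$n_steps) * (cfg$er_end - cfg$er_start) / cfg$n_steps
  scfg <- cfg$solver
  reg <- reg_vector(compiled, scfg)
  lig_names <- model$ligaments$name

  q <- numeric(length(nm))
  rows <- vector("list", length(schedule))
  sols <- vector("list", length(schedule))
  for (i in seq_along(schedule)) {
    sol <- solve_step_compiled(compiled, nm, schedule[i], q, scfg)
    if (!sol$converged && scfg$abort_on_failure) {
      stop("PER protocol: step ", i - 1L, " (er = ", schedule[i],
           " deg) did not converge (residual ",
           format(sol$residual_norm, digits = 4), ")", call. = FALSE)
    }
    q <- sol$coords
    det <- perankle_eval(unname(q), deg2rad(schedule[i]), compiled, reg,
                         scfg$external_force, TRUE)
    df_i <- which(nm == paste0(model$driver_segment, "_df"))
    ev_i <- which(nm == paste0(model$driver_segment, "_ev"))
    row <- tibble::tibble(
      step = i - 1L,
      er_deg = schedule[i],
      df_deg = cfg$initial_dorsiflexion + rad2deg(q[[df_i]]),
      # clinical pronation of the (fixed) foot relative to the leg: with X
      # anterior and Z lateral, foot eversion is a negative rotation about
      # +X, so pronation equals the tibia's +X Euler component directly
      pronation_deg = rad2deg(q[[ev_i]]),
      residual = sol$residual_norm,
      converged = sol$converged)
    ten <- as.numeric(det$lig_tension)
    for (j in seq_along(lig_names)) row[[lig_names[j]]] <- ten[j]
    rows[[i]] <- row
    sols[[i]] <- sol
  }
  trace <- dplyr::bind_rows(rows)
  attr(trace, "solutions") <- sols
  attr(trace, "ligaments") <- lig_names
  class(trace) <- c("tension_trace", class(trace))
  trace
}

#' Joint reaction forces at a state
#'
#' For every penalty joint, the reaction is `penalty_stiffness` times the
#' world-frame gap vector between the parent and child attachment points;
#' the returned force is the force exerted on the child segment.
#'
#' @param model an [ankle_model()].
#' @param state an `ankle_state` from [build_state()].
#' @return tibble with columns `joint`, `fx`, `fy`, `fz`, `magnitude`
#'   (newtons, world frame).
#' @export
joint_reaction_forces <- function(model, state) {
  purrr::pmap_dfr(model$joints, function(name, parent, child, parent_point,
                                         child_point, penalty_stiffness,
                                         ...) {
    wp <- transform_point(state$poses[[parent]], parent_point)
    wc <- transform_point(state$poses[[child]], child_point)
    f <- penalty_stiffness * (wp - wc)   # force on the child
    tibble::tibble(joint = name, fx = f[1], fy = f[2], fz = f[3],
                   magnitude = sqrt(sum(f^2)))
  })
}

#' Detect a tension plateau
#'
#' The plateau onset is the first step after which the per-step increase
#' stays below `slope_threshold` for at least `sustain` consecutive steps;
#' the plateau value is the mean of the series from the onset to the end.
#'
#' @param series tensions by step (newtons), steps 0..n.
#' @param slope_threshold N per step; default 1.
#' @param sustain consecutive sub-threshold steps required; default 5.
#' @return list with `onset_step` (integer, 0-based) and `plateau_value`
#'   (N); both `NA` if no plateau exists.
#' @export
detect_plateau <- function(series, slope_threshold = 1, sustain = 5L) {
  n <- length(series) - 1L
  stopifnot(n >= sustain)
  d <- diff(series)
  for (s in 0:(n - sustain)) {
    if (all(d[(s + 1):(s + sustain)] < slope_threshold)) {
      return(list(onset_step = s,
                  plateau_value = mean(series[(s + 1):(n + 1)])))
    }
  }
  list(onset_step = NA_integer_, plateau_value = NA_real_)
}

#' Detect the onset of a tension rise after an initial slack phase
#'
#' Returns the step just after the maximal initial run of steps whose
#' tension does not exceed `tension_floor`: the step at which the ligament
#' first carries load. `NA` if the series never exceeds the floor; 0 if it
#' is above the floor from the start.
#'
#' @param series tensions by step (newtons), nonnegative.
#' @param tension_floor newtons; default 1.
#' @return integer step (0-based) or `NA`.
#' @export
detect_rise_onset <- function(series, tension_floor = 1) {
  stopifnot(all(series >= 0))
  above <- series > tension_floor
  if (!any(above)) return(NA_integer_)
  as.integer(which(above)[1] - 1L)
}

#' Per-ligament curve statistics of a tension trace
#'
#' Applies [detect_plateau()] and [detect_rise_onset()] to every ligament
#' column of a trace (plus an aggregate `IOL` row summing the interosseous
#' fibers, when present).
#'
#' @param trace a `tension_trace` from [run_per_protocol()].
#' @param slope_threshold,sustain,tension_floor passed to the detectors.
#' @return tibble: `ligament`, `initial_tension`, `final_tension`,
#'   `plateau_onset_step`, `plateau_value`, `rise_onset_step`.
#' @export
curve_stats <- function(trace, slope_threshold = 1, sustain = 5L,
                        tension_floor = 1) {
  ligs <- attr(trace, "ligaments")
  if (is.null(ligs)) {
    ligs <- setdiff(names(trace), c("step", "er_deg", "df_deg",
                                    "pronation_deg", "residual",
                                    "converged"))
  }
  series_list <- stats::setNames(lapply(ligs, function(l) trace[[l]]), ligs)
  iol <- grep("^IOL", ligs, value = TRUE)
  if (length(iol) > 1) {
    series_list$IOL <- Reduce(`+`, series_list[iol])
  }
  purrr::imap_dfr(series_list, function(s, nm) {
    pl <- detect_plateau(s, slope_threshold, sustain)
    tibble::tibble(ligament = nm,
                   initial_tension = s[1],
                   final_tension = s[length(s)],
                   plateau_onset_step = pl$onset_step,
                   plateau_value = pl$plateau_value,
                   rise_onset_step = detect_rise_onset(s, tension_floor))
  })
}

#' Global free-body balance at an equilibrium state
#'
#' Checks Newton's third-law bookkeeping of the force extraction: the net
#' world-frame force and moment transmitted to the fixed hindfoot must equal
#' the net load applied to the system — the regularization/guidance loads,
#' any external dead load on the driver segment, and the driver couple about
#' its instantaneous axis. Both residuals are ~0 at a converged equilibrium
#' of a capsule-free model (capsule restraints act directly on Euler
#' coordinates and are not point forces, so models using them are checked on
#' the force residual only).
#'
#' @param model an [ankle_model()].
#' @param coords equilibrium coordinates.
#' @param driver_er prescribed external rotation, degrees.
#' @param cfg the [solver_config()] used for the solve.
#' @return list with `force_residual` and `moment_residual` (3-vectors, N
#'   and N m) and their norms.
#' @export
force_balance <- function(model, coords, driver_er, cfg = solver_config()) {
  state <- build_state(model, coords, driver_er)
  fixed <- model$segments$name[model$segments$fixed]
  lig <- ligament_states(model, state)

  Fh <- c(0, 0, 0); Mh <- c(0, 0, 0)
  add <- function(seg, w, f) {
    if (seg %in% fixed) {
      Fh <<- Fh + f
      Mh <<- Mh + pracma_cross(w, f)
    }
  }
  for (i in seq_len(nrow(model$ligaments))) {
    l <- model$ligaments[i, ]
    wo <- transform_point(state$poses[[l$origin_segment]], l$origin_point[[1]])
    wi <- transform_point(state$poses[[l$insertion_segment]],
                          l$insertion_point[[1]])
    u <- lig$direction[[i]]
    Fi <- lig$tension[i]
    if (!is.finite(Fi) || Fi == 0 || any(is.na(u))) next
    add(l$origin_segment, wo, -Fi * u)
    add(l$insertion_segment, wi, Fi * u)
  }
  jr <- joint_reaction_forces(model, state)
  for (i in seq_len(nrow(model$joints))) {
    j <- model$joints[i, ]
    wp <- transform_point(state$poses[[j$parent]], j$parent_point[[1]])
    wc <- transform_point(state$poses[[j$child]], j$child_point[[1]])
    f <- c(jr$fx[i], jr$fy[i], jr$fz[i])
    add(j$child, wc, f)
    add(j$parent, wp, -f)
  }

  # applied loads on the driver segment
  drv <- model$driver_segment
  tname <- paste0(drv, c("_tx", "_ty", "_tz"))
  tdrv <- as.numeric(coords[tname])
  f_reg <- -cfg$translation_regularization * tdrv
  f_ext <- cfg$external_force
  compiled <- compile_model(model)
  reg <- reg_vector(compiled, cfg)
  ev <- perankle_eval(unname(as.numeric(coords)), deg2rad(driver_er),
                      compiled, reg, cfg$external_force, FALSE)

  # applied couples: rotational regularization/guidance on every free
  # segment, mapped from generalized torques to world couples through each
  # segment's (non-orthogonal) Euler axis matrix
  m_reg <- c(0, 0, 0)
  seg_axes <- function(a, b) {
    rbind(c(0, 0, 1),                                   # dorsiflexion axis
          as.numeric(rot_z(a) %*% c(1, 0, 0)),          # eversion axis
          as.numeric(rot_z(a) %*% rot_x(b) %*% c(0, 1, 0)))  # long axis
  }
  for (i in seq_len(nrow(model$segments))) {
    s <- model$segments$name[i]
    if (model$segments$fixed[i]) next
    slots <- paste0(s, c("_df", "_ev", "_er"))
    tau <- numeric(3)
    for (j in 1:3) {
      if (slots[j] %in% names(coords)) {
        id <- match(slots[j], coord_names(model))
        tau[j] <- -reg[id] * as.numeric(coords[[slots[j]]])
      }
    }
    a <- as.numeric(coords[[paste0(s, "_df")]])
    b <- as.numeric(coords[[paste0(s, "_ev")]])
    if (any(tau != 0)) {
      m_reg <- m_reg + solve(seg_axes(a, b), tau)
    }
  }

  # driver couple: the generalized force conjugate to the prescribed angle
  # acts along the dual (reciprocal) vector of the long-axis Euler slot,
  # since the intrinsic Euler axes are not mutually orthogonal
  a <- as.numeric(coords[[paste0(drv, "_df")]])
  b <- as.numeric(coords[[paste0(drv, "_ev")]])
  m_driver <- ev$grad_er * solve(seg_axes(a, b), c(0, 0, 1))

  force_residual <- Fh - (f_ext + f_reg)
  moment_residual <- Mh -
    (pracma_cross(tdrv, f_ext + f_reg) + m_driver + m_reg)
  list(force_residual = force_residual,
       moment_residual = moment_residual,
       force_norm = sqrt(sum(force_residual^2)),
       moment_norm = sqrt(sum(moment_residual^2)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Write / read a tension trace as CSV
#'
#' Comma separator, `.` decimal, header row, LF line endings, numbers at a
#' fixed significant-digit count so identical runs produce byte-identical
#' files.
#'
#' @param trace a `tension_trace`.
#' @param path file path.
#' @param digits significant digits for numeric columns (default 9).
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a tibble.
#' @export
write_trace_csv <- function(trace, path, digits = 9) {
  df <- as.data.frame(trace)
  cols <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[cols]) {
    if (nm == "step") next
    df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  lines <- do.call(paste, c(lapply(df, as.character), sep = ","))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$converged <- as.logical(df$converged)
  out <- tibble::as_tibble(df)
  attr(out, "ligaments") <- setdiff(names(out),
                                    c("step", "er_deg", "df_deg",
                                      "pronation_deg", "residual",
                                      "converged"))
  class(out) <- c("tension_trace", class(out))
  out
}
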