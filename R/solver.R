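#' Solver configuration
#'
#' @param gradient_tolerance convergence threshold on the Euclidean norm of
#'   the free-coordinate energy gradient (N / N m mixed units). Default 1e-6.
#' @param max_iterations Newton iteration cap per step. Default 500.
#' @param joint_penalty_stiffness default penalty stiffness (N/m) used by
#'   model generators for the anatomical joints. Default 1e7.
#' @param translation_regularization quadratic regularization (N/m) on the
#'   driver segment's penalized translations, keeping the prescribed
#'   rotation axis well-defined. Default 1e3.
#' @param rotation_regularization weak restoring stiffness (N m/rad) pulling
#'   every free rotation coordinate toward its reference value, standing in
#'   for the soft tissue envelope; keeps rotational modes that no taut
#'   ligament resists well-posed. Default 2.
#' @param driver_rotation_guidance compliant guidance stiffness (N m/rad) on
#'   the driver segment's free rotations, length 2 (dorsiflexion, eversion):
#'   the test rig that holds the leg over the fixed foot while prescribing
#'   external rotation guides flexion rather stiffly but leaves coronal tilt
#'   loose, so flexion and pronation still change, against this stiffness.
#'   Default c(120, 3).
#' @param external_force optional world-frame dead load (N, length 3)
#'   applied at the driver segment's frame origin; default zero (the PER
#'   protocol is displacement-controlled with no axial preload).
#' @param fixed_coords optional character vector of coordinate names to
#'   freeze at their initial values (useful for reduced/toy problems).
#' @param levenberg_initial initial Levenberg damping added to the Hessian
#'   diagonal when a raw Newton step fails to decrease the energy.
#' @param abort_on_failure if `TRUE`, [continuation_run()] stops at the
#'   first non-converged step instead of carrying on.
#' @return a list of class `solver_config`.
#' @export
solver_config <- function(gradient_tolerance = 1e-6,
                          max_iterations = 500L,
                          joint_penalty_stiffness = 1e7,
                          translation_regularization = 1e3,
                          rotation_regularization = 2,
                          driver_rotation_guidance = c(120, 3),
                          external_force = c(0, 0, 0),
                          fixed_coords = character(),
                          levenberg_initial = 1e-6,
                          abort_on_failure = FALSE) {
  stopifnot(gradient_tolerance > 0, max_iterations >= 1,
            joint_penalty_stiffness > 0, translation_regularization >= 0,
            rotation_regularization >= 0, all(driver_rotation_guidance >= 0),
            length(external_force) == 3L, levenberg_initial > 0)
  structure(list(gradient_tolerance = gradient_tolerance,
                 max_iterations = as.integer(max_iterations),
                 joint_penalty_stiffness = joint_penalty_stiffness,
                 translation_regularization = translation_regularization,
                 rotation_regularization = rotation_regularization,
                 driver_rotation_guidance = driver_rotation_guidance,
                 external_force = as.numeric(external_force),
                 fixed_coords = fixed_coords,
                 levenberg_initial = levenberg_initial,
                 abort_on_failure = abort_on_failure),
            class = "solver_config")
}

# internal solve on a pre-compiled model; returns list(coords, residual_norm,
# converged, iterations, energy)
solve_step_compiled <- function(compiled, nm, driver_er, initial_coords,
                                cfg) {
  q <- unname(as.numeric(initial_coords))
  stopifnot(length(q) == compiled$ncoord, all(is.finite(q)),
            is.finite(driver_er))
  er <- deg2rad(driver_er)
  reg <- reg_vector(compiled, cfg)
  free <- !(nm %in% cfg$fixed_coords)
  nf <- sum(free)

  ev <- perankle_eval(q, er, compiled, reg, cfg$external_force, FALSE)
  gnorm <- sqrt(sum(ev$grad[free]^2))
  iter <- 0L
  lambda <- 0
  while (gnorm > cfg$gradient_tolerance && iter < cfg$max_iterations &&
         nf > 0) {
    iter <- iter + 1L
    H <- perankle_hessian(q, er, compiled, reg, cfg$external_force)[free, free,
                                                                    drop = FALSE]
    g <- ev$grad[free]
    dscale <- pmax(abs(diag(H)), 1e-8)
    step_ok <- FALSE
    for (trial in 1:60) {
      Hd <- H + diag(lambda * dscale, nf)
      d <- tryCatch(solve(Hd, -g), error = function(e) NULL)
      if (!is.null(d) && all(is.finite(d))) {
        qn <- q
        qn[free] <- qn[free] + d
        evn <- perankle_eval(qn, er, compiled, reg, cfg$external_force, FALSE)
        # accept on energy decrease or on gradient-norm decrease (handles
        # flat, ligament-slack directions where energy is locally constant)
        gn <- sqrt(sum(evn$grad[free]^2))
        if (is.finite(evn$energy) &&
            (evn$energy <= ev$energy + 1e-12 * (1 + abs(ev$energy)) ||
             gn < gnorm)) {
          q <- qn; ev <- evn; gnorm <- gn
          lambda <- if (lambda == 0) 0 else lambda / 4
          if (lambda < 1e-12) lambda <- 0
          step_ok <- TRUE
          break
        }
      }
      lambda <- if (lambda == 0) cfg$levenberg_initial else lambda * 10
    }
    if (!step_ok) break
  }
  list(coords = stats::setNames(q, nm), residual_norm = gnorm,
       converged = gnorm <= cfg$gradient_tolerance, iterations = iter,
       energy = ev$energy)
}

#' Solve one quasi-static equilibrium step
#'
#' Minimizes the total potential energy over the free generalized
#' coordinates at a fixed prescribed external-rotation angle, using damped
#' Newton iterations on the analytic gradient (Hessian by central finite
#' differences of the gradient). Convergence is declared on the gradient
#' norm, so equilibrium is asserted directly.
#'
#' @param model an [ankle_model()].
#' @param driver_er prescribed external rotation, degrees.
#' @param initial_coords starting coordinates (default: all zero).
#' @param cfg a [solver_config()].
#' @return list of class `step_solution`: `coords`, `residual_norm`,
#'   `converged`, `iterations`, `energy`. Non-convergence is flagged, never
#'   silent.
#' @export
solve_step <- function(model, driver_er, initial_coords = NULL,
                       cfg = solver_config()) {
  compiled <- compile_model(model)
  nm <- coord_names(model)
  if (is.null(initial_coords)) initial_coords <- numeric(length(nm))
  out <- solve_step_compiled(compiled, nm, driver_er, initial_coords, cfg)
  class(out) <- "step_solution"
  out
}

#' Continuation over a prescribed external-rotation schedule
#'
#' Solves a sequence of static equilibria, warm-starting every step from the
#' previous step's solution — a quasi-static sweep mirroring a slow physical
#' rotation.
#'
#' @param model an [ankle_model()].
#' @param driver_schedule numeric vector of external-rotation angles
#'   (degrees), monotone nondecreasing.
#' @param cfg a [solver_config()].
#' @param initial_coords starting coordinates for the first step.
#' @return list of `step_solution`s, one per schedule entry.
#' @export
continuation_run <- function(model, driver_schedule, cfg = solver_config(),
                             initial_coords = NULL) {
  stopifnot(length(driver_schedule) >= 1,
            !is.unsorted(driver_schedule, strictly = FALSE))
  compiled <- compile_model(model)
  nm <- coord_names(model)
  q <- if (is.null(initial_coords)) numeric(length(nm)) else initial_coords
  out <- vector("list", length(driver_schedule))
  for (i in seq_along(driver_schedule)) {
    sol <- solve_step_compiled(compiled, nm, driver_schedule[i], q, cfg)
    class(sol) <- "step_solution"
    out[[i]] <- sol
    if (!sol$converged && cfg$abort_on_failure) {
      warning("continuation aborted: step ", i, " (er = ",
              driver_schedule[i], " deg) did not converge")
      out <- out[seq_len(i)]
      break
    }
    q <- sol$coords
  }
  out
}

#' @export
print.step_solution <- function(x, ...) {
  cat("<step_solution> converged:", x$converged,
      " residual:", format(x$residual_norm, digits = 4),
      " iterations:", x$iterations, "\n")
  invisible(x)
}
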