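#' Tension-only ligament force law
#'
#' Piecewise toe/linear law (Blankevoort-style) for a passive ligament that
#' develops tensile force only in elongation. With total strain
#' `eps = (L - L0)/L0 + prestrain`:
#' \deqn{F = 0 \quad (\epsilon \le 0)}
#' \deqn{F = k\,\epsilon^2/(4\epsilon_t) \quad (0 < \epsilon \le 2\epsilon_t)}
#' \deqn{F = k\,(\epsilon - \epsilon_t) \quad (\epsilon > 2\epsilon_t)}
#' The law is continuous and once-differentiable at both branch junctions.
#'
#' @param strain total strain (dimensionless), may be a vector.
#' @param k linear-branch stiffness: force in newtons at unit strain.
#' @param eps_t toe-region half-width (strain at which the quadratic toe
#'   hands over to the linear branch is `2 * eps_t`); default 0.03.
#' @return tension in newtons (vectorized over `strain`).
#' @export
#' @examples
#' ligament_tension(c(-0.05, 0.06, 0.10), k = 1000, eps_t = 0.03)
ligament_tension <- function(strain, k, eps_t = 0.03) {
  stopifnot(all(k >= 0), all(eps_t > 0))
  toe <- strain > 0 & strain <= 2 * eps_t
  lin <- strain > 2 * eps_t
  out <- numeric(length(strain))
  if (length(k) == 1 && length(eps_t) == 1) {
    out[toe] <- k * strain[toe]^2 / (4 * eps_t)
    out[lin] <- k * (strain[lin] - eps_t)
  } else {
    k <- rep_len(k, length(strain)); eps_t <- rep_len(eps_t, length(strain))
    out[toe] <- k[toe] * strain[toe]^2 / (4 * eps_t[toe])
    out[lin] <- k[lin] * (strain[lin] - eps_t[lin])
  }
  out
}

#' Stored elastic energy of a ligament at a given strain
#'
#' Potential whose derivative with respect to ligament length is
#' [ligament_tension()]: `dV/dL = F` with `dL = L0 d(eps)`.
#'
#' @inheritParams ligament_tension
#' @param L0 slack length in metres.
#' @return energy in joules (vectorized over `strain`).
#' @export
strain_energy <- function(strain, k, eps_t = 0.03, L0 = 1) {
  stopifnot(all(k >= 0), all(eps_t > 0), all(L0 > 0))
  n <- max(length(strain), length(k), length(eps_t), length(L0))
  strain <- rep_len(strain, n); k <- rep_len(k, n)
  eps_t <- rep_len(eps_t, n); L0 <- rep_len(L0, n)
  out <- numeric(n)
  toe <- strain > 0 & strain <= 2 * eps_t
  lin <- strain > 2 * eps_t
  out[toe] <- k[toe] * L0[toe] * strain[toe]^3 / (12 * eps_t[toe])
  out[lin] <- k[lin] * L0[lin] *
    ((strain[lin] - eps_t[lin])^2 / 2 + eps_t[lin]^2 / 6)
  out
}

#' Ligament length in a kinematic state
#'
#' Straight-line Euclidean distance between the world-frame attachment
#' points (no wrapping surfaces).
#'
#' @param state an `ankle_state` from [build_state()].
#' @param lig one row of a model's `ligaments` tibble (or a list with the
#'   same fields).
#' @return length in metres. Coincident endpoints return 0 with a warning
#'   (direction undefined).
#' @export
ligament_length <- function(state, lig) {
  wo <- transform_point(state$poses[[lig$origin_segment[[1]]]],
                        lig$origin_point[[1]])
  wi <- transform_point(state$poses[[lig$insertion_segment[[1]]]],
                        lig$insertion_point[[1]])
  L <- sqrt(sum((wo - wi)^2))
  if (L < 1e-12) {
    warning("ligament '", lig$name[[1]],
            "' has coincident endpoints; direction undefined")
  }
  L
}

#' Per-ligament state records at a model state
#'
#' @param model an [ankle_model()].
#' @param state an `ankle_state`.
#' @return tibble with one row per ligament: `name`, `length` (m), `strain`,
#'   `tension` (N), and `direction` (unit 3-vector insertion -> origin,
#'   world frame, list-column).
#' @export
ligament_states <- function(model, state) {
  lig <- model$ligaments
  purrr::pmap_dfr(lig, function(name, origin_segment, insertion_segment,
                                origin_point, insertion_point, slack_length,
                                stiffness, toe_strain, prestrain, ...) {
    wo <- transform_point(state$poses[[origin_segment]], origin_point)
    wi <- transform_point(state$poses[[insertion_segment]], insertion_point)
    d <- wo - wi
    L <- sqrt(sum(d^2))
    eps <- (L - slack_length) / slack_length + prestrain
    tibble::tibble(
      name = name, length = L, strain = eps,
      tension = ligament_tension(eps, stiffness, toe_strain),
      direction = list(if (L > 1e-12) d / L else c(NA_real_, NA_real_,
                                                   NA_real_)))
  })
}

#' Total potential energy of the model at a state
#'
#' Sum of ligament strain energies, quadratic joint-penalty energies,
#' solver regularization on the driver segment's penalized translations,
#' and the potential of any configured external dead load. This is the
#' scalar objective whose stationary points are the quasi-static equilibria;
#' minimizing it yields ligament tensions and joint reaction forces
#' concurrently.
#'
#' @param model an [ankle_model()].
#' @param state an `ankle_state` from [build_state()].
#' @param cfg a [solver_config()].
#' @return energy in joules.
#' @export
total_energy <- function(model, state, cfg = solver_config()) {
  compiled <- compile_model(model)
  ev <- perankle_eval(unname(state$coords), deg2rad(state$driver_er),
                      compiled, reg_vector(compiled, cfg),
                      cfg$external_force, FALSE)
  ev$energy
}

#' Gradient of the total energy with respect to the free coordinates
#'
#' Analytic generalized forces (N for translations, N m for rotations);
#' the equilibrium condition is that this vector vanishes.
#'
#' @param model an [ankle_model()].
#' @param coords free coordinate vector (see [coord_names()]).
#' @param driver_er prescribed external rotation, degrees.
#' @param cfg a [solver_config()].
#' @return named numeric vector, one element per free coordinate.
#' @export
energy_gradient <- function(model, coords, driver_er,
                            cfg = solver_config()) {
  compiled <- compile_model(model)
  nm <- coord_names(model)
  stopifnot(length(coords) == length(nm))
  ev <- perankle_eval(unname(as.numeric(coords)), deg2rad(driver_er),
                      compiled, reg_vector(compiled, cfg),
                      cfg$external_force, FALSE)
  stats::setNames(as.numeric(ev$grad), nm)
}
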