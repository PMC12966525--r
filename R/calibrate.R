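#' Calibration targets
#'
#' An anchor set ties simulated quantities to published values. Each row
#' names a quantity of the reference PER trace:
#' * `"tension"` — tension of `ligament` at `step` (N);
#' * `"tension_sum"` — summed tension of all ligaments whose name starts
#'   with `ligament` (used for the interosseous fibers), at `step`;
#' * `"tension_delta"` — tension at `step` minus tension at `step2`
#'   (encodes "the curve flattens out");
#' * `"plateau_value"`, `"plateau_onset"` — from [detect_plateau()];
#' * `"rise_onset"` — from [detect_rise_onset()];
#' * `"pronation"`, `"dorsiflexion"` — emergent joint angles at `step`
#'   (degrees).
#'
#' @param quantity,ligament,step,step2,value,weight vectors defining the
#'   anchors (recycled to common length). `ligament` is `NA` for kinematic
#'   anchors; `step2` only applies to `tension_delta`.
#' @return tibble of class `calibration_targets`.
#' @export
calibration_targets <- function(quantity, ligament = NA_character_,
                                step = NA_integer_, step2 = NA_integer_,
                                value, weight = 1) {
  out <- tibble::tibble(quantity = quantity, ligament = ligament,
                        step = as.integer(step), step2 = as.integer(step2),
                        value = as.numeric(value), weight = weight)
  stopifnot(nrow(out) >= 1, all(out$quantity %in% c(
    "tension", "tension_sum", "tension_delta", "plateau_value",
    "plateau_onset", "rise_onset", "pronation", "dorsiflexion")))
  class(out) <- c("calibration_targets", class(out))
  out
}

# evaluate one anchor row against a trace
eval_target_row <- function(trace, quantity, ligament, step, step2, ...) {
  series <- function() {
    if (!is.na(ligament) && ligament %in% names(trace)) {
      trace[[ligament]]
    } else {
      cols <- grep(paste0("^", ligament), names(trace), value = TRUE)
      if (length(cols) == 0) stop("unknown ligament in targets: ", ligament)
      rowSums(trace[, cols, drop = FALSE])
    }
  }
  switch(quantity,
    tension = series()[step + 1L],
    tension_sum = series()[step + 1L],
    tension_delta = series()[step + 1L] - series()[step2 + 1L],
    plateau_value = detect_plateau(series())$plateau_value,
    plateau_onset = {
      o <- detect_plateau(series())$onset_step
      if (is.na(o)) length(series()) else as.numeric(o)
    },
    rise_onset = {
      o <- detect_rise_onset(series())
      if (is.na(o)) length(series()) else as.numeric(o)
    },
    pronation = trace$pronation_deg[step + 1L],
    dorsiflexion = trace$df_deg[step + 1L],
    stop("unknown target quantity: ", quantity))
}

#' Evaluate calibration targets against a simulated trace
#'
#' @param trace a `tension_trace`.
#' @param targets a [calibration_targets()] tibble.
#' @return the targets tibble with extra columns `achieved` and `residual`
#'   (`achieved - value`).
#' @export
evaluate_targets <- function(trace, targets) {
  targets$achieved <- purrr::pmap_dbl(targets, function(...) {
    eval_target_row(trace, ...)
  })
  targets$residual <- targets$achieved - targets$value
  targets
}

#' Declare free calibration parameters
#'
#' @param ligaments ligament names whose parameters are free.
#' @param stiffness,prestrain,attachments which parameter families to free.
#' @param stiffness_bounds multiplicative bounds on stiffness.
#' @param prestrain_bounds absolute bounds on prestrain.
#' @param attachment_bound per-component bound (m) on attachment-site
#'   perturbations.
#' @return tibble with one row per scalar parameter: `ligament`, `parameter`,
#'   `start`, `lower`, `upper`.
#' @export
calibration_parameters <- function(ligaments,
                                   stiffness = TRUE, prestrain = TRUE,
                                   attachments = FALSE,
                                   stiffness_bounds = c(0.2, 5),
                                   prestrain_bounds = c(-0.19, 0.19),
                                   attachment_bound = 0.005) {
  rows <- list()
  for (l in ligaments) {
    if (stiffness) {
      rows <- c(rows, list(tibble::tibble(
        ligament = l, parameter = "stiffness_mult", start = 1,
        lower = stiffness_bounds[1], upper = stiffness_bounds[2])))
    }
    if (prestrain) {
      rows <- c(rows, list(tibble::tibble(
        ligament = l, parameter = "prestrain", start = NA_real_,
        lower = prestrain_bounds[1], upper = prestrain_bounds[2])))
    }
    if (attachments) {
      for (end in c("origin", "insertion")) {
        for (ax in c("x", "y", "z")) {
          rows <- c(rows, list(tibble::tibble(
            ligament = l, parameter = paste(end, ax, sep = "_"), start = 0,
            lower = -attachment_bound, upper = attachment_bound)))
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

# apply a raw parameter vector to a model according to a parameter spec
apply_parameters <- function(model, spec, p) {
  stopifnot(length(p) == nrow(spec))
  lig <- model$ligaments
  ax_i <- c(x = 1L, y = 2L, z = 3L)
  for (i in seq_len(nrow(spec))) {
    j <- which(lig$name == spec$ligament[i])
    stopifnot(length(j) == 1)
    par <- spec$parameter[i]
    if (par == "stiffness_mult") {
      lig$stiffness[j] <- lig$stiffness[j] * p[i]
    } else if (par == "prestrain") {
      lig$prestrain[j] <- p[i]
    } else {
      end <- sub("_[xyz]$", "", par)
      ax <- ax_i[[sub("^.*_", "", par)]]
      col <- if (end == "origin") "origin_point" else "insertion_point"
      pt <- lig[[col]][[j]]
      pt[ax] <- pt[ax] + p[i]
      lig[[col]][[j]] <- pt
    }
  }
  model$ligaments <- lig
  model
}

# fill NA starts from the model's current values
spec_starts <- function(model, spec) {
  for (i in seq_len(nrow(spec))) {
    if (is.na(spec$start[i])) {
      j <- which(model$ligaments$name == spec$ligament[i])
      spec$start[i] <- switch(spec$parameter[i],
        stiffness_mult = 1,
        prestrain = model$ligaments$prestrain[j],
        0)
    }
  }
  spec
}

#' Calibrate ligament parameters to tension anchors
#'
#' Bounded weighted least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) over the declared free parameters, minimizing
#' the weighted residuals of the anchor set evaluated on the simulated PER
#' trace. Deterministic for a fixed start, parameter spec and configuration.
#' Discrete anchors (plateau/rise onsets) contribute to the reported
#' residuals but are piecewise constant in the parameters; they are pinned
#' in practice through smooth `tension` / `tension_delta` companions.
#'
#' @param model starting [ankle_model()].
#' @param targets a [calibration_targets()] tibble.
#' @param parameters a [calibration_parameters()] tibble.
#' @param protocol the [protocol_config()] under which anchors are defined.
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @param ptol,ftol convergence tolerances passed to the optimizer.
#' @param ridge weight of a mild ridge residual `ridge * (p - start) /
#'   (upper - lower)` per parameter, regularizing ill-posed fits and
#'   guaranteeing at least as many residuals as parameters.
#' @return object of class `perankle_calibration`: `model` (fitted),
#'   `residuals` (per-anchor tibble), `objective`, `converged`, `message`,
#'   `parameters` (spec with fitted values), `trace` (fitted-model trace).
#' @export
calibrate <- function(model, targets, parameters,
                      protocol = protocol_config(), maxiter = 25L,
                      ptol = 1e-6, ftol = 1e-8, ridge = 1e-3) {
  assert_valid_model(model)
  stopifnot(nrow(targets) >= 1, nrow(parameters) >= 1)
  spec <- spec_starts(model, parameters)
  smooth <- !targets$quantity %in% c("plateau_onset", "rise_onset")
  if (!any(smooth)) {
    stop("calibration needs at least one smooth anchor", call. = FALSE)
  }
  pscale <- pmax(spec$upper - spec$lower, 1e-8)
  resid_fn <- function(p) {
    m <- apply_parameters(model, spec, p)
    tr <- run_per_protocol(m, protocol)
    ev <- evaluate_targets(tr, targets[smooth, ])
    r <- ev$weight * ev$residual
    if (any(!is.finite(r))) {
      stop("calibration objective is non-finite", call. = FALSE)
    }
    c(r, ridge * (p - spec$start) / pscale)
  }
  fit <- minpack.lm::nls.lm(
    par = spec$start, lower = spec$lower, upper = spec$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ptol = ptol,
                                         ftol = ftol))
  fitted_model <- apply_parameters(model, spec, fit$par)
  tr <- run_per_protocol(fitted_model, protocol)
  res <- evaluate_targets(tr, targets)
  spec$fitted <- fit$par
  out <- list(model = fitted_model, residuals = res,
              objective = sum((res$weight * res$residual)[smooth]^2),
              converged = fit$info %in% 1:4,
              message = fit$message, info = fit$info,
              iterations = fit$niter, parameters = spec, trace = tr)
  class(out) <- "perankle_calibration"
  out
}

#' @export
print.perankle_calibration <- function(x, ...) {
  cat("<perankle_calibration> converged:", x$converged,
      " objective:", format(x$objective, digits = 5),
      " iterations:", x$iterations, "\n")
  print(x$residuals[, c("quantity", "ligament", "step", "value", "achieved",
                        "residual")])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' `tidy()` returns the per-anchor residual table; `glance()` a one-row fit
#' summary.
#'
#' @param x a `perankle_calibration`.
#' @param ... unused.
#' @export
tidy.perankle_calibration <- function(x, ...) {
  tibble::as_tibble(x$residuals)
}

#' @rdname tidy.perankle_calibration
#' @export
glance.perankle_calibration <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 iterations = x$iterations,
                 n_anchors = nrow(x$residuals),
                 n_parameters = nrow(x$parameters))
}

#' The packaged calibrated reference model
#'
#' Loads the pre-calibrated synthetic ankle model shipped with the package.
#' Its ligament stiffnesses, prestrains and small attachment perturbations
#' were fitted (see `data-raw/build_reference_model.R`) so that the default
#' PER protocol reproduces the published tension anchors; the calibration
#' configuration and residuals are recorded in the model metadata.
#'
#' @return an [ankle_model()].
#' @export
reference_model <- function() {
  path <- system.file("extdata", "reference-model.json",
                      package = "perankle", mustWork = TRUE)
  read_ankle_model(path)
}

#' Published tension and kinematic anchors for the reference PER run
#'
#' The printed anchor set: deltoid-band tensions at step 33 (TNL 230 N,
#' dATTL 175 N, dPTTL ~180 N), plateau values (TSL 175 N, TCL 243 N, AITFL
#' ~160 N from step 30, summed IOL ~40 N), the step-0 TCL tension (~200 N),
#' the emergent pronation at step 33 (6 degrees), and the dPTTL rise-onset
#' step (28).
#'
#' @return a [calibration_targets()] tibble.
#' @export
reference_targets <- function() {
  calibration_targets(
    quantity = c("tension", "tension", "plateau_value", "plateau_value",
                 "tension", "plateau_value", "plateau_value", "tension",
                 "pronation", "rise_onset"),
    ligament = c("TNL", "dATTL", "TSL", "TCL", "TCL", "AITFL", "IOL",
                 "dPTTL", NA, "dPTTL"),
    step = c(33L, 33L, NA, NA, 0L, NA, NA, 33L, 33L, NA),
    value = c(230, 175, 175, 243, 200, 160, 40, 180, 6, 28))
}
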