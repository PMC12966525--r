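# Small models built in code for the unit tests.

empty_joints <- function() {
  tibble::tibble(name = character(), parent = character(),
                 child = character(),
                 parent_point = list(), child_point = list(),
                 penalty_stiffness = numeric(),
                 capsule_stiffness = list())
}

# A hinge toy: fixed hindfoot, driven tibia, no joints, `ligs` ligament rows.
# With every coordinate but tibia_df frozen, this is a 1-DOF problem.
toy_model <- function(ligs, metadata = list(name = "toy")) {
  segments <- tibble::tibble(name = c("hindfoot", "tibia"),
                             fixed = c(TRUE, FALSE))
  ankle_model(segments, empty_joints(), ligs, metadata = metadata)
}

toy_ligament <- function(name = "band",
                         origin_point = c(0.02, 0.05, -0.01),
                         insertion_point = c(0.05, -0.03, -0.01),
                         slack_length = NULL, stiffness = 1000,
                         toe_strain = 0.03, prestrain = 0) {
  if (is.null(slack_length)) {
    slack_length <- sqrt(sum((origin_point - insertion_point)^2))
  }
  tibble::tibble(name = name,
                 origin_segment = "tibia", insertion_segment = "hindfoot",
                 origin_point = list(origin_point),
                 insertion_point = list(insertion_point),
                 slack_length = slack_length, stiffness = stiffness,
                 toe_strain = toe_strain, prestrain = prestrain)
}

# freeze everything except the named coordinates
freeze_except <- function(model, keep, ...) {
  solver_config(fixed_coords = setdiff(coord_names(model), keep), ...)
}

# Staged brute-force scan of the 1-DOF energy landscape in tibia_df.
# Returns the minimizing angle in radians, refined to `final_step` rad.
grid_search_df <- function(model, driver_er, cfg, lo = -0.3, hi = 0.3,
                           final_step = 1e-8) {
  q <- zero_coords(model)
  energy_at <- function(df) {
    vapply(df, function(a) {
      q[["tibia_df"]] <- a
      total_energy(model, build_state(model, q, driver_er), cfg)
    }, numeric(1))
  }
  step <- (hi - lo) / 400
  centre <- NA_real_
  while (TRUE) {
    grid <- seq(lo, hi, by = step)
    e <- energy_at(grid)
    centre <- grid[which.min(e)]
    if (step <= final_step) break
    lo <- centre - 2 * step
    hi <- centre + 2 * step
    step <- step / 50
  }
  centre
}

# deterministic random coordinates of plausible magnitude
random_coords <- function(model, sd_rot = 0.02, sd_trans = 2e-4) {
  nm <- coord_names(model)
  q <- stats::rnorm(length(nm), sd = sd_rot)
  q[grepl("_t[xyz]$", nm)] <- stats::rnorm(sum(grepl("_t[xyz]$", nm)),
                                           sd = sd_trans)
  stats::setNames(q, nm)
}
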