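#' Construct a passive ankle model
#'
#' An `ankle_model` bundles rigid segments, penalty joints and tension-only
#' ligaments. The canonical PER model has four segments — `tibia`, `fibula`,
#' `talus` and a fixed `hindfoot` unit (all remaining foot bones welded to
#' ground) — three penalty joints (talocrural, subtalar, proximal
#' tibiofibular) and fourteen ligament elements (eleven named bands plus
#' three interosseous-membrane fibers).
#'
#' @param segments tibble/data.frame with columns `name` (chr), `fixed`
#'   (lgl), and optionally list-columns `ref_translation` (3-vectors, m) and
#'   `ref_rotation` (3x3 matrices) giving each segment's reference pose.
#' @param joints tibble with columns `name`, `parent`, `child` (chr),
#'   list-columns `parent_point`, `child_point` (3-vectors, segment-local
#'   metres), and `penalty_stiffness` (N/m).
#' @param ligaments tibble with columns `name`, `origin_segment`,
#'   `insertion_segment`, list-columns `origin_point`, `insertion_point`
#'   (3-vectors, m), and numeric `slack_length` (m), `stiffness` (N at unit
#'   strain on the linear branch), `toe_strain`, `prestrain`.
#' @param metadata named list (model name, seed, provenance ...).
#' @param driver_segment name of the segment whose external-rotation Euler
#'   component is prescribed by the protocol driver (default `"tibia"`).
#' @return an object of class `ankle_model`.
#' @seealso [validate_model()], [generate_anatomy()], [reference_model()]
#' @export
ankle_model <- function(segments, joints, ligaments, metadata = list(),
                        driver_segment = "tibia") {
  segments <- tibble::as_tibble(segments)
  joints <- tibble::as_tibble(joints)
  ligaments <- tibble::as_tibble(ligaments)
  if (!"capsule_stiffness" %in% names(joints)) {
    joints$capsule_stiffness <- replicate(nrow(joints), c(0, 0, 0),
                                          simplify = FALSE)
  } else if (!is.list(joints$capsule_stiffness)) {
    joints$capsule_stiffness <- lapply(joints$capsule_stiffness,
                                       function(x) rep_len(x, 3L))
  }
  if (!"capsule_frame" %in% names(joints)) {
    joints$capsule_frame <- replicate(nrow(joints), diag(3),
                                      simplify = FALSE)
  }
  if (!"ref_translation" %in% names(segments)) {
    segments$ref_translation <- replicate(nrow(segments), c(0, 0, 0),
                                          simplify = FALSE)
  }
  if (!"ref_rotation" %in% names(segments)) {
    segments$ref_rotation <- replicate(nrow(segments), diag(3),
                                       simplify = FALSE)
  }
  model <- structure(
    list(segments = segments, joints = joints, ligaments = ligaments,
         metadata = metadata, driver_segment = driver_segment),
    class = "ankle_model")
  model
}

#' @export
print.ankle_model <- function(x, ...) {
  cat("<ankle_model>", if (!is.null(x$metadata$name)) x$metadata$name else "",
      "\n  segments: ", paste(x$segments$name, collapse = ", "),
      "\n  joints:   ", paste(x$joints$name, collapse = ", "),
      "\n  ligaments:", nrow(x$ligaments), "elements (",
      paste(utils::head(x$ligaments$name, 6), collapse = ", "), "...)\n")
  invisible(x)
}

#' Validate an ankle model definition
#'
#' Reports structural defects: dangling segment references, duplicate names,
#' nonpositive slack lengths or penalty stiffnesses, negative ligament
#' stiffness, out-of-range toe strain or prestrain, and missing fixed
#' segment. Reporting only — never throws.
#'
#' @param model an [ankle_model()].
#' @return a tibble with columns `where`, `name`, `problem`; zero rows for a
#'   valid model.
#' @export
validate_model <- function(model) {
  v <- list()
  bad <- function(where, name, problem) {
    tibble::tibble(where = where, name = name, problem = problem)
  }
  seg <- model$segments
  if (anyDuplicated(seg$name)) {
    v <- c(v, list(bad("segments", seg$name[duplicated(seg$name)][1],
                       "duplicate segment name")))
  }
  if (!any(seg$fixed)) {
    v <- c(v, list(bad("segments", NA_character_, "no fixed segment")))
  }
  if (!model$driver_segment %in% seg$name) {
    v <- c(v, list(bad("segments", model$driver_segment,
                       "driver segment not present")))
  }
  for (i in seq_len(nrow(model$joints))) {
    j <- model$joints[i, ]
    for (s in c(j$parent, j$child)) {
      if (!s %in% seg$name) {
        v <- c(v, list(bad("joints", j$name,
                           paste0("references missing segment '", s, "'"))))
      }
    }
    if (j$parent == j$child) {
      v <- c(v, list(bad("joints", j$name, "parent equals child")))
    }
    if (!is.finite(j$penalty_stiffness) || j$penalty_stiffness <= 0) {
      v <- c(v, list(bad("joints", j$name, "penalty_stiffness must be > 0")))
    }
    cs <- j$capsule_stiffness[[1]]
    if (length(cs) != 3L || any(!is.finite(cs)) || any(cs < 0)) {
      v <- c(v, list(bad("joints", j$name,
                         "capsule_stiffness must be 3 values >= 0")))
    }
    cf <- j$capsule_frame[[1]]
    if (!is.matrix(cf) || any(dim(cf) != 3L) ||
        max(abs(crossprod(cf) - diag(3))) > 1e-6) {
      v <- c(v, list(bad("joints", j$name,
                         "capsule_frame must be a 3x3 orthonormal matrix")))
    }
  }
  if (anyDuplicated(model$ligaments$name)) {
    dup <- model$ligaments$name[duplicated(model$ligaments$name)][1]
    v <- c(v, list(bad("ligaments", dup, "duplicate ligament name")))
  }
  for (i in seq_len(nrow(model$ligaments))) {
    l <- model$ligaments[i, ]
    for (s in c(l$origin_segment, l$insertion_segment)) {
      if (!s %in% seg$name) {
        v <- c(v, list(bad("ligaments", l$name,
                           paste0("references missing segment '", s, "'"))))
      }
    }
    if (!is.finite(l$slack_length) || l$slack_length <= 0) {
      v <- c(v, list(bad("ligaments", l$name, "slack_length must be > 0")))
    }
    if (!is.finite(l$stiffness) || l$stiffness < 0) {
      v <- c(v, list(bad("ligaments", l$name, "stiffness must be >= 0")))
    }
    if (!is.finite(l$toe_strain) || l$toe_strain <= 0) {
      v <- c(v, list(bad("ligaments", l$name, "toe_strain must be > 0")))
    }
    if (!is.finite(l$prestrain) || abs(l$prestrain) >= 0.2) {
      v <- c(v, list(bad("ligaments", l$name, "|prestrain| must be < 0.2")))
    }
  }
  if (length(v) == 0) {
    tibble::tibble(where = character(), name = character(),
                   problem = character())
  } else {
    dplyr::bind_rows(v)
  }
}

assert_valid_model <- function(model) {
  rep <- validate_model(model)
  if (nrow(rep) > 0) {
    stop("invalid model: ", paste(rep$where, rep$name, rep$problem,
                                  sep = " / ", collapse = "; "),
         call. = FALSE)
  }
  invisible(model)
}

#' Read / write an ankle model as JSON
#'
#' The on-disk format is a small JSON dialect: lengths in metres, stiffness
#' in newtons (force at unit strain), penalty stiffness in N/m, angles (in
#' metadata) in degrees. `write_ankle_model()` is deterministic so files
#' round-trip byte-identically.
#'
#' @param path file path.
#' @param model an [ankle_model()].
#' @return `read_ankle_model()` returns an `ankle_model`;
#'   `write_ankle_model()` returns `path` invisibly.
#' @export
read_ankle_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format) || !identical(doc$format, "perankle-model")) {
    stop("not a perankle model document (missing format: perankle-model): ",
         path, call. = FALSE)
  }
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      stop("model document field missing: ", where, "$", field, call. = FALSE)
    }
    x[[field]]
  }
  num3 <- function(x, where) {
    x <- as.numeric(unlist(x))
    if (length(x) != 3L || anyNA(x)) {
      stop("model document field ", where, " is not a numeric 3-vector",
           call. = FALSE)
    }
    x
  }
  segments <- dplyr::bind_rows(lapply(doc$segments, function(s) {
    tibble::tibble(name = need(s, "name", "segments"),
                   fixed = isTRUE(s$fixed))
  }))
  joints <- dplyr::bind_rows(lapply(doc$joints, function(j) {
    tibble::tibble(
      name = need(j, "name", "joints"),
      parent = need(j, "parent", "joints"),
      child = need(j, "child", "joints"),
      parent_point = list(num3(need(j, "parent_point", "joints"),
                               "joints$parent_point")),
      child_point = list(num3(need(j, "child_point", "joints"),
                              "joints$child_point")),
      penalty_stiffness = as.numeric(need(j, "penalty_stiffness", "joints")),
      capsule_stiffness = list(rep_len(as.numeric(unlist(
        j$capsule_stiffness %||% 0)), 3L)),
      capsule_frame = list(if (is.null(j$capsule_frame)) diag(3) else
        matrix(as.numeric(unlist(j$capsule_frame)), 3, 3, byrow = TRUE)))
  }))
  ligaments <- dplyr::bind_rows(lapply(doc$ligaments, function(l) {
    tibble::tibble(
      name = need(l, "name", "ligaments"),
      origin_segment = need(l, "origin_segment", "ligaments"),
      insertion_segment = need(l, "insertion_segment", "ligaments"),
      origin_point = list(num3(need(l, "origin_point", "ligaments"),
                               "ligaments$origin_point")),
      insertion_point = list(num3(need(l, "insertion_point", "ligaments"),
                                  "ligaments$insertion_point")),
      slack_length = as.numeric(need(l, "slack_length", "ligaments")),
      stiffness = as.numeric(need(l, "stiffness", "ligaments")),
      toe_strain = as.numeric(need(l, "toe_strain", "ligaments")),
      prestrain = as.numeric(need(l, "prestrain", "ligaments")))
  }))
  ankle_model(segments, joints, ligaments,
              metadata = doc$metadata %||% list(),
              driver_segment = doc$driver_segment %||% "tibia")
}

#' @rdname read_ankle_model
#' @export
write_ankle_model <- function(model, path) {
  doc <- list(
    format = "perankle-model",
    version = 1L,
    driver_segment = model$driver_segment,
    metadata = model$metadata,
    segments = purrr::pmap(model$segments[, c("name", "fixed")],
                           function(name, fixed) {
                             list(name = name, fixed = fixed)
                           }),
    joints = purrr::pmap(
      model$joints,
      function(name, parent, child, parent_point, child_point,
               penalty_stiffness, capsule_stiffness, capsule_frame, ...) {
        list(name = name, parent = parent, child = child,
             parent_point = round(parent_point, 12),
             child_point = round(child_point, 12),
             penalty_stiffness = penalty_stiffness,
             capsule_stiffness = round(capsule_stiffness, 12),
             capsule_frame = lapply(seq_len(3), function(r) {
               round(capsule_frame[r, ], 12)
             }))
      }),
    ligaments = purrr::pmap(
      model$ligaments,
      function(name, origin_segment, insertion_segment, origin_point,
               insertion_point, slack_length, stiffness, toe_strain,
               prestrain, ...) {
        list(name = name, origin_segment = origin_segment,
             insertion_segment = insertion_segment,
             origin_point = round(origin_point, 12),
             insertion_point = round(insertion_point, 12),
             slack_length = slack_length, stiffness = stiffness,
             toe_strain = toe_strain, prestrain = prestrain)
      }))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
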