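#' Rigid-body pose
#'
#' A pose is a rotation plus a translation mapping segment-local coordinates
#' to the world frame: `world = R %*% local + t`. The world frame is a
#' right-handed right-ankle convention: X anterior, Y superior (tibial long
#' axis), Z lateral, with the hindfoot reference pose at the origin.
#'
#' @param translation numeric length-3, metres.
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @return An object of class `pose`.
#' @export
#' @examples
#' p <- pose(c(0, 0, 0.05))
#' transform_point(p, c(0, 0, 0))
pose <- function(translation = c(0, 0, 0), rotation = diag(3)) {
  translation <- as.numeric(translation)
  rotation <- unname(as.matrix(rotation))
  stopifnot(length(translation) == 3L, all(dim(rotation) == c(3L, 3L)))
  check_rotation(rotation)
  structure(list(t = translation, R = rotation), class = "pose")
}

check_rotation <- function(R, tol = 1e-9) {
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  invisible(R)
}

#' @export
print.pose <- function(x, ...) {
  cat("<pose> t =", format(x$t, digits = 6), "\n")
  print(round(x$R, 9))
  invisible(x)
}

#' Map a segment-local point to the world frame
#'
#' @param pose a [pose()].
#' @param local_point numeric length-3, metres, in the segment frame.
#' @return numeric length-3 world coordinates, metres.
#' @export
transform_point <- function(pose, local_point) {
  stopifnot(inherits(pose, "pose"), length(local_point) == 3L)
  check_rotation(pose$R)
  as.numeric(pose$R %*% as.numeric(local_point) + pose$t)
}

#' Compose and invert poses
#'
#' `pose_compose(a, b)` is the pose that first applies `b`, then `a`
#' (matrix convention: `R = Ra Rb`, `t = Ra tb + ta`).
#'
#' @param a,b poses.
#' @return a `pose`.
#' @export
pose_compose <- function(a, b) {
  pose(as.numeric(a$R %*% b$t + a$t), a$R %*% b$R)
}

#' @rdname pose_compose
#' @export
pose_inverse <- function(a) {
  pose(as.numeric(-crossprod(a$R, a$t)), t(a$R))
}

# elementary rotations (radians), right-handed about the world axes
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Compose a joint rotation from clinical angles
#'
#' Intrinsic Euler sequence used throughout the package: dorsiflexion about
#' the lateral axis Z, then eversion about the anterior axis X, then the
#' joint's external rotation about the long axis Y, i.e.
#' `R = Rz(df) Rx(ev) Ry(er)`. The external-rotation angle is reported in
#' the joint sense (distal side externally rotated under the proximal side):
#' with the foot fixed, a positive angle rotates the tibia internally —
#' anterior tibial landmarks swing medially — which is the same relative
#' motion as external rotation of the foot under the leg.
#'
#' @param dorsiflexion,eversion,external_rotation angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
clinical_rotation <- function(dorsiflexion, eversion, external_rotation) {
  rot_z(deg2rad(dorsiflexion)) %*% rot_x(deg2rad(eversion)) %*%
    rot_y(deg2rad(external_rotation))
}

#' Decompose a relative rotation into clinical angles
#'
#' Inverse of [clinical_rotation()]. Errors near gimbal lock
#' (|eversion| >= 89 degrees) rather than wrapping silently.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric: `dorsiflexion`, `eversion`, `external_rotation`
#'   (degrees).
#' @export
clinical_angles <- function(R) {
  check_rotation(R, tol = 1e-7)
  # R = Rz(a) Rx(b) Ry(c). Expanding Rx(b) Ry(c) and premultiplying by
  # Rz(a) (which leaves the third row untouched):
  #   R[3,1] = -cos b sin c ; R[3,2] = sin b ; R[3,3] = cos b cos c
  #   R[1,2] = -sin a cos b ; R[2,2] = cos a cos b
  sb <- R[3, 2]
  sb <- max(-1, min(1, sb))
  b <- asin(sb)
  if (abs(b) >= deg2rad(89)) {
    stop("eversion within 1 degree of gimbal lock; decomposition unreliable",
         call. = FALSE)
  }
  a <- atan2(-R[1, 2], R[2, 2])
  c <- atan2(-R[3, 1], R[3, 3])
  c(dorsiflexion = rad2deg(a), eversion = rad2deg(b),
    external_rotation = rad2deg(c))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
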