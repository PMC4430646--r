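#' Planar rigid transforms
#'
#' A `tf2d` is a proper planar rigid transform (rotation followed by
#' translation): `p' = R(theta) p + t`. It is the currency of the
#' calibration and tracking stages, where it expresses changes of
#' coordinates between the image (CS_I), technical (CS_T) and anatomical
#' (CS_A) frames of each body segment.
#'
#' @param theta_deg rotation angle in degrees, counterclockwise positive
#'   (y-up convention).
#' @param tx,ty translation components in pixels.
#' @return An object of class `tf2d` with fields `theta_deg`, `tx`, `ty`.
#' @examples
#' T <- tf2d(10, 5, -3)
#' p <- tf2d_apply(T, c(1, 0))
#' tf2d_apply(tf2d_inverse(T), p)  # back to (1, 0)
#' @export
tf2d <- function(theta_deg = 0, tx = 0, ty = 0) {
  stopifnot(length(theta_deg) == 1, is.finite(theta_deg),
            length(tx) == 1, is.finite(tx),
            length(ty) == 1, is.finite(ty))
  structure(list(theta_deg = unname(theta_deg), tx = unname(tx),
                 ty = unname(ty)), class = "tf2d")
}

#' @export
print.tf2d <- function(x, ...) {
  cat(sprintf("<tf2d> theta = %.4f deg, t = (%.3f, %.3f)\n",
              x$theta_deg, x$tx, x$ty))
  invisible(x)
}

#' Rotation matrix of a transform
#'
#' @param tf a [tf2d()].
#' @return 2x2 rotation matrix (orthonormal, determinant +1).
#' @export
tf2d_rotation <- function(tf) {
  a <- tf$theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Homogeneous 3x3 matrix of a transform
#' @param tf a [tf2d()].
#' @return 3x3 homogeneous matrix.
#' @export
tf2d_matrix <- function(tf) {
  m <- diag(3)
  m[1:2, 1:2] <- tf2d_rotation(tf)
  m[1:2, 3] <- c(tf$tx, tf$ty)
  m
}

#' Apply a transform to points
#'
#' @param tf a [tf2d()].
#' @param pts numeric vector `c(x, y)` or an n x 2 matrix of points.
#' @return transformed points, same shape as input.
#' @export
tf2d_apply <- function(tf, pts) {
  R <- tf2d_rotation(tf)
  if (is.matrix(pts)) {
    out <- pts %*% t(R)
    out[, 1] <- out[, 1] + tf$tx
    out[, 2] <- out[, 2] + tf$ty
    out
  } else {
    as.vector(R %*% pts) + c(tf$tx, tf$ty)
  }
}

#' Compose two transforms
#'
#' `tf2d_compose(A, B)` returns the transform that first applies `B`, then
#' `A` (matrix product `A %*% B` in homogeneous form). This mirrors the
#' frame-change chaining used for the anatomical transforms, e.g.
#' `T[CS_A -> CS_I] = compose(T[CS_T -> CS_I], T[CS_A -> CS_T])`.
#'
#' @param a,b [tf2d()] objects.
#' @return a [tf2d()].
#' @export
tf2d_compose <- function(a, b) {
  Ra <- tf2d_rotation(a)
  t_new <- as.vector(Ra %*% c(b$tx, b$ty)) + c(a$tx, a$ty)
  tf2d(a$theta_deg + b$theta_deg, t_new[1], t_new[2])
}

#' Invert a transform
#' @param tf a [tf2d()].
#' @return the inverse [tf2d()], with `compose(tf, inverse(tf))` identity.
#' @export
tf2d_inverse <- function(tf) {
  R <- tf2d_rotation(tf)
  t_inv <- -as.vector(t(R) %*% c(tf$tx, tf$ty))
  tf2d(-tf$theta_deg, t_inv[1], t_inv[2])
}

#' Linear interpolation between two transforms
#'
#' Used to bridge tracking gaps: rotation angle and translation are
#' interpolated componentwise.
#'
#' @param a,b [tf2d()] endpoints.
#' @param w weight in `[0, 1]`; 0 gives `a`, 1 gives `b`.
#' @return a [tf2d()].
#' @export
tf2d_interpolate <- function(a, b, w) {
  tf2d(a$theta_deg + w * (b$theta_deg - a$theta_deg),
       a$tx + w * (b$tx - a$tx),
       a$ty + w * (b$ty - a$ty))
}
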