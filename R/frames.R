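#' Rigid-body frames
#'
#' A frame is a rigid transform: a 3x3 rotation matrix `R` (orthonormal,
#' det = +1) and a 3-vector translation `p` in metres. Frames compose as
#' `parent %then% child`: first apply the child transform in the parent's
#' coordinates.
#'
#' @param R 3x3 rotation matrix.
#' @param p length-3 translation (m).
#' @return An object of class `frame`.
#' @export
frame <- function(R = diag(3), p = c(0, 0, 0)) {
  R <- as.matrix(R)
  p <- as.numeric(p)
  stopifnot(identical(dim(R), c(3L, 3L)), length(p) == 3L)
  structure(list(R = R, p = p), class = "frame")
}

#' @rdname frame
#' @export
frame_identity <- function() frame()

#' Compose two frames
#'
#' @param f,g frames; `g` is expressed in `f`'s coordinates.
#' @return The composed frame mapping `g`-local coordinates to the frame
#'   `f` is expressed in.
#' @export
frame_compose <- function(f, g) {
  frame(f$R %*% g$R, as.numeric(f$p + f$R %*% g$p))
}

#' Apply a frame to points
#'
#' @param f a frame.
#' @param pts a 3-vector or an n x 3 matrix of local points.
#' @return Transformed point(s), same shape as the input.
#' @export
frame_apply <- function(f, pts) {
  if (is.matrix(pts)) {
    t(f$R %*% t(pts) + f$p)
  } else {
    as.numeric(f$R %*% pts + f$p)
  }
}

#' Rotation about an axis (Rodrigues formula)
#'
#' @param axis unit 3-vector.
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Axis-angle logarithm of a rotation matrix
#'
#' Returns the rotation vector (axis times angle, radians) of `R`. Used by
#' orientation-matching routines.
#'
#' @param R 3x3 rotation matrix.
#' @return length-3 rotation vector.
#' @export
rot_log <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  ang <- acos(ca)
  if (ang < 1e-12) return(c(0, 0, 0))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (abs(pi - ang) < 1e-6) {
    # near pi the skew part degenerates; fall back to the symmetric part
    A <- (R + diag(3)) / 2
    u <- sqrt(pmax(diag(A), 0))
    i <- which.max(u)
    u <- A[, i] / u[i]
    return(ang * u / sqrt(sum(u^2)))
  }
  ang * w / (2 * sin(ang))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalised")
  v / n
}
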