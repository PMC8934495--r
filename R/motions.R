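#' Motion specification
#'
#' The four studied arm motions. Abduction (`ABD`) and scaption (`SCP`)
#' elevate the arm from 0 to 120 degrees of humero-thoracic elevation, in
#' the coronal plane and in the scapular plane (30 degrees anterior to
#' coronal) respectively. Internal rotation (`IR`) rotates the humerus about
#' its long axis from 0 to 40 degrees; external rotation (`ER`) runs from 40
#' back to 0 degrees of external rotation by default (the source protocol
#' states both directions in different places; `er_reversed = FALSE` runs 0
#' to 40 instead). Axial rotations are performed at a small constant
#' elevation (the arm held just off the trunk) with the palm facing
#' posterior at the start.
#'
#' @param name one of `"ABD"`, `"SCP"`, `"IR"`, `"ER"`.
#' @param n_steps number of time samples (>= 2), default 25.
#' @param duration nominal capture duration (s) before time stretching,
#'   default 2.
#' @param rotation_elevation_deg elevation at which IR/ER are performed
#'   (degrees), default 15.
#' @param er_reversed logical; `TRUE` (default) runs ER from 40 to 0 degrees.
#' @param elbow_flexion_deg fixed elbow flexion the motion is performed
#'   with: 0 (straight arm) for the elevation motions, 90 for the
#'   axial-rotation motions (clinical rotation posture).
#' @return A `motion_spec` object.
#' @export
motion_spec <- function(name, n_steps = 25, duration = 2,
                        rotation_elevation_deg = 15, er_reversed = TRUE,
                        elbow_flexion_deg = NULL) {
  name <- match.arg(name, c("ABD", "SCP", "IR", "ER"))
  stopifnot(n_steps >= 2, duration > 0)
  if (is.null(elbow_flexion_deg)) {
    elbow_flexion_deg <- if (name %in% c("IR", "ER")) 90 else 0
  }
  rng <- switch(name,
                ABD = c(0, 120), SCP = c(0, 120), IR = c(0, 40),
                ER = if (er_reversed) c(40, 0) else c(0, 40))
  structure(list(name = name, angle_start = rng[1], angle_end = rng[2],
                 n_steps = as.integer(n_steps), duration = duration,
                 rotation_elevation_deg = rotation_elevation_deg,
                 elbow_flexion_deg = elbow_flexion_deg),
            class = "motion_spec")
}

# minimum-jerk profile: s(0)=0, s(1)=1, zero endpoint velocity/acceleration
min_jerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

# simplified scapulo-humeral rhythm: above 30 degrees of humero-thoracic
# elevation the scapula contributes 1 degree of upward rotation for every
# 2 degrees at the gleno-humeral joint (total split 2:1)
scapular_rhythm <- function(elev_ht_deg) pmax(0, (elev_ht_deg - 30) / 3)

# gleno-humeral rotation matrix for plane-of-elevation / elevation / axial
# angles (degrees), in the Y-X-Y intrinsic convention used by the ball
# variants
gh_rotation <- function(plane_deg, elev_deg, axial_deg) {
  rot_axis_angle(c(0, 1, 0), deg2rad(plane_deg)) %*%
    rot_axis_angle(c(-1, 0, 0), deg2rad(elev_deg)) %*%
    rot_axis_angle(c(0, 1, 0), deg2rad(axial_deg))
}

#' Solve gleno-humeral coordinates for a target humeral orientation
#'
#' Gauss-Newton on the model's gleno-humeral DOFs, minimising the rotation
#' log of the mismatch between the humerus world rotation and the target.
#' Used to drive the dual-bearing joint assembly (hinge + gimbal) through
#' the same humeral motions as the ball-joint variants.
#'
#' @param model a `shoulder_model` with `gh_dofs` set.
#' @param R_target 3x3 target world rotation of the humerus.
#' @param q_base full configuration supplying the non-GH coordinates and the
#'   warm start for the GH coordinates.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   rotation mismatch (rad).
#' @return Numeric vector of GH coordinate values (radians).
#' @export
match_gh_orientation <- function(model, R_target, q_base,
                                 max_iter = 60, tol = 1e-12) {
  idx <- model$gh_dofs
  q <- q_base
  err <- function(qv) {
    fk <- forward_kinematics(model, qv)
    rot_log(t(fk$frames[["humerus"]]$R) %*% R_target)
  }
  for (it in seq_len(max_iter)) {
    e <- err(q)
    if (sqrt(sum(e^2)) < tol) break
    J <- matrix(0, 3, length(idx))
    h <- 1e-6
    for (k in seq_along(idx)) {
      qp <- q; qp[idx[k]] <- qp[idx[k]] + h
      J[, k] <- (err(qp) - e) / h
    }
    step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(length(idx)),
                           -crossprod(J, e)),
                     error = function(err2) rep(0, length(idx)))
    q[idx] <- q[idx] + drop(step)
    if (max(abs(step)) < 1e-14) break
  }
  q[idx]
}

# GH dof values realising the given anatomical angles on any variant
gh_angles_to_q <- function(model, plane_deg, elev_deg, axial_deg, q_base) {
  if (model$joints[[model$dof_joint[model$gh_dofs[1]]]]$kind == "ball") {
    deg2rad(c(plane_deg, elev_deg, axial_deg))
  } else {
    scap <- if (length(model$scap_dof)) q_base[model$scap_dof] else 0
    R_t <- rot_axis_angle(c(-1, 0, 0), scap) %*%
      gh_rotation(plane_deg, elev_deg, axial_deg)
    match_gh_orientation(model, R_t, q_base)
  }
}

#' Generate a joint-coordinate trajectory for a named motion
#'
#' Produces a smooth minimum-jerk time series of model configurations
#' realising the requested motion: elevation motions split the
#' humero-thoracic angle between the gleno-humeral joint and the scapular
#' upward-rotation hinge by the simplified 2:1 scapulo-humeral rhythm
#' (engaging above 30 degrees); axial rotations hold a small constant
#' elevation. Endpoint derivatives of the profile are zero (quasi-static
#' start and stop).
#'
#' @param model a `shoulder_model` built by [build_shoulder_model()].
#' @param spec a [motion_spec()] (or a motion name, converted with
#'   defaults).
#' @return A `motion_trajectory`: list with `time` (s), `Q` (n x DOF matrix,
#'   radians), `angle_deg` (the driven anatomical angle per frame), `spec`.
#' @export
generate_trajectory <- function(model, spec) {
  if (is.character(spec)) spec <- motion_spec(spec)
  n <- spec$n_steps
  time <- seq(0, spec$duration, length.out = n)
  ang <- spec$angle_start +
    (spec$angle_end - spec$angle_start) * min_jerk(seq(0, 1, length.out = n))
  Q <- matrix(0, n, model$ndof, dimnames = list(NULL, model$dof_names))
  plane <- switch(spec$name, ABD = 0, SCP = 30, IR = 0, ER = 0)
  q_prev <- numeric(model$ndof)
  for (i in seq_len(n)) {
    if (spec$name %in% c("ABD", "SCP")) {
      scap <- scapular_rhythm(ang[i])
      elev <- ang[i] - scap
      axial <- 0
    } else {
      scap <- scapular_rhythm(spec$rotation_elevation_deg)
      elev <- spec$rotation_elevation_deg - scap
      axial <- if (spec$name == "IR") ang[i] else -ang[i]
    }
    q <- q_prev
    q[model$scap_dof] <- deg2rad(scap)
    q[model$gh_dofs] <- gh_angles_to_q(model, plane, elev, axial, q)
    Q[i, ] <- q
    q_prev <- q
  }
  structure(list(time = time, Q = Q, angle_deg = ang, spec = spec),
            class = "motion_trajectory")
}

#' Default anatomical marker set
#'
#' Nine synthetic surface markers (three per segment on thorax, scapula and
#' humerus), emulating an anatomical-landmark motion-capture marker
#' protocol.
#'
#' @return List of `list(name, body, point)` marker definitions.
#' @export
default_marker_set <- function() {
  list(
    list(name = "STRN", body = "thorax", point = c(0.05, 0.35, 0.00)),
    list(name = "C7", body = "thorax", point = c(-0.06, 0.45, 0.00)),
    list(name = "XIPH", body = "thorax", point = c(0.06, 0.15, 0.00)),
    list(name = "ACRO", body = "scapula", point = c(0.000, 0.010, 0.030)),
    list(name = "SPIN", body = "scapula", point = c(-0.080, -0.010, -0.030)),
    list(name = "INFA", body = "scapula", point = c(-0.050, -0.120, -0.030)),
    list(name = "HLAT", body = "humerus", point = c(0.000, -0.280, 0.030)),
    list(name = "HMED", body = "humerus", point = c(0.000, -0.280, -0.030)),
    list(name = "HMID", body = "humerus", point = c(0.025, -0.150, 0.000)))
}

#' Synthesize marker-capture data from a trajectory
#'
#' World marker positions from forward kinematics plus i.i.d. Gaussian
#' capture noise per axis. Deterministic for a given seed.
#'
#' @param model a `shoulder_model`.
#' @param trajectory a `motion_trajectory` (or a list with `time` and `Q`).
#' @param markers marker definitions, default [default_marker_set()].
#' @param noise_sd marker noise standard deviation per axis (m), >= 0.
#' @param seed RNG seed.
#' @param rate nominal capture rate (Hz), default 100 (metadata only; the
#'   sample times come from the trajectory).
#' @return A `marker_set`: list with `markers`, `time`, `rate` and `traj`,
#'   an `n x 3 x n_markers` array of world positions (m).
#' @export
synthesize_markers <- function(model, trajectory, markers = default_marker_set(),
                               noise_sd = 0, seed = 42, rate = 100) {
  stopifnot(noise_sd >= 0)
  n <- nrow(trajectory$Q)
  arr <- array(NA_real_, c(n, 3, length(markers)),
               dimnames = list(NULL, c("x", "y", "z"),
                               vapply(markers, `[[`, "", "name")))
  for (i in seq_len(n)) {
    fk <- forward_kinematics(model, trajectory$Q[i, ])
    for (m in seq_along(markers)) {
      arr[i, , m] <- frame_apply(fk$frames[[markers[[m]]$body]],
                                 markers[[m]]$point)
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
  }
  structure(list(markers = markers, time = trajectory$time, rate = rate,
                 traj = arr), class = "marker_set")
}

#' Marker-based inverse kinematics
#'
#' Per-frame nonlinear least squares (Gauss-Newton on the analytic point
#' Jacobian) minimising the sum of squared distances between observed and
#' model marker positions, warm-started from the previous frame. No temporal
#' smoothing is applied (the quasi-static treatment stretches time instead
#' of filtering).
#'
#' @param model a `shoulder_model`.
#' @param markerset a `marker_set`.
#' @param q0 initial configuration for the first frame (default zeros).
#' @param max_iter Gauss-Newton iteration cap per frame (default 100).
#' @param tol convergence tolerance on the coordinate step (rad).
#' @return List with `Q` (n x DOF, radians), `rms` (per-frame RMS marker
#'   residual, m) and `converged` (logical per frame).
#' @export
inverse_kinematics <- function(model, markerset, q0 = NULL, max_iter = 100,
                               tol = 1e-12) {
  mk <- markerset$markers
  moving <- vapply(mk, function(m) length(model$body_dofs[[m$body]]) > 0, TRUE)
  if (sum(moving) < 3) stop("need at least 3 markers on the moving subtree")
  n <- dim(markerset$traj)[1]
  Q <- matrix(0, n, model$ndof, dimnames = list(NULL, model$dof_names))
  rms <- numeric(n)
  converged <- logical(n)
  q <- if (is.null(q0)) numeric(model$ndof) else q0
  for (i in seq_len(n)) {
    for (it in seq_len(max_iter)) {
      fk <- forward_kinematics(model, q)
      r <- numeric(0)
      J <- matrix(0, 0, model$ndof)
      for (m in seq_along(mk)) {
        p <- frame_apply(fk$frames[[mk[[m]]$body]], mk[[m]]$point)
        r <- c(r, markerset$traj[i, , m] - p)
        J <- rbind(J, point_jacobian(model, q, mk[[m]]$body, mk[[m]]$point,
                                     fk = fk))
      }
      step <- tryCatch(
        drop(solve(crossprod(J) + 1e-10 * diag(model$ndof), crossprod(J, r))),
        error = function(e) rep(0, model$ndof))
      q <- q + step
      if (max(abs(step)) < tol) { converged[i] <- TRUE; break }
    }
    fk <- forward_kinematics(model, q)
    res <- vapply(seq_along(mk), function(m) {
      p <- frame_apply(fk$frames[[mk[[m]]$body]], mk[[m]]$point)
      sum((markerset$traj[i, , m] - p)^2)
    }, 0)
    rms[i] <- sqrt(sum(res) / (3 * length(mk)))
    Q[i, ] <- q
  }
  list(Q = Q, rms = rms, converged = converged)
}

#' Stretch the time scale of a series
#'
#' Multiplies the timestamps by `factor`, leaving sample values untouched;
#' implied velocities and accelerations scale by `1/factor` and
#' `1/factor^2`. Stretching by 1000 turns a noisy capture timeline into a
#' quasi-static one without filtering the data.
#'
#' @param series any list with a numeric `time` element (e.g. a
#'   `motion_trajectory` or `marker_set`).
#' @param factor positive stretch factor, default 1000.
#' @return The series with stretched timestamps.
#' @export
time_stretch <- function(series, factor = 1000) {
  stopifnot(factor > 0)
  series$time <- series$time * factor
  series
}

#' Peak implied angular acceleration of a coordinate series
#'
#' Maximum absolute second finite difference of any coordinate with respect
#' to the series timestamps (rad/s^2). Used as a quasi-static acceptance
#' check: after stretching time by 1000 the implied accelerations drop by
#' 1e6.
#'
#' @param series list with `time` (s) and `Q` (n x DOF, radians).
#' @return Peak |d2q/dt2| (rad/s^2); 0 for fewer than 3 frames.
#' @export
peak_angular_acceleration <- function(series) {
  n <- nrow(series$Q)
  if (n < 3) return(0)
  dt <- diff(series$time)
  acc <- 0
  for (i in 2:(n - 1)) {
    v1 <- (series$Q[i, ] - series$Q[i - 1, ]) / dt[i - 1]
    v2 <- (series$Q[i + 1, ] - series$Q[i, ]) / dt[i]
    acc <- max(acc, max(abs((v2 - v1) / ((dt[i - 1] + dt[i]) / 2))))
  }
  acc
}
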