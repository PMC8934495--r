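#' Body segments and joints of a rigid kinematic chain
#'
#' `body_segment()` describes one rigid part: its mass, centre of mass in the
#' body frame, and optional attached point loads (e.g. a hand-held weight,
#' modelled as a point mass rigidly fixed to the segment).
#'
#' @param name identifier.
#' @param mass segment mass (kg), >= 0.
#' @param com centre of mass, body-frame coordinates (m).
#' @param point_loads list of `list(point = c(x,y,z), mass = kg)` entries.
#' @return A `body_segment` object.
#' @export
body_segment <- function(name, mass = 0, com = c(0, 0, 0), point_loads = list()) {
  stopifnot(is.character(name), length(name) == 1L, mass >= 0)
  for (pl in point_loads) {
    stopifnot(length(pl$point) == 3L, pl$mass >= 0)
  }
  structure(list(name = name, mass = mass, com = as.numeric(com),
                 point_loads = point_loads),
            class = "body_segment")
}

#' @rdname body_segment
#'
#' @details
#' `joint_spec()` declares the connection between a parent and a child body.
#' Supported kinds and rotational degrees of freedom: `fixed` (0), `hinge`
#' (1), `gimbal` (2 ordered intrinsic rotations) and `ball` (3 ordered
#' intrinsic rotations). `axes` holds one unit 3-vector per DOF, expressed in
#' the joint frame; rotations are applied in order about the current
#' (intrinsic) axes. `limits`, if given, is a 2-column matrix of per-DOF
#' coordinate ranges in radians.
#'
#' @param kind one of `"fixed"`, `"hinge"`, `"gimbal"`, `"ball"`.
#' @param parent,child body names.
#' @param parent_offset,child_offset static frames placing the joint in the
#'   parent body and the child body in the joint frame.
#' @param axes list of unit 3-vectors, one per rotational DOF.
#' @param limits optional DOF x 2 matrix of coordinate ranges (rad).
#' @export
joint_spec <- function(name, kind, parent, child,
                       parent_offset = frame_identity(),
                       child_offset = frame_identity(),
                       axes = list(), limits = NULL) {
  kind <- match.arg(kind, c("fixed", "hinge", "gimbal", "ball"))
  ndof <- joint_dof_count(kind)
  if (length(axes) != ndof) {
    stop(sprintf("joint '%s' (%s) expects %d axis vector(s), got %d",
                 name, kind, ndof, length(axes)))
  }
  axes <- lapply(axes, function(a) {
    a <- as.numeric(a)
    stopifnot(length(a) == 3L)
    n <- sqrt(sum(a^2))
    if (abs(n - 1) > 1e-8) stop(sprintf("joint '%s': axis must have unit norm", name))
    a / n
  })
  if (!is.null(limits)) {
    limits <- matrix(as.numeric(limits), ncol = 2)
    stopifnot(nrow(limits) == ndof)
  }
  structure(list(name = name, kind = kind, parent = parent, child = child,
                 parent_offset = parent_offset, child_offset = child_offset,
                 axes = axes, limits = limits),
            class = "joint_spec")
}

#' Degrees of freedom of a joint kind
#'
#' @param kind joint kind string.
#' @return Integer DOF count: fixed 0, hinge 1, gimbal 2, ball 3.
#' @export
joint_dof_count <- function(kind) {
  switch(kind, fixed = 0L, hinge = 1L, gimbal = 2L, ball = 3L,
         stop("unknown joint kind: ", kind))
}

#' Assemble a kinematic chain model
#'
#' Builds the full model used by the simulator: rigid bodies connected by a
#' joint tree rooted at the body that no joint lists as a child (normally the
#' thorax), plus muscle elements and wrapping surfaces. Generalized
#' coordinates `q` are ordered by a parent-first traversal of the joint tree,
#' with each multi-DOF joint contributing its coordinates in axis order.
#'
#' @param bodies list of [body_segment()] objects.
#' @param joints list of [joint_spec()] objects forming a tree.
#' @param muscles list of [muscle_element()] objects.
#' @param wraps list of [wrap_surface()] objects.
#' @param gravity gravity vector (m/s^2); default `c(0, -9.81, 0)` (y up).
#' @param gh_joint name of the joint across which the gleno-humeral joint
#'   reaction force is reported (for the dual-bearing prosthesis this is the
#'   scapula-ring fixed joint).
#' @param variant free-form tag (`"NS"`, `"RSP"`, `"DBSP"`, ...).
#' @return A `shoulder_model` object.
#' @export
chain_model <- function(bodies, joints, muscles = list(), wraps = list(),
                        gravity = c(0, -9.81, 0), gh_joint = NULL,
                        variant = "custom") {
  body_names <- vapply(bodies, `[[`, "", "name")
  if (anyDuplicated(body_names)) stop("duplicate body names")
  names(bodies) <- body_names

  joint_names <- vapply(joints, `[[`, "", "name")
  if (anyDuplicated(joint_names)) stop("duplicate joint names")
  names(joints) <- joint_names

  children <- vapply(joints, `[[`, "", "child")
  parents <- vapply(joints, `[[`, "", "parent")
  if (!all(children %in% body_names) || !all(parents %in% body_names)) {
    stop("joint references a body that does not exist")
  }
  if (anyDuplicated(children)) {
    stop("joint graph is not a tree: body '",
         children[duplicated(children)][1], "' has more than one parent joint")
  }
  roots <- setdiff(body_names, children)
  if (length(roots) != 1L) {
    stop("joint graph must have exactly one root body, found: ",
         paste(roots, collapse = ", "))
  }

  # topological order, parent before child
  ordered <- character(0)
  placed <- roots
  remaining <- joints
  while (length(remaining) > 0) {
    ready <- vapply(remaining, function(j) j$parent %in% placed, TRUE)
    if (!any(ready)) stop("joint graph is disconnected or cyclic")
    for (j in remaining[ready]) {
      ordered <- c(ordered, j$name)
      placed <- c(placed, j$child)
    }
    remaining <- remaining[!ready]
  }
  joints <- joints[ordered]

  # q layout
  dof_joint <- integer(0)  # joint index per dof
  dof_axis <- integer(0)   # axis index within joint per dof
  dof_names <- character(0)
  for (ji in seq_along(joints)) {
    nd <- joint_dof_count(joints[[ji]]$kind)
    if (nd > 0) {
      dof_joint <- c(dof_joint, rep(ji, nd))
      dof_axis <- c(dof_axis, seq_len(nd))
      dof_names <- c(dof_names, paste0(joints[[ji]]$name,
                                       if (nd > 1) paste0("_", seq_len(nd)) else ""))
    }
  }

  # ancestor DOFs per body
  body_dofs <- stats::setNames(vector("list", length(bodies)), body_names)
  body_dofs[[roots]] <- integer(0)
  for (ji in seq_along(joints)) {
    j <- joints[[ji]]
    own <- which(dof_joint == ji)
    body_dofs[[j$child]] <- c(body_dofs[[j$parent]], own)
  }

  model <- structure(list(
    bodies = bodies, joints = joints, muscles = muscles, wraps = wraps,
    gravity = as.numeric(gravity), gh_joint = gh_joint, variant = variant,
    root = roots, ndof = length(dof_joint),
    dof_joint = dof_joint, dof_axis = dof_axis, dof_names = dof_names,
    body_dofs = body_dofs), class = "shoulder_model")

  # referential integrity for muscles and wraps
  wrap_names <- vapply(wraps, `[[`, "", "name")
  names(model$wraps) <- wrap_names
  for (m in muscles) {
    for (pt in m$path$points) {
      if (!pt$body %in% body_names)
        stop("muscle '", m$name, "' references unknown body '", pt$body, "'")
    }
    if (!all(m$path$wraps %in% wrap_names))
      stop("muscle '", m$name, "' references an unknown wrap surface")
  }
  for (w in wraps) {
    if (!w$body %in% body_names)
      stop("wrap '", w$name, "' references unknown body '", w$body, "'")
  }
  names(model$muscles) <- vapply(muscles, `[[`, "", "name")
  model
}

#' @export
print.shoulder_model <- function(x, ...) {
  cat(sprintf("<shoulder_model> variant %s: %d bodies, %d joints (%d DOF), %d muscle elements, %d wrap surfaces\n",
              x$variant, length(x$bodies), length(x$joints), x$ndof,
              length(x$muscles), length(x$wraps)))
  invisible(x)
}

#' @export
summary.shoulder_model <- function(object, ...) {
  jt <- data.frame(
    joint = vapply(object$joints, `[[`, "", "name"),
    kind = vapply(object$joints, `[[`, "", "kind"),
    parent = vapply(object$joints, `[[`, "", "parent"),
    child = vapply(object$joints, `[[`, "", "child"),
    dof = vapply(object$joints, function(j) joint_dof_count(j$kind), 0L),
    row.names = NULL)
  grp <- table(vapply(object$muscles, `[[`, "", "group"))
  out <- list(variant = object$variant, joints = jt,
              muscle_elements = grp, ndof = object$ndof)
  class(out) <- "summary.shoulder_model"
  out
}

#' @export
print.summary.shoulder_model <- function(x, ...) {
  cat("Shoulder model variant:", x$variant, "-", x$ndof, "DOF\n\nJoints:\n")
  print(x$joints)
  cat("\nMuscle elements per group:\n")
  print(x$muscle_elements)
  invisible(x)
}

#' Check a configuration vector against a model
#'
#' Verifies the coordinate vector length and any declared joint coordinate
#' limits.
#'
#' @param model a `shoulder_model`.
#' @param q numeric coordinate vector (radians).
#' @return `q`, invisibly; errors on violation.
#' @export
check_configuration <- function(model, q) {
  if (length(q) != model$ndof) {
    stop(sprintf("configuration has %d coordinates but model '%s' has %d DOF (%s)",
                 length(q), model$variant, model$ndof,
                 paste(model$dof_names, collapse = ", ")))
  }
  for (k in seq_along(q)) {
    j <- model$joints[[model$dof_joint[k]]]
    if (!is.null(j$limits)) {
      lim <- j$limits[model$dof_axis[k], ]
      if (q[k] < lim[1] - 1e-9 || q[k] > lim[2] + 1e-9) {
        stop(sprintf("coordinate %s = %.4f rad outside joint limits [%.4f, %.4f]",
                     model$dof_names[k], q[k], lim[1], lim[2]))
      }
    }
  }
  invisible(q)
}

#' Forward kinematics
#'
#' Computes the world frame of every body at configuration `q`, along with
#' the world axis and centre of every rotational DOF (used for analytic point
#' Jacobians). The root body frame is the identity. Fixed joints transmit
#' their static offsets unchanged; hinge/gimbal/ball joints apply their 1/2/3
#' ordered intrinsic axis rotations.
#'
#' @param model a `shoulder_model`.
#' @param q coordinate vector (radians), length `model$ndof`.
#' @return A list with `frames` (named list of [frame()] per body),
#'   `dof_axis_world` (3 x ndof matrix of world rotation axes), and
#'   `dof_center_world` (3 x ndof matrix of world joint centres).
#' @export
forward_kinematics <- function(model, q) {
  check_configuration(model, q)
  frames <- stats::setNames(vector("list", length(model$bodies)),
                            names(model$bodies))
  frames[[model$root]] <- frame_identity()
  u_w <- matrix(0, 3, max(1, model$ndof))
  c_w <- matrix(0, 3, max(1, model$ndof))
  for (ji in seq_along(model$joints)) {
    j <- model$joints[[ji]]
    f <- frame_compose(frames[[j$parent]], j$parent_offset)
    own <- which(model$dof_joint == ji)
    # gimbal singularity advisory: the two rotated axes nearly parallel
    for (k in seq_along(own)) {
      ax <- j$axes[[k]]
      u_w[, own[k]] <- as.numeric(f$R %*% ax)
      c_w[, own[k]] <- f$p
      f <- frame_compose(f, frame(rot_axis_angle(ax, q[own[k]])))
    }
    if (j$kind == "gimbal") {
      a1 <- as.numeric(u_w[, own[1]])
      a2 <- as.numeric(u_w[, own[2]])
      if (abs(sum(a1 * a2)) > 1 - 1e-6) {
        warning(sprintf("gimbal joint '%s' near singular alignment", j$name))
      }
    }
    frames[[j$child]] <- frame_compose(f, j$child_offset)
  }
  list(frames = frames, dof_axis_world = u_w, dof_center_world = c_w)
}

#' Point Jacobian
#'
#' Partial derivatives of the world position of a body-fixed point with
#' respect to every generalized coordinate (m/rad). Column `j` is
#' `u_j x (p - c_j)` for ancestor DOFs of the body and zero otherwise.
#'
#' @param model a `shoulder_model`.
#' @param q configuration (radians).
#' @param body body name.
#' @param point_local point in body coordinates (m).
#' @param fk optional precomputed [forward_kinematics()] result.
#' @return 3 x DOF matrix.
#' @export
point_jacobian <- function(model, q, body, point_local, fk = NULL) {
  if (!body %in% names(model$bodies)) stop("unknown body: ", body)
  if (is.null(fk)) fk <- forward_kinematics(model, q)
  p <- frame_apply(fk$frames[[body]], point_local)
  J <- matrix(0, 3, model$ndof)
  for (k in model$body_dofs[[body]]) {
    u <- fk$dof_axis_world[, k]
    r <- p - fk$dof_center_world[, k]
    J[, k] <- c(u[2] * r[3] - u[3] * r[2],
                u[3] * r[1] - u[1] * r[3],
                u[1] * r[2] - u[2] * r[1])
  }
  J
}

#' Generalized gravity torques
#'
#' Quasi-static generalized forces produced by segment weights and attached
#' point loads: `tau[j] = sum_i J_i[,j] . (m_i g)` over all segment centres
#' of mass and point loads. No velocity or acceleration terms.
#'
#' @param model a `shoulder_model`.
#' @param q configuration (radians).
#' @param fk optional precomputed forward kinematics.
#' @return Numeric vector of length DOF (N m).
#' @export
gravity_load_torques <- function(model, q, fk = NULL) {
  if (is.null(fk)) fk <- forward_kinematics(model, q)
  tau <- numeric(model$ndof)
  g <- model$gravity
  for (b in model$bodies) {
    pts <- list()
    if (b$mass > 0) pts[[length(pts) + 1]] <- list(point = b$com, mass = b$mass)
    for (pl in b$point_loads) if (pl$mass > 0) pts[[length(pts) + 1]] <- pl
    if (length(pts) == 0) next
    dofs <- model$body_dofs[[b$name]]
    if (length(dofs) == 0) next
    for (pt in pts) {
      p <- frame_apply(fk$frames[[b$name]], pt$point)
      fg <- pt$mass * g
      for (k in dofs) {
        u <- fk$dof_axis_world[, k]
        r <- p - fk$dof_center_world[, k]
        tau[k] <- tau[k] + sum((c(u[2] * r[3] - u[3] * r[2],
                                  u[3] * r[1] - u[1] * r[3],
                                  u[1] * r[2] - u[2] * r[1])) * fg)
      }
    }
  }
  tau
}

#' Total potential energy of the model (J)
#'
#' Convenience for verifying gravity torques: `gravity_load_torques()` equals
#' `-dV/dq` by the principle of virtual work.
#'
#' @inheritParams gravity_load_torques
#' @return Scalar potential energy (J), with the zero level at the world
#'   origin.
#' @export
potential_energy <- function(model, q, fk = NULL) {
  if (is.null(fk)) fk <- forward_kinematics(model, q)
  g <- model$gravity
  V <- 0
  for (b in model$bodies) {
    if (b$mass > 0) {
      p <- frame_apply(fk$frames[[b$name]], b$com)
      V <- V - b$mass * sum(g * p)
    }
    for (pl in b$point_loads) {
      p <- frame_apply(fk$frames[[b$name]], pl$point)
      V <- V - pl$mass * sum(g * p)
    }
  }
  V
}
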