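#' Torques the muscles must produce
#'
#' Quasi-static inverse statics: at every instant the muscle (and reserve)
#' torques must balance gravity and the attached loads exactly, so
#' `tau_required = -gravity_load_torques(model, q)`. No inertial terms.
#'
#' @param model a `shoulder_model`.
#' @param q configuration (radians).
#' @param fk optional precomputed forward kinematics.
#' @return Numeric vector (N m) of length DOF.
#' @export
required_torques <- function(model, q, fk = NULL) {
  -gravity_load_torques(model, q, fk = fk)
}

#' Assemble the equilibrium system at one pose
#'
#' Builds the moment-arm matrix `R` (DOF x muscles), the per-muscle
#' activation-to-force gains at the current geometry, the required torques,
#' and the reserve-actuator gains. DOFs listed in `exclude_dofs` (e.g. a
#' kinematically driven scapulo-thoracic coordinate absorbed by an ideal
#' coordinate actuator) are dropped from the system.
#'
#' @param model a `shoulder_model`.
#' @param q configuration (radians).
#' @param exclude_dofs integer indices of DOFs handled by ideal coordinate
#'   actuators rather than by the muscles.
#' @param reserve_gain reserve actuator scale (N m, default 1); one value recycled over
#'   the retained DOFs.
#' @param h moment-arm finite-difference step (rad).
#' @return An `equilibrium_system` list with elements `R`, `f_gain`,
#'   `tau_required`, `reserve_gains`, `dofs`, `muscle_names`.
#' @export
equilibrium_system <- function(model, q, exclude_dofs = integer(0),
                               reserve_gain = 1, h = 1e-4) {
  fk <- forward_kinematics(model, q)
  keep <- setdiff(seq_len(model$ndof), exclude_dofs)
  R <- moment_arm_matrix(model, q, h = h)[keep, , drop = FALSE]
  f_gain <- vapply(model$muscles, function(m) {
    if (!m$active) return(0)
    muscle_force_gain(m, solve_path(m$path, fk$frames, model$wraps, m$name)$length)
  }, 0)
  tau <- required_torques(model, q, fk = fk)[keep]
  structure(list(R = R, f_gain = f_gain, tau_required = tau,
                 reserve_gains = rep_len(reserve_gain, length(keep)),
                 dofs = keep, muscle_names = names(model$muscles)),
            class = "equilibrium_system")
}

# strictly convex box-constrained QP: min 0.5 a' H a - b' a, 0 <= a <= ub,
# solved by a primal active-set method. H must be symmetric positive
# definite. Returns list(a, iterations, converged).
solve_box_qp <- function(H, b, ub = rep(1, length(b)), tol = 1e-12) {
  n <- length(b)
  a <- numeric(n)
  state <- rep.int(0L, n)  # 0 free, -1 at lower, +1 at upper
  state[] <- -1L           # start with everything clamped at zero (feasible)
  for (it in seq_len(50L * max(n, 2L))) {
    free <- which(state == 0L)
    target <- a
    if (length(free) > 0) {
      rhs <- b[free] - H[free, state == 1L, drop = FALSE] %*% ub[state == 1L]
      target[free] <- drop(solve(H[free, free, drop = FALSE], rhs))
    }
    target[state == -1L] <- 0
    target[state == 1L] <- ub[state == 1L]
    if (length(free) > 0 &&
        (any(target[free] < -tol) || any(target[free] > ub[free] + tol))) {
      # step toward the target until the first bound blocks
      d <- target - a
      tmax <- 1
      blocker <- 0L; bstate <- 0L
      for (i in free) {
        if (d[i] < -tol && a[i] + tmax * d[i] < 0) {
          t_i <- -a[i] / d[i]
          if (t_i < tmax) { tmax <- t_i; blocker <- i; bstate <- -1L }
        } else if (d[i] > tol && a[i] + tmax * d[i] > ub[i]) {
          t_i <- (ub[i] - a[i]) / d[i]
          if (t_i < tmax) { tmax <- t_i; blocker <- i; bstate <- 1L }
        }
      }
      a <- a + tmax * d
      a <- pmin(pmax(a, 0), ub)
      if (blocker > 0L) state[blocker] <- bstate
      next
    }
    a <- target
    g <- drop(H %*% a) - b
    viol_lo <- which(state == -1L & g < -1e-10)
    viol_hi <- which(state == 1L & g > 1e-10)
    if (length(viol_lo) == 0 && length(viol_hi) == 0) {
      return(list(a = a, iterations = it, converged = TRUE))
    }
    cand <- c(viol_lo, viol_hi)
    worst <- cand[which.max(abs(g[cand]))]
    state[worst] <- 0L
  }
  list(a = a, iterations = it, converged = FALSE)
}

#' Static optimization of muscle redundancy
#'
#' Resolves the muscle force distribution at one pose by minimising the sum
#' of squared muscle activations plus a heavy penalty on reserve actuator
#' use:
#' `min sum(a_i^2) + w_r * sum((s_j / g_j)^2)` subject to
#' `R diag(f_gain) a + s = tau_required`, `0 <= a <= 1`,
#' where `s` are idealised reserve torques at every retained DOF (gain
#' `g_j`). Eliminating `s` leaves a strictly convex box-constrained QP in the
#' activations, solved exactly by a primal active-set method; the equality
#' constraint then holds to machine precision by construction. Reserves
#' engage only when the muscles cannot produce the required torques.
#'
#' @param system an [equilibrium_system()].
#' @param w_reserve reserve penalty weight (default `1e4`).
#' @return A `solve_report`: activations, forces (N), reserve torques (N m),
#'   objective value, equilibrium residual norm (N m), and status
#'   (`"optimal"`, `"infeasible_reserves_used"` or `"failed"`).
#' @export
static_optimization <- function(system, w_reserve = 1e4) {
  M <- system$R %*% diag(system$f_gain, nrow = length(system$f_gain))
  G <- system$reserve_gains
  P <- M / G                      # rows scaled by 1/g_j
  tauG <- system$tau_required / G
  n <- length(system$f_gain)
  H <- 2 * (diag(n) + w_reserve * crossprod(P))
  b <- 2 * w_reserve * drop(crossprod(P, tauG))
  qp <- solve_box_qp(H, b)
  a <- qp$a
  s <- drop(system$tau_required - M %*% a)
  forces <- system$f_gain * a
  obj <- sum(a^2) + w_reserve * sum((s / G)^2)
  residual <- sqrt(sum((drop(M %*% a) + s - system$tau_required)^2))
  status <- if (!qp$converged) "failed"
            else if (max(abs(s)) > 1e-3) "infeasible_reserves_used"
            else "optimal"
  structure(list(activations = stats::setNames(a, system$muscle_names),
                 forces = stats::setNames(forces, system$muscle_names),
                 reserve_torques = stats::setNames(s, rownames(system$R)),
                 objective_value = obj, residual_norm = residual,
                 status = status, iterations = qp$iterations),
            class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("<solve_report> status %s | objective %.4g | residual %.2e N m | max reserve %.3g N m\n",
              x$status, x$objective_value, x$residual_norm,
              max(abs(x$reserve_torques))))
  invisible(x)
}

# per-body world forces applied by one muscle under tension `tension`,
# given its solved path. Returns list of list(body, force).
muscle_body_forces <- function(sol, tension) {
  out <- list()
  add <- function(body, f) {
    out[[length(out) + 1L]] <<- list(body = body, force = f)
  }
  for (seg in sol$segments) {
    A <- seg$from$w; B <- seg$to$w
    if (is.null(seg$wrap)) {
      u <- unit3(B - A)
      add(seg$from$body, tension * u)    # pull A toward B
      add(seg$to$body, -tension * u)     # pull B toward A
    } else {
      uA <- unit3(seg$T1 - A)
      uB <- unit3(seg$T2 - B)
      add(seg$from$body, tension * uA)
      add(seg$to$body, tension * uB)
      add(seg$wrap_body, -tension * (uA + uB))  # net force on the obstacle
    }
  }
  out
}

# body names in the subtree rooted at the child of `joint`
distal_bodies <- function(model, joint) {
  j <- model$joints[[joint]]
  if (is.null(j)) stop("unknown joint: ", joint)
  out <- j$child
  repeat {
    more <- vapply(model$joints, function(jj) jj$parent %in% out &&
                     !(jj$child %in% out), TRUE)
    if (!any(more)) break
    out <- c(out, vapply(model$joints[more], `[[`, "", "child"))
  }
  out
}

#' Joint reaction force
#'
#' Free-body balance of the subtree distal to the named joint: the reaction
#' transmitted across the joint equals minus the sum of all external forces
#' acting on the distal bodies -- gravity on segment masses and point loads,
#' plus the muscle tension forces applied at attachments, eyelets and wrap
#' contacts on distal bodies. Muscles lying entirely within the subtree
#' cancel internally. For the dual-bearing prosthesis the reported joint is
#' the scapula-ring fixed joint, i.e. the reaction between scapula and
#' glenoid ring.
#'
#' @param model a `shoulder_model`.
#' @param q configuration (radians).
#' @param forces named vector of muscle tensions (N), as returned in a
#'   `solve_report`.
#' @param joint joint name; default the model's `gh_joint`.
#' @return A `joint_reaction_force`: list with `force_world` (3-vector, N),
#'   `magnitude` (N) and `joint`.
#' @export
joint_reaction_force <- function(model, q, forces, joint = model$gh_joint) {
  if (is.null(joint)) stop("no joint named and model has no gh_joint set")
  fk <- forward_kinematics(model, q)
  distal <- distal_bodies(model, joint)
  total <- c(0, 0, 0)
  for (bn in distal) {
    b <- model$bodies[[bn]]
    if (b$mass > 0) total <- total + b$mass * model$gravity
    for (pl in b$point_loads) total <- total + pl$mass * model$gravity
  }
  for (m in model$muscles) {
    f <- forces[[m$name]]
    if (is.null(f) || is.na(f) || f == 0 || !m$active) next
    sol <- solve_path(m$path, fk$frames, model$wraps, m$name)
    for (bf in muscle_body_forces(sol, f)) {
      if (bf$body %in% distal) total <- total + bf$force
    }
  }
  structure(list(force_world = -total, magnitude = sqrt(sum(total^2)),
                 joint = joint), class = "joint_reaction_force")
}

#' Gravitational moment about a joint centre
#'
#' Magnitude-ready 3-vector moment of gravity (segment masses and point
#' loads) of the distal subtree about the joint's world centre. Used for the
#' friction-moment ratio, where the denominator is the gleno-humeral joint
#' moment carried across the bearing.
#'
#' @inheritParams joint_reaction_force
#' @return 3-vector moment (N m).
#' @export
gravity_moment_about <- function(model, q, joint = model$gh_joint) {
  fk <- forward_kinematics(model, q)
  j <- model$joints[[joint]]
  if (is.null(j)) stop("unknown joint: ", joint)
  c0 <- frame_compose(fk$frames[[j$parent]], j$parent_offset)$p
  distal <- distal_bodies(model, joint)
  Mv <- c(0, 0, 0)
  for (bn in distal) {
    b <- model$bodies[[bn]]
    pts <- list()
    if (b$mass > 0) pts[[1]] <- list(point = b$com, mass = b$mass)
    for (pl in b$point_loads) pts[[length(pts) + 1L]] <- pl
    for (pt in pts) {
      p <- frame_apply(fk$frames[[bn]], pt$point)
      fg <- pt$mass * model$gravity
      r <- p - c0
      Mv <- Mv + c(r[2] * fg[3] - r[3] * fg[2],
                   r[3] * fg[1] - r[1] * fg[3],
                   r[1] * fg[2] - r[2] * fg[1])
    }
  }
  Mv
}
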