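#' Wrapping surfaces
#'
#' A smooth convex obstacle (sphere or ellipsoid) fixed to a body, deflecting
#' the line of action of the muscles assigned to it. The surface acts as a
#' frictionless virtual deflection support for the muscle mid-line. Radii are
#' semi-axes in the owning body's frame (the ellipsoid is axis-aligned with
#' the body frame).
#'
#' @param name identifier.
#' @param kind `"sphere"` or `"ellipsoid"`.
#' @param body owning body name.
#' @param center surface centre in body coordinates (m).
#' @param radii length-3 semi-axes (m); a sphere must have three equal radii
#'   (a scalar is recycled).
#' @return A `wrap_surface` object.
#' @export
wrap_surface <- function(name, kind, body, center, radii) {
  kind <- match.arg(kind, c("sphere", "ellipsoid"))
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, 3)
  stopifnot(length(radii) == 3L, all(radii > 0))
  if (kind == "sphere" && diff(range(radii)) > 1e-12) {
    stop("sphere wrap '", name, "' must have equal radii")
  }
  structure(list(name = name, kind = kind, body = body,
                 center = as.numeric(center), radii = radii),
            class = "wrap_surface")
}

#' Muscle path specification
#'
#' An ordered polyline of body-fixed points from origin to insertion,
#' optionally passing via intermediate frictionless eyelets, with the names
#' of wrap surfaces allowed to deflect its straight segments (single-surface
#' wrapping per segment).
#'
#' @param origin,insertion `list(body =, point =)` attachment descriptors.
#' @param via optional list of such descriptors, ordered origin to insertion.
#' @param wraps character vector of wrap surface names.
#' @return A `muscle_path` object.
#' @export
muscle_path <- function(origin, insertion, via = list(), wraps = character(0)) {
  pts <- c(list(origin), via, list(insertion))
  pts <- lapply(pts, function(p) list(body = p$body, point = as.numeric(p$point)))
  structure(list(points = pts, wraps = as.character(wraps)),
            class = "muscle_path")
}

# exact sphere wrap in the plane through the two endpoints and the centre;
# returns NULL when the straight segment clears (or merely grazes) the sphere
sphere_wrap_2pt <- function(A, B, C, r, muscle = "?", surface = "?",
                            n_arc_pts = 9L) {
  dA <- sqrt(sum((A - C)^2)); dB <- sqrt(sum((B - C)^2))
  if (dA < r * (1 - 1e-12) || dB < r * (1 - 1e-12)) {
    stop(sprintf("muscle '%s': endpoint inside wrap surface '%s'", muscle, surface))
  }
  # distance from C to segment AB
  d <- B - A
  t <- sum((C - A) * d) / sum(d * d)
  t <- min(1, max(0, t))
  dist <- sqrt(sum((A + t * d - C)^2))
  if (dist >= r) return(NULL)  # clear line of sight (grazing counts as clear)
  e1 <- (A - C) / dA
  b <- (B - C) - sum((B - C) * e1) * e1
  nb <- sqrt(sum(b * b))
  if (nb < 1e-15) return(NULL)  # A, B, C collinear: segment through centre
  e2 <- b / nb
  phi <- acos(min(1, max(-1, sum((A - C) * (B - C)) / (dA * dB))))
  aA <- acos(min(1, r / dA)); aB <- acos(min(1, r / dB))
  theta <- phi - aA - aB
  if (theta <= 0) return(NULL)  # tangent lines clear each other
  T1 <- C + r * (cos(aA) * e1 + sin(aA) * e2)
  ang2 <- phi - aB
  T2 <- C + r * (cos(ang2) * e1 + sin(ang2) * e2)
  tanA <- sqrt(max(dA^2 - r^2, 0)); tanB <- sqrt(max(dB^2 - r^2, 0))
  # sampled arc points (geodesic in the wrap plane), endpoints included
  ang <- seq(aA, ang2, length.out = n_arc_pts)
  arc <- t(sapply(ang, function(a) C + r * (cos(a) * e1 + sin(a) * e2)))
  list(T1 = T1, T2 = T2, length = tanA + tanB + r * theta, arc = arc,
       arc_len = r * theta)
}

# ellipsoid wrap via the scaled-sphere construction: map the ellipsoid to
# the unit sphere by axis scaling, take the exact sphere wrap there, and map
# the on-surface geodesic back. The mapped route is smooth, unique and
# continuous in the endpoints (the iterative shortest-path refinement,
# available with refine = TRUE, can jump between locally-shortest routes for
# paths passing near the disc centre and is therefore off by default).
ellipsoid_wrap_2pt <- function(A, B, C, Rb, radii, muscle = "?", surface = "?",
                               n_arc = 16L, refine = FALSE, reltol = 1e-13) {
  # to wrap-local axis-aligned coordinates, then scale to the unit sphere
  Al <- as.numeric(t(Rb) %*% (A - C)) / radii
  Bl <- as.numeric(t(Rb) %*% (B - C)) / radii
  if (sqrt(sum(Al^2)) < 1 - 1e-12 || sqrt(sum(Bl^2)) < 1 - 1e-12) {
    stop(sprintf("muscle '%s': endpoint inside wrap surface '%s'", muscle, surface))
  }
  seed <- sphere_wrap_2pt(Al, Bl, c(0, 0, 0), 1, muscle, surface,
                          n_arc_pts = if (refine) 9L else n_arc + 2L)
  if (is.null(seed)) return(NULL)
  if (!refine) {
    pts_l <- seed$arc * rep(radii, each = nrow(seed$arc))
    arc_w <- t(Rb %*% t(pts_l)) + matrix(C, nrow(pts_l), 3, byrow = TRUE)
    Aw <- t(Rb %*% (radii * Al)) + C
    Bw <- t(Rb %*% (radii * Bl)) + C
    full <- rbind(Aw, arc_w, Bw)
    len <- sum(sqrt(rowSums(diff(full)^2)))
    return(list(T1 = arc_w[1, ], T2 = arc_w[nrow(arc_w), ], length = len,
                arc = arc_w,
                arc_len = sum(sqrt(rowSums(diff(arc_w)^2)))))
  }
  # spherical chart in a rotated basis whose pole is normal to the seed wrap
  # plane, keeping the path near the chart equator (no pole degeneracy)
  e3 <- c(Al[2] * Bl[3] - Al[3] * Bl[2], Al[3] * Bl[1] - Al[1] * Bl[3],
          Al[1] * Bl[2] - Al[2] * Bl[1])
  if (sqrt(sum(e3^2)) < 1e-12) e3 <- c(0, 0, 1) else e3 <- unit3(e3)
  e1 <- unit3(Al)
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2], e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  Bas <- cbind(e1, e2, e3)
  # interior surface points seeded from the scaled-sphere geodesic
  ang <- seq(0, 1, length.out = n_arc + 2L)[2:(n_arc + 1L)]
  P0 <- seed$arc[1 + round(ang * (nrow(seed$arc) - 1)), , drop = FALSE] %*% Bas
  par0 <- as.numeric(t(apply(P0, 1, function(p)
    c(acos(min(1, max(-1, p[3] / sqrt(sum(p^2))))), atan2(p[2], p[1])))))
  ia <- seq(1, 2 * n_arc, 2)
  Aw <- radii * Al; Bw <- radii * Bl
  usph <- function(par) {
    th <- par[ia]; ph <- par[ia + 1]
    cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)) %*% t(Bas)
  }
  pts_of <- function(par) {
    u <- usph(par)
    rbind(Aw, u * rep(radii, each = n_arc), Bw)
  }
  path_len <- function(par) {
    p <- pts_of(par)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }
  path_grad <- function(par) {
    th <- par[ia]; ph <- par[ia + 1]
    st <- sin(th); ct <- cos(th); sp <- sin(ph); cp <- cos(ph)
    p <- pts_of(par)
    d <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    u <- d / sqrt(rowSums(d^2))          # unit vectors along segments
    # dL/dP_i for interior point i: u[i-1,] - u[i,]
    gP <- u[seq_len(n_arc), , drop = FALSE] - u[seq_len(n_arc) + 1L, , drop = FALSE]
    dth <- (cbind(ct * cp, ct * sp, -st) %*% t(Bas)) * rep(radii, each = n_arc)
    dph <- (cbind(-st * sp, st * cp, 0) %*% t(Bas)) * rep(radii, each = n_arc)
    g <- numeric(2 * n_arc)
    g[ia] <- rowSums(gP * dth)
    g[ia + 1] <- rowSums(gP * dph)
    g
  }
  opt <- stats::optim(par0, path_len, gr = path_grad, method = "BFGS",
                      control = list(reltol = reltol, maxit = 200))
  pts_l <- pts_of(opt$par)[-c(1, n_arc + 2L), , drop = FALSE]
  # back to world coordinates
  arc_w <- t(Rb %*% t(pts_l)) + matrix(C, nrow(pts_l), 3, byrow = TRUE)
  len <- opt$value
  list(T1 = arc_w[1, ], T2 = arc_w[nrow(arc_w), ], length = len, arc = arc_w,
       arc_len = sum(sqrt(rowSums(diff(arc_w)^2))))
}

#' Solve a muscle path at given body frames
#'
#' Each straight segment between consecutive fixed path points is tested
#' against the wrap surfaces assigned to the muscle; if the segment
#' intersects a surface it is replaced by a tangent-arc-tangent route over
#' it: the exact shortest route for spheres (in the plane through the two
#' points and the centre); for ellipsoids the sphere route in axis-scaled
#' coordinates mapped back to the surface, which is smooth, unique and
#' continuous in the endpoints (an iterative on-surface shortest-path
#' refinement exists in the internals but is not used by the solver; see the
#' methods vignette). A segment that merely grazes a surface is reported
#' unwrapped.
#'
#' @param path a [muscle_path()].
#' @param frames named list of body [frame()]s (from [forward_kinematics()]).
#' @param wraps named list of [wrap_surface()] objects available to the path.
#' @param muscle muscle name, used in error messages.
#' @return A `path_solution`: list with `nodes` (list of
#'   `list(body, point_world, kind)`), `length` (m), `wrapped` (named logical
#'   per assigned wrap), `segments` (per-segment records used for force
#'   application).
#' @export
solve_path <- function(path, frames, wraps, muscle = "?") {
  fixed <- lapply(path$points, function(p) {
    if (is.null(frames[[p$body]])) stop("no frame for body '", p$body, "'")
    list(body = p$body, w = frame_apply(frames[[p$body]], p$point))
  })
  act <- wraps[path$wraps]
  wrapped <- stats::setNames(rep(FALSE, length(act)),
                             vapply(act, `[[`, "", "name"))
  total <- 0
  segments <- list()
  for (i in seq_len(length(fixed) - 1L)) {
    A <- fixed[[i]]$w; B <- fixed[[i + 1L]]$w
    seg <- list(from = fixed[[i]], to = fixed[[i + 1L]], wrap = NULL)
    sol <- NULL
    for (w in act) {
      fw <- frames[[w$body]]
      Cw <- frame_apply(fw, w$center)
      sol <- if (w$kind == "sphere") {
        sphere_wrap_2pt(A, B, Cw, w$radii[1], muscle, w$name)
      } else {
        ellipsoid_wrap_2pt(A, B, Cw, fw$R, w$radii, muscle, w$name)
      }
      if (!is.null(sol)) {
        wrapped[w$name] <- TRUE
        seg$wrap <- w$name
        seg$wrap_body <- w$body
        seg$T1 <- sol$T1; seg$T2 <- sol$T2
        seg$length <- sol$length
        seg$arc <- sol$arc
        break
      }
    }
    if (is.null(sol)) seg$length <- sqrt(sum((B - A)^2))
    total <- total + seg$length
    segments[[i]] <- seg
  }
  structure(list(length = total, wrapped = wrapped, segments = segments,
                 fixed = fixed),
            class = "path_solution")
}

#' Waypoints of a solved path
#'
#' @param sol a `path_solution`.
#' @return n x 3 matrix of world waypoints (fixed points, tangent points and
#'   sampled arc points, in order).
#' @export
path_waypoints <- function(sol) {
  out <- sol$fixed[[1]]$w
  for (seg in sol$segments) {
    if (!is.null(seg$wrap)) out <- rbind(out, seg$arc)
    out <- rbind(out, seg$to$w)
  }
  out <- matrix(out, ncol = 3)
  dimnames(out) <- NULL
  out
}

#' Length of a muscle's path at a configuration
#'
#' @param model a `shoulder_model`.
#' @param q configuration (radians).
#' @param muscle muscle name.
#' @param fk optional precomputed forward kinematics.
#' @return Path length (m).
#' @export
muscle_length <- function(model, q, muscle, fk = NULL) {
  if (is.null(fk)) fk <- forward_kinematics(model, q)
  m <- model$muscles[[muscle]]
  if (is.null(m)) stop("unknown muscle: ", muscle)
  solve_path(m$path, fk$frames, model$wraps, muscle)$length
}

#' Tendon-excursion moment arm
#'
#' Moment arm of a muscle about one generalized coordinate, computed as the
#' negative derivative of path length with respect to the coordinate
#' (central finite difference): `r = -dL/dq`.
#'
#' @param model a `shoulder_model`.
#' @param q configuration (radians).
#' @param muscle muscle name.
#' @param dof_index coordinate index (1..DOF).
#' @param h finite-difference step (rad), in `[1e-6, 1e-2]`.
#' @return Moment arm (m); positive when increasing the coordinate shortens
#'   the muscle.
#' @export
moment_arm <- function(model, q, muscle, dof_index, h = 1e-4) {
  stopifnot(h >= 1e-6, h <= 1e-2,
            dof_index >= 1, dof_index <= model$ndof)
  qp <- q; qp[dof_index] <- qp[dof_index] + h
  qm <- q; qm[dof_index] <- qm[dof_index] - h
  -(muscle_length(model, qp, muscle) - muscle_length(model, qm, muscle)) / (2 * h)
}

# does DOF k change muscle geometry? true iff k separates the set of bodies
# the path (and its wraps) touches
dof_affects_muscle <- function(model, muscle) {
  m <- model$muscles[[muscle]]
  bodies <- unique(c(vapply(m$path$points, `[[`, "", "body"),
                     vapply(model$wraps[m$path$wraps], `[[`, "", "body")))
  aff <- logical(model$ndof)
  for (k in seq_len(model$ndof)) {
    below <- vapply(bodies, function(b) k %in% model$body_dofs[[b]], TRUE)
    aff[k] <- any(below) && !all(below)
  }
  aff
}

#' Moment-arm matrix
#'
#' Moment arms of every active muscle about every generalized coordinate at
#' configuration `q` (DOF x muscles, metres). Columns of inactive muscles are
#' zero; coordinates that cannot change a muscle's geometry (they move all of
#' its attachment bodies rigidly, or none) are skipped analytically.
#'
#' @inheritParams moment_arm
#' @return DOF x n_muscle matrix with muscle names as column names.
#' @export
moment_arm_matrix <- function(model, q, h = 1e-4) {
  nm <- length(model$muscles)
  R <- matrix(0, model$ndof, nm,
              dimnames = list(model$dof_names, names(model$muscles)))
  if (nm == 0) return(R)
  fks <- vector("list", model$ndof)
  for (k in seq_len(model$ndof)) {
    qp <- q; qp[k] <- qp[k] + h
    qm <- q; qm[k] <- qm[k] - h
    fks[[k]] <- list(p = forward_kinematics(model, qp),
                     m = forward_kinematics(model, qm))
  }
  for (mi in seq_len(nm)) {
    m <- model$muscles[[mi]]
    if (!m$active) next
    aff <- dof_affects_muscle(model, m$name)
    for (k in which(aff)) {
      Lp <- solve_path(m$path, fks[[k]]$p$frames, model$wraps, m$name)$length
      Lm <- solve_path(m$path, fks[[k]]$m$frames, model$wraps, m$name)$length
      R[k, mi] <- -(Lp - Lm) / (2 * h)
    }
  }
  R
}

#' Wrapping surface for an implant
#'
#' Builds the muscle-deflection surface of a prosthetic implant, inflated by
#' half of the deltoid muscle thickness so that the deflected mid-line of the
#' deltoid elements clears the hardware realistically.
#'
#' Reverse prosthesis: 36 mm glenosphere, inflated to a 56 mm sphere.
#' Dual-bearing prosthesis: 55 mm glenoid ring, inflated in its two in-plane
#' axes to an ellipsoid with principal-axis diameters 75, 75 and 28 mm.
#'
#' @param implant `"RSP"` or `"DBSP"`.
#' @param deltoid_half_thickness inflation (m); default 0.010 (half of a
#'   20 mm deltoid element thickness).
#' @param body owning body name.
#' @param center surface centre in body coordinates (m).
#' @return A [wrap_surface()].
#' @export
build_wrap_for_implant <- function(implant, deltoid_half_thickness = 0.010,
                                   body = "scapula", center = c(0, 0, 0)) {
  infl <- deltoid_half_thickness
  switch(match.arg(implant, c("RSP", "DBSP")),
    RSP = wrap_surface("rsp_glenosphere_wrap", "sphere", body, center,
                       radii = 0.036 / 2 + infl),
    DBSP = wrap_surface("dbsp_ring_wrap", "ellipsoid", body, center,
                        radii = c(0.055 / 2 + infl, 0.055 / 2 + infl,
                                  0.028 / 2)))
}
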