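#' Default shoulder geometry constants
#'
#' The default model geometry is synthetic: segment dimensions and inertial
#' parameters follow standard adult anthropometry, and muscle attachment
#' coordinates are plausible constructions chosen to reproduce the
#' qualitative lines of action of the deltoid and rotator cuff. They are NOT
#' anatomical ground truth (the cadaver-derived attachment datasets behind
#' published shoulder models are not redistributable). Coordinates are
#' right-handed, metres: y up, x anterior, z lateral (right side).
#'
#' @keywords internal
#' @name shouldersim-geometry
NULL

# world-frame anchor points of the default skeleton (m)
.geom <- list(
  sc_joint      = c(0.000, 0.400, 0.020),   # sterno-clavicular
  ac_in_clav    = c(0.000, 0.020, 0.130),   # acromio-clavicular, clavicle frame
  glenoid_in_scap = c(0.000, -0.045, 0.020),# glenoid face centre, scapula frame
  glenoid_half_height = 0.0175,             # inferior rim is this far below centre
  ns_cor_lateral = 0.010,                   # humeral head centre lateral of glenoid face
  humeral_head_radius = 0.024,
  elbow_in_hum  = c(0.000, -0.290, 0.000),
  wrist_in_ulna = c(0.000, -0.260, 0.000),
  masses = list(thorax = 30, head = 5, clavicle = 0.2, scapula = 0.7,
                humerus = 2.17, ulna = 0.65, radius = 0.65, hand = 0.49)
)

# group-level maximum isometric forces (N). Calibrated so that each group's
# summed f_max matches the force/activation ratio a published peak-force
# table implies for that group; per-element f_max is the group sum divided by
# the element count.
.group_fmax <- c(anterior_deltoid = 504.8, middle_deltoid = 1169.6,
                 posterior_deltoid = 1650.0, supraspinatus = 623.3,
                 infraspinatus = 1441.5, teres_minor = 500.8,
                 subscapularis = 1424.0)

.group_nelem <- c(anterior_deltoid = 4L, middle_deltoid = 4L,
                  posterior_deltoid = 7L, supraspinatus = 4L,
                  infraspinatus = 6L, teres_minor = 3L, subscapularis = 11L)

# synthetic attachment tables: origin (body + local point) and insertion
# (humerus local point) per element
shoulder_muscle_table <- function() {
  rows <- list()
  add <- function(group, k, obody, opt, ipt) {
    rows[[length(rows) + 1L]] <<- list(
      name = sprintf("%s_%d", group, k), group = group,
      origin_body = obody, origin = opt, insertion = ipt)
  }
  for (k in 1:4) {  # anterior deltoid: clavicular origins
    add("anterior_deltoid", k, "clavicle",
        c(0.015, 0.020, 0.085 + (k - 1) * 0.015),
        c(0.012, -0.100 - (k - 1) * 0.005, 0.006))
  }
  for (k in 1:4) {  # middle deltoid: acromial origins
    add("middle_deltoid", k, "scapula",
        c(0.000, 0.005, 0.005 + (k - 1) * 0.010),
        c(0.000, -0.100 - (k - 1) * 0.005, 0.014))
  }
  for (k in 1:7) {  # posterior deltoid: scapular spine origins
    add("posterior_deltoid", k, "scapula",
        c(-0.025 - (k - 1) * 0.012, -0.005, -0.005),
        c(-0.010, -0.095 - (k - 1) * 0.004, 0.008))
  }
  for (k in 1:4) {  # supraspinatus: supraspinous fossa to superior tuberosity
    add("supraspinatus", k, "scapula",
        c(-0.030 - (k - 1) * 0.010, -0.010, -0.030),
        c(0.004 + (k - 1) * 0.001, 0.016, 0.020))
  }
  for (k in 1:6) {  # infraspinatus: infraspinous fossa to posterior tuberosity
    add("infraspinatus", k, "scapula",
        c(-0.040 - (k - 1) * 0.008, -0.055, -0.030),
        c(-0.012, 0.006 - (k - 1) * 0.002, 0.019))
  }
  for (k in 1:3) {  # teres minor: lateral border
    add("teres_minor", k, "scapula",
        c(-0.025, -0.085 - (k - 1) * 0.012, -0.020),
        c(-0.014, -0.008 - (k - 1) * 0.003, 0.016))
  }
  for (k in 1:11) { # subscapularis: anterior fossa to lesser tuberosity
    add("subscapularis", k, "scapula",
        c(0.004, -0.030 - (k - 1) * 0.007, -0.035),
        c(0.015, 0.004 - (k - 1) * 0.002, 0.010))
  }
  rows
}

# shared skeleton bodies/joints; the gleno-humeral connection is supplied by
# the variant-specific builder as a list of extra bodies + joints that ends
# by attaching "humerus" so that its frame sits at `ns_cor` with identity
# rotation in the neutral pose.
shoulder_skeleton <- function(gh_bodies, gh_joints, hand_load_kg = 2,
                              elbow_flexion_deg = 90) {
  g <- .geom
  bodies <- c(list(
    body_segment("thorax", g$masses$thorax, com = c(0, 0.15, 0)),
    body_segment("head", g$masses$head, com = c(0, 0.07, 0)),
    body_segment("clavicle", g$masses$clavicle, com = c(0, 0.010, 0.065)),
    body_segment("scapula", g$masses$scapula, com = c(-0.030, -0.070, -0.010)),
    body_segment("humerus", g$masses$humerus, com = c(0, -0.130, 0)),
    body_segment("ulna", g$masses$ulna, com = c(0, -0.120, 0)),
    body_segment("radius", g$masses$radius, com = c(0, -0.120, 0)),
    body_segment("hand", g$masses$hand, com = c(0, -0.070, 0),
                 point_loads = if (hand_load_kg > 0)
                   list(list(point = c(0, -0.070, 0), mass = hand_load_kg))
                 else list())),
    gh_bodies)
  joints <- c(list(
    joint_spec("neck", "fixed", "thorax", "head",
               parent_offset = frame(p = c(0, 0.55, 0))),
    joint_spec("sterno_clav", "fixed", "thorax", "clavicle",
               parent_offset = frame(p = g$sc_joint)),
    joint_spec("acromio_clav", "hinge", "clavicle", "scapula",
               parent_offset = frame(p = g$ac_in_clav),
               axes = list(c(-1, 0, 0)))),
    gh_joints,
    list(
      joint_spec("elbow", "fixed", "humerus", "ulna",
                 parent_offset = frame(
                   R = rot_axis_angle(c(0, 0, 1), deg2rad(elbow_flexion_deg)),
                   p = g$elbow_in_hum)),
      joint_spec("radioulnar", "fixed", "ulna", "radius"),
      joint_spec("wrist", "fixed", "ulna", "hand",
                 parent_offset = frame(p = g$wrist_in_ulna))))
  list(bodies = bodies, joints = joints)
}

# build the shared muscle element list; `wrap_name` (or NULL) is assigned to
# the deltoid elements. f_max per element divides the calibrated group sum;
# l_opt/l_slack are set later from a reference-pose path length.
shoulder_muscles <- function(wrap_name = NULL) {
  tab <- shoulder_muscle_table()
  lapply(tab, function(r) {
    is_deltoid <- grepl("deltoid", r$group)
    muscle_element(
      name = r$name, group = r$group,
      f_max = .group_fmax[[r$group]] / .group_nelem[[r$group]],
      l_opt = 0.10, l_slack = 0,  # placeholders, calibrated at build time
      path = muscle_path(
        origin = list(body = r$origin_body, point = r$origin),
        insertion = list(body = "humerus", point = r$insertion),
        wraps = if (is_deltoid && !is.null(wrap_name)) wrap_name
                else character(0)))
  })
}

# set l_opt/l_slack from the path length at a mid-range reference pose:
# l_slack = 0.2 L_ref, l_opt = 0.8 L_ref, so fibres operate near the plateau
# of the force-length curve across the studied ranges of motion
calibrate_fiber_lengths <- function(model, elev_deg = 40) {
  qref <- numeric(model$ndof)
  qref[model$gh_dofs] <- gh_angles_to_q(model, plane_deg = 0,
                                        elev_deg = elev_deg, axial_deg = 0,
                                        q_base = qref)
  fk <- forward_kinematics(model, qref)
  for (i in seq_along(model$muscles)) {
    m <- model$muscles[[i]]
    L <- solve_path(m$path, fk$frames, model$wraps, m$name)$length
    model$muscles[[i]]$l_slack <- 0.2 * L
    model$muscles[[i]]$l_opt <- 0.8 * L
  }
  model
}

ns_cor_world <- function() {
  g <- .geom
  g$sc_joint + g$ac_in_clav + g$glenoid_in_scap + c(0, 0, g$ns_cor_lateral)
}

#' Build the natural shoulder (NS) model
#'
#' Gleno-humeral ball-and-socket joint at the anatomical humeral head centre,
#' parameterised as an intrinsic Y-X-Y rotation sequence (plane of elevation,
#' elevation, axial rotation). All seven studied muscle groups are active,
#' including the supraspinatus; the deltoid elements wrap over a humeral-head
#' sphere. The scapula carries a single upward-rotation hinge relative to the
#' clavicle implementing a simplified scapulo-humeral rhythm.
#'
#' @param hand_load_kg point mass rigidly attached to the hand (kg),
#'   default 2.
#' @param elbow_flexion_deg fixed elbow flexion (degrees), default 0
#'   (straight arm, as in standard elevation protocols; the axial-rotation
#'   protocols use 90). Elbow and wrist are fixed joints.
#' @return A `shoulder_model`, variant `"NS"`.
#' @export
build_natural_shoulder <- function(hand_load_kg = 2, elbow_flexion_deg = 0) {
  g <- .geom
  cor <- ns_cor_world()
  cor_in_scap <- g$glenoid_in_scap + c(0, 0, g$ns_cor_lateral)
  gh <- joint_spec("gleno_humeral", "ball", "scapula", "humerus",
                   parent_offset = frame(p = cor_in_scap),
                   axes = list(c(0, 1, 0), c(-1, 0, 0), c(0, 1, 0)))
  sk <- shoulder_skeleton(list(), list(gh), hand_load_kg, elbow_flexion_deg)
  wrap <- wrap_surface("humeral_head_wrap", "sphere", "humerus",
                       center = c(0, 0, 0), radii = g$humeral_head_radius)
  model <- chain_model(sk$bodies, sk$joints,
                       muscles = shoulder_muscles("humeral_head_wrap"),
                       wraps = list(wrap), gh_joint = "gleno_humeral",
                       variant = "NS")
  model$gh_dofs <- which(model$dof_joint ==
                           which(names(model$joints) == "gleno_humeral"))
  model$scap_dof <- which(model$dof_joint ==
                            which(names(model$joints) == "acromio_clav"))
  calibrate_fiber_lengths(model)
}

#' Build the reverse shoulder prosthesis (RSP) model
#'
#' Ball-and-socket joint with the centre of rotation medialised onto the
#' glenoid face, on the antero-posterior midline 18 mm above the inferior
#' edge of the glenoid rim; a 36 mm glenosphere inflated to a 56 mm
#' spherical wrapping surface deflects the deltoid. The supraspinatus is
#' deactivated. The humerus keeps the NS attachment coordinates and sits in
#' the same neutral pose.
#'
#' @inheritParams build_natural_shoulder
#' @param glenosphere_diameter glenosphere diameter (m), default 0.036.
#' @param cor_above_rim COR height above the inferior glenoid rim (m),
#'   default 0.018.
#' @param deltoid_half_thickness wrap inflation (m), default 0.010.
#' @return A `shoulder_model`, variant `"RSP"`.
#' @export
build_rsp <- function(hand_load_kg = 2, elbow_flexion_deg = 0,
                      glenosphere_diameter = 0.036, cor_above_rim = 0.018,
                      deltoid_half_thickness = 0.010) {
  g <- .geom
  # COR on the glenoid face (no lateral offset), 18 mm above the inferior rim
  cor_in_scap <- g$glenoid_in_scap +
    c(0, cor_above_rim - g$glenoid_half_height, 0)
  ns_cor_in_scap <- g$glenoid_in_scap + c(0, 0, g$ns_cor_lateral)
  gh <- joint_spec("gleno_humeral", "ball", "scapula", "humerus",
                   parent_offset = frame(p = cor_in_scap),
                   child_offset = frame(p = ns_cor_in_scap - cor_in_scap),
                   axes = list(c(0, 1, 0), c(-1, 0, 0), c(0, 1, 0)))
  sk <- shoulder_skeleton(list(), list(gh), hand_load_kg, elbow_flexion_deg)
  wrap <- build_wrap_for_implant("RSP", deltoid_half_thickness,
                                 body = "scapula", center = cor_in_scap)
  wrap$radii <- rep(glenosphere_diameter / 2 + deltoid_half_thickness, 3)
  model <- chain_model(sk$bodies, sk$joints,
                       muscles = shoulder_muscles(wrap$name),
                       wraps = list(wrap), gh_joint = "gleno_humeral",
                       variant = "RSP")
  model$gh_dofs <- which(model$dof_joint ==
                           which(names(model$joints) == "gleno_humeral"))
  model$scap_dof <- which(model$dof_joint ==
                            which(names(model$joints) == "acromio_clav"))
  model <- deactivate_supraspinatus(model)
  calibrate_fiber_lengths(model)
}

#' Build the dual-bearing shoulder prosthesis (DBSP) model
#'
#' Five-joint glenoid-sparing assembly:
#' scapula -> glenoid ring (fixed, ring plane tilted 10 degrees downward) ->
#' PE bearing (hinge about the ring axis) -> ball head (gimbal, two ordered
#' rotations) -> offset adapter (fixed) -> humerus (fixed). The two centres
#' of rotation (hinge axis point at the ring centre; gimbal centre) are
#' offset from each other along the ring axis. Total scapula-humerus
#' mobility is 1 + 2 = 3 rotational DOF, as for the ball joints. An
#' ellipsoid wrapping surface (75 x 75 x 28 mm principal-axis diameters,
#' i.e. the 55 mm ring inflated in-plane by the deltoid half thickness)
#' fixed to the ring deflects the deltoid. The supraspinatus is deactivated.
#'
#' @inheritParams build_natural_shoulder
#' @param ring_outer_diameter glenoid ring outer diameter (m), default 0.055.
#' @param ring_tilt_deg downward tilt of the ring relative to the glenoid
#'   plane (degrees), default 10.
#' @param dual_cor_offset distance between the two centres of rotation along
#'   the ring axis (m); the implant drawings do not dimension it, default
#'   0.010 (declared assumption).
#' @param deltoid_half_thickness wrap inflation (m), default 0.010.
#' @return A `shoulder_model`, variant `"DBSP"`.
#' @export
build_dbsp <- function(hand_load_kg = 2, elbow_flexion_deg = 0,
                       ring_outer_diameter = 0.055, ring_tilt_deg = 10,
                       dual_cor_offset = 0.010,
                       deltoid_half_thickness = 0.010) {
  g <- .geom
  ring_in_scap <- g$glenoid_in_scap
  R_tilt <- rot_axis_angle(c(1, 0, 0), deg2rad(ring_tilt_deg))
  gh_bodies <- list(
    body_segment("glenoid_ring", 0.05),
    body_segment("pe_bearing", 0.02),
    body_segment("ball_head", 0.08),
    body_segment("offset_adapter", 0.05))
  # place the humerus at the NS COR with identity rotation in neutral pose
  ns_cor_in_scap <- g$glenoid_in_scap + c(0, 0, g$ns_cor_lateral)
  gimbal_in_scap <- ring_in_scap + as.numeric(R_tilt %*% c(0, 0, dual_cor_offset))
  hum_off_local <- as.numeric(t(R_tilt) %*% (ns_cor_in_scap - gimbal_in_scap))
  gh_joints <- list(
    joint_spec("scapula_ring", "fixed", "scapula", "glenoid_ring",
               parent_offset = frame(R = R_tilt, p = ring_in_scap)),
    joint_spec("ring_pe", "hinge", "glenoid_ring", "pe_bearing",
               axes = list(c(0, 0, 1))),
    joint_spec("pe_ball", "gimbal", "pe_bearing", "ball_head",
               parent_offset = frame(p = c(0, 0, dual_cor_offset)),
               axes = list(c(1, 0, 0), c(0, 0, 1))),
    joint_spec("ball_adapter", "fixed", "ball_head", "offset_adapter",
               parent_offset = frame(p = hum_off_local / 2)),
    joint_spec("adapter_humerus", "fixed", "offset_adapter", "humerus",
               parent_offset = frame(R = t(R_tilt), p = hum_off_local / 2)))
  sk <- shoulder_skeleton(gh_bodies, gh_joints, hand_load_kg,
                          elbow_flexion_deg)
  wrap <- build_wrap_for_implant("DBSP", deltoid_half_thickness,
                                 body = "glenoid_ring", center = c(0, 0, 0))
  wrap$radii[1:2] <- ring_outer_diameter / 2 + deltoid_half_thickness
  model <- chain_model(sk$bodies, sk$joints,
                       muscles = shoulder_muscles(wrap$name),
                       wraps = list(wrap), gh_joint = "scapula_ring",
                       variant = "DBSP")
  ji <- function(nm) which(names(model$joints) == nm)
  model$gh_dofs <- which(model$dof_joint %in% c(ji("ring_pe"), ji("pe_ball")))
  model$scap_dof <- which(model$dof_joint == ji("acromio_clav"))
  model <- deactivate_supraspinatus(model)
  calibrate_fiber_lengths(model)
}

#' Build a shoulder model by variant tag
#'
#' @param variant `"NS"`, `"RSP"` or `"DBSP"` (case-insensitive).
#' @param ... passed to the variant builder.
#' @return A `shoulder_model`.
#' @export
build_shoulder_model <- function(variant, ...) {
  switch(toupper(variant),
         NS = build_natural_shoulder(...),
         RSP = build_rsp(...),
         DBSP = build_dbsp(...),
         stop("unknown variant: ", variant))
}

#' Coulomb friction-moment bound for a prosthetic bearing
#'
#' Conservative upper bound on the contribution of bearing friction to the
#' joint reaction moment: the friction moment of a spherical/annular bearing
#' is bounded by `mu * JRF * r` with `r` the outer contact radius, and is
#' expressed as a percentage of the gleno-humeral joint moment.
#'
#' @param mu friction coefficient (dimensionless, >= 0; UHMWPE on CoCr is
#'   below 0.05).
#' @param bearing_radius outer bearing contact radius (m), > 0.
#' @param jrf joint reaction force magnitude (N).
#' @param joint_moment gleno-humeral joint moment magnitude (N m), > 0.
#' @return A `friction_estimate`: `friction_moment` (N m), `joint_moment`
#'   (N m) and `ratio_percent` (= 100 * friction / joint moment).
#' @export
friction_moment_ratio <- function(mu, bearing_radius, jrf, joint_moment) {
  stopifnot(mu >= 0, bearing_radius > 0)
  if (joint_moment <= 0) stop("joint_moment must be positive")
  fm <- mu * jrf * bearing_radius
  structure(list(friction_moment = fm, joint_moment = joint_moment,
                 ratio_percent = 100 * fm / joint_moment),
            class = "friction_estimate")
}

#' @export
print.friction_estimate <- function(x, ...) {
  cat(sprintf("<friction_estimate> friction %.3g N m / joint %.3g N m = %.2f%%\n",
              x$friction_moment, x$joint_moment, x$ratio_percent))
  invisible(x)
}
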