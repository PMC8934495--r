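#' Model configuration files
#'
#' Shoulder models round-trip through a YAML configuration with the field
#' units of the implant drawings: lengths in millimetres, masses in
#' kilograms, angles in degrees. Internally everything is SI (metres,
#' newtons, radians). Frame rotations are stored as axis + angle (degrees).
#'
#' @param model a `shoulder_model`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  f2c <- function(f) {
    rv <- rot_log(f$R)
    ang <- sqrt(sum(rv^2))
    list(axis = if (ang > 0) as.list(rv / ang) else list(1, 0, 0),
         angle_deg = rad2deg(ang),
         origin_mm = as.list(f$p * 1000))
  }
  cfg <- list(
    variant = model$variant,
    gravity = as.list(model$gravity),
    gh_joint = model$gh_joint,
    gh_joint_names = unique(vapply(model$gh_dofs, function(k)
      model$joints[[model$dof_joint[k]]]$name, "")),
    scap_joint_name = if (length(model$scap_dof))
      model$joints[[model$dof_joint[model$scap_dof[1]]]]$name else NULL,
    bodies = lapply(model$bodies, function(b) list(
      name = b$name, mass_kg = b$mass, com_mm = as.list(b$com * 1000),
      point_loads = lapply(b$point_loads, function(pl)
        list(point_mm = as.list(pl$point * 1000), mass_kg = pl$mass)))),
    joints = lapply(model$joints, function(j) list(
      name = j$name, kind = j$kind, parent = j$parent, child = j$child,
      parent_offset = f2c(j$parent_offset),
      child_offset = f2c(j$child_offset),
      axes = lapply(j$axes, as.list),
      limits_deg = if (is.null(j$limits)) NULL
                   else lapply(seq_len(nrow(j$limits)), function(i)
                     as.list(rad2deg(j$limits[i, ]))))),
    wraps = lapply(model$wraps, function(w) list(
      name = w$name, kind = w$kind, body = w$body,
      center_mm = as.list(w$center * 1000),
      radii_mm = as.list(w$radii * 1000))),
    muscles = lapply(model$muscles, function(m) list(
      name = m$name, group = m$group, f_max_N = m$f_max,
      l_opt_mm = m$l_opt * 1000, l_slack_mm = m$l_slack * 1000,
      active = m$active, wraps = as.list(m$path$wraps),
      path = lapply(m$path$points, function(p)
        list(body = p$body, point_mm = as.list(p$point * 1000))))))
  cfg <- rapply(cfg, function(x) if (is.numeric(x)) signif(x, 9) else x,
                how = "replace")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @return `read_model_config()` returns the reconstructed
#'   `shoulder_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  num3 <- function(x, where) {
    v <- suppressWarnings(as.numeric(unlist(x)))
    if (length(v) != 3 || anyNA(v)) stop("config error at ", where,
                                         ": expected 3 numbers")
    v
  }
  c2f <- function(fc, where) {
    ang <- deg2rad(fc$angle_deg)
    frame(R = rot_axis_angle(num3(fc$axis, paste0(where, "$axis")), ang),
          p = num3(fc$origin_mm, paste0(where, "$origin_mm")) / 1000)
  }
  bodies <- lapply(cfg$bodies, function(b) body_segment(
    b$name, b$mass_kg, com = num3(b$com_mm, paste0("bodies/", b$name)) / 1000,
    point_loads = lapply(b$point_loads, function(pl)
      list(point = num3(pl$point_mm, "point_loads") / 1000,
           mass = pl$mass_kg))))
  joints <- lapply(cfg$joints, function(j) {
    if (!j$kind %in% c("fixed", "hinge", "gimbal", "ball")) {
      stop(sprintf("config error at joints/%s$kind: '%s' is not a joint kind",
                   j$name, j$kind))
    }
    joint_spec(j$name, j$kind, j$parent, j$child,
               parent_offset = c2f(j$parent_offset,
                                   paste0("joints/", j$name, "/parent_offset")),
               child_offset = c2f(j$child_offset,
                                  paste0("joints/", j$name, "/child_offset")),
               axes = lapply(j$axes, function(a)
                 num3(a, paste0("joints/", j$name, "/axes"))),
               limits = if (!is.null(j$limits_deg))
                 deg2rad(do.call(rbind, lapply(j$limits_deg, unlist))))
  })
  wraps <- lapply(cfg$wraps, function(w) wrap_surface(
    w$name, w$kind, w$body,
    center = num3(w$center_mm, paste0("wraps/", w$name)) / 1000,
    radii = as.numeric(unlist(w$radii_mm)) / 1000))
  muscles <- lapply(cfg$muscles, function(m) muscle_element(
    m$name, m$group, m$f_max_N, m$l_opt_mm / 1000, m$l_slack_mm / 1000,
    path = muscle_path(
      origin = list(body = m$path[[1]]$body,
                    point = num3(m$path[[1]]$point_mm, m$name) / 1000),
      insertion = list(body = m$path[[length(m$path)]]$body,
                       point = num3(m$path[[length(m$path)]]$point_mm,
                                    m$name) / 1000),
      via = lapply(m$path[-c(1, length(m$path))], function(p)
        list(body = p$body, point = num3(p$point_mm, m$name) / 1000)),
      wraps = unlist(m$wraps)),
    active = m$active))
  model <- chain_model(bodies, joints, muscles, wraps,
                       gravity = as.numeric(unlist(cfg$gravity)),
                       gh_joint = cfg$gh_joint, variant = cfg$variant)
  ji <- match(unlist(cfg$gh_joint_names), names(model$joints))
  model$gh_dofs <- which(model$dof_joint %in% ji)
  if (!is.null(cfg$scap_joint_name)) {
    model$scap_dof <- which(model$dof_joint ==
                              match(cfg$scap_joint_name, names(model$joints)))
  } else model$scap_dof <- integer(0)
  model
}

#' Write per-solution result CSVs
#'
#' Writes `forces.csv` (time, element, group, activation, force_N),
#' `jrf.csv` (time, angle_deg, jrf_N and world components) and
#' `reserves.csv` to a directory.
#'
#' @param sol a `shoulder_solution`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_solution_csvs <- function(sol, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(sol)
  utils::write.csv(df[, c("time", "element", "group", "activation",
                          "force_N")],
                   file.path(dir, sprintf("forces_%s.csv", sol$motion)),
                   row.names = FALSE)
  utils::write.csv(data.frame(time = sol$time, angle_deg = sol$angle_deg,
                              jrf_N = sol$jrf, fx = sol$jrf_vec[, 1],
                              fy = sol$jrf_vec[, 2], fz = sol$jrf_vec[, 3],
                              status = sol$status),
                   file.path(dir, sprintf("jrf_%s.csv", sol$motion)),
                   row.names = FALSE)
  utils::write.csv(cbind(data.frame(time = sol$time), sol$reserves),
                   file.path(dir, sprintf("reserves_%s.csv", sol$motion)),
                   row.names = FALSE)
  invisible(dir)
}

#' Marker trajectory CSV I/O
#'
#' Long-format marker files with columns `time_s, marker, x_m, y_m, z_m`.
#'
#' @param markerset a `marker_set`.
#' @param path CSV path.
#' @return `write_marker_csv()` returns `path` invisibly;
#'   `read_marker_csv()` returns a `marker_set` (marker body/point
#'   definitions are not stored in the CSV and are left `NULL`).
#' @export
write_marker_csv <- function(markerset, path) {
  nmk <- dim(markerset$traj)[3]
  nm <- dimnames(markerset$traj)[[3]]
  df <- do.call(rbind, lapply(seq_len(nmk), function(m) data.frame(
    time_s = markerset$time, marker = nm[m],
    x_m = markerset$traj[, 1, m], y_m = markerset$traj[, 2, m],
    z_m = markerset$traj[, 3, m])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_csv
#' @param rate capture rate metadata (Hz).
#' @export
read_marker_csv <- function(path, rate = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "marker", "x_m", "y_m", "z_m")
  if (!all(need %in% names(df))) {
    stop("marker CSV must have columns ", paste(need, collapse = ", "))
  }
  mk <- unique(df$marker)
  time <- sort(unique(df$time_s))
  arr <- array(NA_real_, c(length(time), 3, length(mk)),
               dimnames = list(NULL, c("x", "y", "z"), mk))
  for (m in seq_along(mk)) {
    sub <- df[df$marker == mk[m], ]
    sub <- sub[order(sub$time_s), ]
    arr[, , m] <- as.matrix(sub[, c("x_m", "y_m", "z_m")])
  }
  structure(list(markers = NULL, time = time, rate = rate, traj = arr),
            class = "marker_set")
}

#' Motion coordinate CSV I/O
#'
#' Long-format joint coordinate files with columns
#' `time_s, dof, angle_deg`.
#'
#' @param trajectory a `motion_trajectory` (or list with `time` and `Q`).
#' @param path CSV path.
#' @return `path` / a list with `time` and `Q` (radians).
#' @export
write_motion_csv <- function(trajectory, path) {
  dn <- colnames(trajectory$Q)
  df <- do.call(rbind, lapply(seq_along(dn), function(k) data.frame(
    time_s = trajectory$time, dof = dn[k],
    angle_deg = rad2deg(trajectory$Q[, k]))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_csv
#' @export
read_motion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "dof", "angle_deg")
  if (!all(need %in% names(df))) {
    stop("motion CSV must have columns ", paste(need, collapse = ", "))
  }
  dofs <- unique(df$dof)
  time <- sort(unique(df$time_s))
  Q <- matrix(NA_real_, length(time), length(dofs),
              dimnames = list(NULL, dofs))
  for (k in seq_along(dofs)) {
    sub <- df[df$dof == dofs[k], ]
    Q[, k] <- deg2rad(sub$angle_deg[order(sub$time_s)])
  }
  list(time = time, Q = Q)
}
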