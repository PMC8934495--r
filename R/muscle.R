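#' Muscle force elements
#'
#' Each muscle is a tensile force-generating element following a quasi-static
#' Hill-type model with a rigid tendon: the force-velocity factor is
#' identically 1 (no inertial or velocity effects in the quasi-static
#' protocol), so force depends only on activation and current geometry.
#'
#' @param name identifier.
#' @param group functional group, e.g. `"anterior_deltoid"`,
#'   `"middle_deltoid"`, `"posterior_deltoid"`, `"supraspinatus"`,
#'   `"infraspinatus"`, `"teres_minor"`, `"subscapularis"` or any other name.
#' @param f_max maximum isometric force (N), > 0.
#' @param l_opt optimal fibre length (m), > 0.
#' @param l_slack tendon slack length (m), >= 0.
#' @param path a [muscle_path()].
#' @param active logical; deactivated elements produce zero force at any
#'   activation and contribute zero columns to the equilibrium system.
#' @return A `muscle_element` object.
#' @export
muscle_element <- function(name, group, f_max, l_opt, l_slack, path,
                           active = TRUE) {
  stopifnot(f_max > 0, l_opt > 0, l_slack >= 0)
  structure(list(name = name, group = group, f_max = f_max, l_opt = l_opt,
                 l_slack = l_slack, path = path, active = isTRUE(active)),
            class = "muscle_element")
}

#' Active force-length curve
#'
#' Normalised active force capacity as a function of normalised fibre length
#' `l_norm = l_fiber / l_opt`: a Gaussian bell `exp(-((l_norm - 1)/0.45)^2)`,
#' equal to 1 at the optimal length, symmetric about it, and truncated to 0
#' outside `[0.5, 1.5]`.
#'
#' @param l_norm normalised fibre length (> 0), vectorised.
#' @return Values in `[0, 1]`.
#' @export
active_force_length <- function(l_norm) {
  if (any(l_norm <= 0)) stop("non-positive normalised fibre length")
  out <- exp(-((l_norm - 1) / 0.45)^2)
  out[l_norm < 0.5 | l_norm > 1.5] <- 0
  out
}

#' Passive force-length curve
#'
#' Exponential toe curve engaging beyond the optimal length; disabled by
#' default in the simulations (activation-driven forces only).
#'
#' @param l_norm normalised fibre length, vectorised.
#' @return Normalised passive force (multiplied by `f_max` by
#'   [muscle_force()]).
#' @export
passive_force_length <- function(l_norm) {
  out <- ifelse(l_norm > 1, (exp(5 * (l_norm - 1)) - 1) / (exp(5 * 0.5) - 1), 0)
  pmax(out, 0)
}

#' Quasi-static muscle force
#'
#' `F = a * f_max * fl(l_fiber/l_opt) [+ f_max * fp(l_fiber/l_opt)]` with a
#' rigid tendon, `l_fiber = path_length - l_slack` clamped at >= 0. Linear in
#' activation at fixed geometry (passive term excluded), which is what makes
#' the static-optimization problem a convex QP. A deactivated element returns
#' 0 regardless of activation.
#'
#' @param a activation in `[0, 1]`.
#' @param element a [muscle_element()].
#' @param path_length current path length (m).
#' @param passive logical, include the passive term (default `FALSE`).
#' @return Force (N), >= 0.
#' @export
muscle_force <- function(a, element, path_length, passive = FALSE) {
  stopifnot(a >= 0, a <= 1)
  if (!element$active) return(0)
  gain <- muscle_force_gain(element, path_length)
  Fp <- 0
  l_fiber <- max(path_length - element$l_slack, 0)
  if (passive && l_fiber > 0) {
    Fp <- element$f_max * passive_force_length(l_fiber / element$l_opt)
  }
  a * gain + Fp
}

#' Activation-to-force gain at current geometry
#'
#' `dF/da = f_max * fl(l_fiber/l_opt)` for an active element, 0 for a
#' deactivated one. Degenerate geometry (fibre length clamped to zero, or
#' outside the active range) yields zero gain with a warning.
#'
#' @inheritParams muscle_force
#' @return Gain (N per unit activation).
#' @export
muscle_force_gain <- function(element, path_length) {
  if (!element$active) return(0)
  l_fiber <- path_length - element$l_slack
  if (l_fiber <= 0) {
    warning(sprintf("muscle '%s': fibre length clamped to zero (path %.3f m <= slack %.3f m)",
                    element$name, path_length, element$l_slack))
    return(0)
  }
  element$f_max * active_force_length(l_fiber / element$l_opt)
}

#' Deactivate the supraspinatus
#'
#' In the prosthesis models the supraspinatus is rendered inactive, since it
#' is usually cut/impaired by the surgeon to place the implant. Elements stay
#' in the model (same muscle set in all variants) but produce zero force and
#' zero equilibrium columns. Idempotent.
#'
#' @param model a `shoulder_model`.
#' @return The model with all supraspinatus elements inactive.
#' @export
deactivate_supraspinatus <- function(model) {
  idx <- which(vapply(model$muscles, `[[`, "", "group") == "supraspinatus")
  if (length(idx) == 0) {
    warning("model has no supraspinatus elements; nothing to deactivate")
    return(model)
  }
  for (i in idx) model$muscles[[i]]$active <- FALSE
  model
}
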