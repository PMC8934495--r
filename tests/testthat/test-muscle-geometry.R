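# frames helper: static two-body scene with a wrap on the root
wrap_scene <- function(wrap) {
  list(frames = list(base = frame_identity(), arm = frame_identity()),
       wraps = stats::setNames(list(wrap), wrap$name))
}

test_that("sphere wrapping matches an independent shortest-path minimisation", {
  r <- 0.05
  w <- wrap_surface("s", "sphere", "base", center = c(0, 0, 0), radii = r)
  sc <- wrap_scene(w)
  A <- c(-2 * r, 0.2 * r, 0)
  B <- c(2 * r, 0.2 * r, 0)
  p <- muscle_path(origin = list(body = "base", point = A),
                   insertion = list(body = "arm", point = B), wraps = "s")
  sol <- solve_path(p, sc$frames, sc$wraps, "mu")
  expect_true(sol$wrapped[["s"]])

  # independent oracle: numeric minimisation over the two tangent-point
  # angles of |A-P(t1)| + arc + |P(t2)-B| in the wrap plane
  oracle <- stats::optim(c(2.5, 0.5), function(par) {
    P1 <- r * c(cos(par[1]), sin(par[1]), 0)
    P2 <- r * c(cos(par[2]), sin(par[2]), 0)
    sqrt(sum((A - P1)^2)) + r * abs(par[1] - par[2]) + sqrt(sum((P2 - B)^2))
  }, method = "BFGS", control = list(reltol = 1e-15))
  expect_equal(sol$length, oracle$value, tolerance = 1e-9)

  # clear line of sight: Euclidean distance, unwrapped
  A2 <- c(-2 * r, 2 * r, 0)
  p2 <- muscle_path(origin = list(body = "base", point = A2),
                    insertion = list(body = "arm", point = B), wraps = "s")
  sol2 <- solve_path(p2, sc$frames, sc$wraps, "mu")
  expect_false(sol2$wrapped[["s"]])
  expect_equal(sol2$length, sqrt(sum((B - A2)^2)), tolerance = 1e-12)

  # endpoint strictly inside the surface is an error naming both parties
  p3 <- muscle_path(origin = list(body = "base", point = c(0.1 * r, 0, 0)),
                    insertion = list(body = "arm", point = B), wraps = "s")
  expect_error(solve_path(p3, sc$frames, sc$wraps, "deltoid_x"),
               "deltoid_x.*s")
})

test_that("path length is continuous across the grazing boundary", {
  A <- c(-0.10, 0.03, 0)
  B <- c(0.10, 0.03, 0)
  lens <- sapply(seq(0.0295, 0.0305, length.out = 41), function(r) {
    w <- wrap_surface("s", "sphere", "base", c(0, 0, 0), r)
    sc <- wrap_scene(w)
    p <- muscle_path(origin = list(body = "base", point = A),
                     insertion = list(body = "arm", point = B), wraps = "s")
    solve_path(p, sc$frames, sc$wraps, "mu")$length
  })
  expect_lt(max(abs(diff(lens))), 1e-6)
  # grazing tie-break: exactly tangent segment reports unwrapped
  w <- wrap_surface("s", "sphere", "base", c(0, 0, 0), 0.03)
  sc <- wrap_scene(w)
  p <- muscle_path(origin = list(body = "base", point = A),
                   insertion = list(body = "arm", point = B), wraps = "s")
  expect_false(solve_path(p, sc$frames, sc$wraps, "mu")$wrapped[["s"]])
})

test_that("wrapped paths are invariant under rigid motion and never shorter than the chord", {
  set.seed(42)
  for (kind in c("sphere", "ellipsoid")) {
    radii <- if (kind == "sphere") 0.04 else c(0.05, 0.04, 0.02)
    w <- wrap_surface("w", kind, "base", c(0, 0, 0), radii)
    for (rep in 1:25) {
      A <- stats::rnorm(3, sd = 0.1)
      B <- stats::rnorm(3, sd = 0.1)
      if (sqrt(sum((A / radii)^2)) < 1.1 || sqrt(sum((B / radii)^2)) < 1.1) next
      sc <- wrap_scene(w)
      p <- muscle_path(origin = list(body = "base", point = A),
                       insertion = list(body = "arm", point = B), wraps = "w")
      sol <- solve_path(p, sc$frames, sc$wraps, "mu")
      expect_gte(sol$length, sqrt(sum((B - A)^2)) - 1e-12)

      # same scene rigidly rotated and translated
      R <- rot_axis_angle(unit3(stats::rnorm(3)), stats::runif(1, -pi, pi))
      t0 <- stats::rnorm(3)
      fr <- frame(R, t0)
      sc2 <- list(frames = list(base = fr, arm = fr), wraps = sc$wraps)
      sol2 <- solve_path(p, sc2$frames, sc$wraps, "mu")
      expect_equal(sol2$length, sol$length, tolerance = 1e-9)
    }
  }
})

test_that("tendon-excursion moment arms match geometric oracles", {
  # straight-line muscle crossing a hinge at perpendicular distance d
  d <- 0.07
  m <- toy_planar_model(att_x = c(d, d), att_y = c(-0.3, -0.3))
  q <- 0.2
  arm <- moment_arm(m, q, "mu1", 1)
  # oracle: perpendicular distance from the joint centre (origin) to the
  # muscle line at this pose
  fk <- forward_kinematics(m, q)
  A <- c(d, 0.10, 0)
  B <- frame_apply(fk$frames[["arm"]], c(0, -0.3, 0))
  u <- (B - A) / sqrt(sum((B - A)^2))
  perp <- sqrt(sum((A - sum(A * u) * u)^2))
  expect_equal(abs(arm), perp, tolerance = 1e-6)

  # a path entirely on one side of the joint has zero arm about it
  ns <- build_natural_shoulder()
  one_side <- muscle_path(origin = list(body = "arm", point = c(0, -0.1, 0)),
                          insertion = list(body = "arm", point = c(0, -0.2, 0)))
  m2 <- toy_planar_model()
  m2$muscles[["mu1"]]$path <- one_side
  expect_equal(moment_arm(m2, 0.3, "mu1", 1), 0)

  # sphere-wrapped path: finite-difference arm equals the perpendicular
  # distance from the joint centre to the tangent segment
  ns_q <- numeric(ns$ndof); ns_q[ns$gh_dofs[2]] <- deg2rad(30)
  fkn <- forward_kinematics(ns, ns_q)
  mu <- ns$muscles[["middle_deltoid_1"]]
  sol <- solve_path(mu$path, fkn$frames, ns$wraps, mu$name)
  expect_true(any(sol$wrapped))
  arm_fd <- moment_arm(ns, ns_q, "middle_deltoid_1", ns$gh_dofs[2])
  cor <- frame_compose(fkn$frames[["scapula"]],
                       ns$joints[["gleno_humeral"]]$parent_offset)$p
  seg <- sol$segments[[1]]
  uu <- unit3(seg$T1 - seg$from$w)
  v <- cor - seg$from$w
  perp2 <- sqrt(sum((v - sum(v * uu) * uu)^2))
  expect_equal(abs(arm_fd), perp2, tolerance = 1e-5)

  # moment arm magnitude never exceeds the largest distance from the joint
  # centre to any path point
  wp <- path_waypoints(sol)
  maxd <- max(sqrt(rowSums((wp - matrix(cor, nrow(wp), 3, byrow = TRUE))^2)))
  R <- moment_arm_matrix(ns, ns_q)
  expect_lt(max(abs(R[ns$gh_dofs, "middle_deltoid_1"])), maxd + 1e-9)

  expect_error(moment_arm(ns, ns_q, "middle_deltoid_1", 1, h = 1), "h")
})

test_that("implant wrap surfaces carry the published dimensions", {
  rsp <- build_wrap_for_implant("RSP")
  expect_equal(rsp$kind, "sphere")
  expect_equal(rsp$radii, rep(0.056 / 2, 3))  # 56 mm diameter

  dbsp <- build_wrap_for_implant("DBSP")
  expect_equal(dbsp$kind, "ellipsoid")
  expect_equal(2 * dbsp$radii, c(0.075, 0.075, 0.028))  # 75/75/28 mm

  # zero inflation recovers the raw implant dimensions
  rsp0 <- build_wrap_for_implant("RSP", deltoid_half_thickness = 0)
  expect_equal(2 * rsp0$radii[1], 0.036)
  dbsp0 <- build_wrap_for_implant("DBSP", deltoid_half_thickness = 0)
  expect_equal(2 * dbsp0$radii[1:2], c(0.055, 0.055))

  expect_error(build_wrap_for_implant("XYZ"))
  expect_error(wrap_surface("s", "sphere", "b", c(0, 0, 0), c(1, 2, 3)),
               "equal radii")
})
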