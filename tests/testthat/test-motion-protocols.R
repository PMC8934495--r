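test_that("trajectories span the published ranges with quasi-static endpoints", {
  ns <- build_natural_shoulder()
  tr <- generate_trajectory(ns, motion_spec("ABD", n_steps = 50))
  expect_equal(tr$angle_deg[1], 0)
  expect_equal(tr$angle_deg[50], 120)
  expect_true(all(diff(tr$angle_deg) >= 0))
  # scapulo-humeral rhythm split: GH elevation + scapular rotation = total
  expect_equal(unname(rad2deg(tr$Q[50, ns$scap_dof])), 30, tolerance = 1e-9)
  expect_equal(unname(rad2deg(tr$Q[50, ns$gh_dofs[2]])), 90, tolerance = 1e-9)
  # plane and axial stay zero in coronal-plane abduction
  expect_equal(max(abs(tr$Q[, ns$gh_dofs[c(1, 3)]])), 0)

  scp <- generate_trajectory(ns, motion_spec("SCP", n_steps = 5))
  expect_equal(unname(rad2deg(scp$Q[5, ns$gh_dofs[1]])), 30)  # scapular plane

  # n_steps = 2 gives exactly the endpoints
  tr2 <- generate_trajectory(ns, motion_spec("ABD", n_steps = 2))
  expect_equal(tr2$angle_deg, c(0, 120))

  # minimum-jerk profile has zero endpoint velocity and acceleration
  u <- seq(0, 1, length.out = 2001)
  s <- 10 * u^3 - 15 * u^4 + 6 * u^5
  v <- diff(s) / diff(u)
  expect_lt(abs(v[1]), 1e-5)
  expect_lt(abs(v[length(v)]), 1e-5)

  # IR runs 0 -> 40 internal; ER defaults to 40 -> 0 external, with a switch
  ir <- generate_trajectory(ns, motion_spec("IR", n_steps = 5))
  expect_equal(unname(rad2deg(ir$Q[5, ns$gh_dofs[3]])), 40, tolerance = 1e-9)
  er <- generate_trajectory(ns, motion_spec("ER", n_steps = 5))
  expect_equal(unname(rad2deg(er$Q[1, ns$gh_dofs[3]])), -40, tolerance = 1e-9)
  expect_equal(unname(rad2deg(er$Q[5, ns$gh_dofs[3]])), 0, tolerance = 1e-9)
  er2 <- generate_trajectory(ns, motion_spec("ER", er_reversed = FALSE,
                                             n_steps = 5))
  expect_equal(unname(rad2deg(er2$Q[5, ns$gh_dofs[3]])), -40, tolerance = 1e-9)

  expect_error(motion_spec("FLY"))
})

test_that("marker synthesis is exact at zero noise and deterministic under seed", {
  ns <- build_natural_shoulder()
  tr <- generate_trajectory(ns, motion_spec("ABD", n_steps = 6))
  mk <- synthesize_markers(ns, tr, noise_sd = 0)
  fk <- forward_kinematics(ns, tr$Q[3, ])
  defs <- default_marker_set()
  for (m in seq_along(defs)) {
    expect_equal(mk$traj[3, , m],
                 frame_apply(fk$frames[[defs[[m]]$body]], defs[[m]]$point),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(mk$rate, 100)

  mk1 <- synthesize_markers(ns, tr, noise_sd = 0.002, seed = 9)
  mk2 <- synthesize_markers(ns, tr, noise_sd = 0.002, seed = 9)
  expect_identical(mk1$traj, mk2$traj)
  mk3 <- synthesize_markers(ns, tr, noise_sd = 0.002, seed = 10)
  expect_false(identical(mk1$traj, mk3$traj))

  # empirical noise SD within 5% of the request over many samples
  trl <- generate_trajectory(ns, motion_spec("ABD", n_steps = 400))
  clean <- synthesize_markers(ns, trl, noise_sd = 0)
  noisy <- synthesize_markers(ns, trl, noise_sd = 0.003, seed = 4)
  emp <- stats::sd(noisy$traj - clean$traj)
  expect_lt(abs(emp - 0.003) / 0.003, 0.05)
})

test_that("inverse kinematics recovers the generating coordinates", {
  ns <- build_natural_shoulder()
  spec <- motion_spec("ABD", n_steps = 6)
  tr <- generate_trajectory(ns, spec)
  # keep every frame at >= 20 degrees of elevation: the plane/axial pair of
  # the Y-X-Y sequence is unidentifiable from markers at zero elevation
  tr$Q[, ns$gh_dofs[2]] <- tr$Q[, ns$gh_dofs[2]] + deg2rad(20)
  mk <- synthesize_markers(ns, tr, noise_sd = 0)
  ik <- inverse_kinematics(ns, mk)
  expect_true(all(ik$converged))
  expect_lt(max(abs(ik$Q - tr$Q)), 1e-6)
  expect_lt(max(ik$rms), 1e-9)

  # static pose, zero noise: zero residual
  one <- tr
  one$Q <- tr$Q[3, , drop = FALSE]
  one$time <- 0
  mk1 <- synthesize_markers(ns, one, noise_sd = 0)
  ik1 <- inverse_kinematics(ns, mk1)
  expect_lt(ik1$rms[1], 1e-10)

  expect_error(inverse_kinematics(ns, structure(list(
    markers = default_marker_set()[1:2],
    traj = mk$traj[, , 1:2, drop = FALSE]), class = "marker_set")),
    "3 non-collinear|3 markers")
})

test_that("noisy-marker recovery is unbiased at the capture noise level", {
  ns <- build_natural_shoulder()
  q_true <- numeric(ns$ndof)
  q_true[ns$scap_dof] <- deg2rad(8)
  q_true[ns$gh_dofs] <- deg2rad(c(10, 45, 5))
  one <- list(time = 0, Q = matrix(q_true, 1), spec = motion_spec("ABD"))
  errs <- sapply(1:100, function(s) {
    mk <- synthesize_markers(ns, one, noise_sd = 0.002, seed = s)
    ik <- inverse_kinematics(ns, mk, q0 = q_true)
    c(rms = ik$rms[1], err = unname(ik$Q[1, ns$gh_dofs[2]] - q_true[ns$gh_dofs[2]]))
  })
  # residual reflects the injected noise level
  expect_lt(abs(mean(errs["rms", ]) - 0.002) / 0.002, 0.35)
  # elevation recovered without bias (mean error below 0.2 degrees)
  expect_lt(abs(rad2deg(mean(errs["err", ]))), 0.2)
})

test_that("time stretching rescales implied derivatives without touching samples", {
  ns <- build_natural_shoulder()
  tr <- generate_trajectory(ns, motion_spec("ABD", n_steps = 12))
  # identity at factor 1, composition multiplies factors
  expect_identical(time_stretch(tr, 1)$time, tr$time)
  expect_equal(time_stretch(time_stretch(tr, 20), 50)$time,
               time_stretch(tr, 1000)$time)
  expect_identical(time_stretch(tr, 1000)$Q, tr$Q)
  # acceleration drops by exactly factor^2
  a0 <- peak_angular_acceleration(tr)
  a1 <- peak_angular_acceleration(time_stretch(tr, 1000))
  expect_equal(a1 / a0, 1e-6, tolerance = 1e-12)

  # a noisy capture fails a quasi-static filter that the stretched one passes
  noisy <- tr
  set.seed(1)
  noisy$Q <- noisy$Q + matrix(stats::rnorm(length(noisy$Q), sd = 0.01),
                              nrow(noisy$Q))
  expect_gt(peak_angular_acceleration(noisy), 1e-3)
  expect_lt(peak_angular_acceleration(time_stretch(noisy, 1000)), 1e-3)
  expect_error(time_stretch(tr, 0))
})
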