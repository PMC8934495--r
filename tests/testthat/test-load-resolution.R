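test_that("required torques balance gravity exactly", {
  # hanging arm: zero torque about the hinge
  hm <- toy_hinge_model(m = 2, d = 0.25, hand_load = 2)
  expect_equal(required_torques(hm, 0), 0, tolerance = 1e-12)
  # horizontal arm: 9.81 (m d1 + m_load d2)
  tau <- required_torques(hm, pi / 2)
  expect_equal(abs(tau), 9.81 * (2 * 0.25 + 2 * 0.5), tolerance = 1e-9)
  # random poses on a random chain: matches the potential-energy gradient
  m <- random_chain(depth = 4, seed = 77)
  for (r in 1:5) {
    q <- stats::runif(m$ndof, -1, 1)
    tau <- suppressWarnings(required_torques(m, q))
    for (k in seq_len(m$ndof)) {
      qp <- q; qp[k] <- qp[k] + 1e-6
      qm <- q; qm[k] <- qm[k] - 1e-6
      fd <- (suppressWarnings(potential_energy(m, qp)) -
               suppressWarnings(potential_energy(m, qm))) / 2e-6
      expect_lt(abs(tau[k] - fd), 1e-8 * max(1, abs(tau[k])))
    }
  }
})

test_that("static optimization solves small systems in closed form", {
  mk_sys <- function(R, f_gain, tau, g = 1) {
    structure(list(R = R, f_gain = f_gain, tau_required = tau,
                   reserve_gains = rep(g, nrow(R)),
                   dofs = seq_len(nrow(R)),
                   muscle_names = paste0("m", seq_along(f_gain))),
              class = "equilibrium_system")
  }
  # one muscle, one DOF, torque within capacity: a = tau / (r f)
  r <- 0.03; f <- 800; tau <- 9
  rep1 <- static_optimization(mk_sys(matrix(r, 1, 1), f, tau))
  expect_equal(unname(rep1$activations), tau / (r * f), tolerance = 1e-6)
  expect_equal(rep1$status, "optimal")
  expect_lte(rep1$residual_norm, 1e-6)
  # two identical muscles sharing one DOF: equal split
  rep2 <- static_optimization(mk_sys(matrix(c(r, r), 1, 2), c(f, f), tau))
  expect_equal(unname(rep2$activations[1]), unname(rep2$activations[2]),
               tolerance = 1e-9)
  expect_equal(unname(rep2$activations[1]), tau / (2 * r * f),
               tolerance = 1e-6)
  # torque beyond capacity: activations saturate and reserves engage
  rep3 <- static_optimization(mk_sys(matrix(r, 1, 1), f, 5 * r * f))
  expect_equal(unname(rep3$activations), 1, tolerance = 1e-9)
  expect_equal(rep3$status, "infeasible_reserves_used")
  expect_equal(unname(rep3$reserve_torques), 4 * r * f, tolerance = 1e-3)
  # activations stay inside the box
  expect_true(all(rep3$activations >= -1e-12 & rep3$activations <= 1 + 1e-12))
})

test_that("the QP matches a brute-force activation grid on a 3-muscle/2-DOF toy", {
  R <- matrix(c(0.05, 0.02,
                -0.03, 0.06,
                0.025, 0.04), 2, 3)
  f_gain <- c(1, 1, 1)
  tau <- c(0.03, 0.035)
  sys <- structure(list(R = R, f_gain = f_gain, tau_required = tau,
                        reserve_gains = c(1, 1), dofs = 1:2,
                        muscle_names = paste0("m", 1:3)),
                   class = "equilibrium_system")
  rep1 <- static_optimization(sys)
  oracle <- grid_qp_oracle(R %*% diag(f_gain), tau, G = c(1, 1), res = 1e-3)
  expect_lt(abs(rep1$objective_value - oracle$obj), 1e-4)
  expect_lt(max(abs(unname(rep1$activations) - oracle$a)), 2e-3)

  # adding a muscle (an extra column) never increases the optimum
  sys2 <- sys
  sys2$R <- cbind(R, c(0.03, 0.03))
  sys2$f_gain <- c(f_gain, 1)
  sys2$muscle_names <- paste0("m", 1:4)
  rep2 <- static_optimization(sys2)
  expect_lte(rep2$objective_value, rep1$objective_value + 1e-12)
})

test_that("joint reaction forces satisfy an independent free-body balance", {
  # no muscles, arm hanging: |JRF| = total distal weight
  hm <- toy_hinge_model(m = 2, d = 0.25, hand_load = 2)
  j <- joint_reaction_force(hm, 0, numeric(0), joint = "hinge")
  expect_equal(j$magnitude, (2 + 2) * 9.81, tolerance = 1e-9)
  expect_equal(j$force_world, c(0, (2 + 2) * 9.81, 0), tolerance = 1e-9)

  # planar two-muscle toy: independent Newton balance written out by hand
  m <- toy_planar_model(m = 2, d = 0.25)
  th <- 0.5
  sys <- equilibrium_system(m, th)
  rep1 <- static_optimization(sys)
  j2 <- joint_reaction_force(m, th, rep1$forces, joint = "hinge")
  fk <- forward_kinematics(m, th)
  total <- 2 * c(0, -9.81, 0)
  for (i in 1:2) {
    mu <- m$muscles[[i]]
    A <- mu$path$points[[1]]$point           # base attachment, world = local
    B <- frame_apply(fk$frames[["arm"]], mu$path$points[[2]]$point)
    u <- (A - B) / sqrt(sum((A - B)^2))      # pull on the arm, toward origin
    total <- total + rep1$forces[[mu$name]] * u
  }
  expect_lt(max(abs(j2$force_world - (-total))), 1e-6)

  # scaling every mass by k scales the JRF magnitude by k (within capacity)
  for (k in c(0.5, 1.5)) {
    mk <- toy_planar_model(m = 2 * k, d = 0.25)
    sk <- equilibrium_system(mk, th)
    rk <- static_optimization(sk)
    jk <- joint_reaction_force(mk, th, rk$forces, joint = "hinge")
    expect_equal(jk$magnitude, k * j2$magnitude, tolerance = 1e-4)
  }

  # JRF magnitude is invariant under a global rigid rotation of the scene
  # together with gravity
  Rg <- rot_axis_angle(unit3(c(1, 2, 0.5)), 0.8)
  mr <- toy_planar_model(m = 2, d = 0.25)
  mr$gravity <- as.numeric(Rg %*% mr$gravity)
  mr$joints[["hinge"]]$parent_offset <- frame(R = Rg)
  for (i in seq_along(mr$muscles)) {  # rotate the root-fixed attachments too
    pt <- mr$muscles[[i]]$path$points[[1]]$point
    mr$muscles[[i]]$path$points[[1]]$point <- as.numeric(Rg %*% pt)
  }
  sysr <- equilibrium_system(mr, th)
  repr <- static_optimization(sysr)
  jr <- joint_reaction_force(mr, th, repr$forces, joint = "hinge")
  expect_equal(jr$magnitude, j2$magnitude, tolerance = 1e-6)
})
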