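# toy fixtures built in code, shared across the test files

# single hinge: root + one arm body; point mass m at distance d along -y of
# the arm, hinge axis z at the root origin, so the arm swings in the x-y
# plane. theta = 0 means the arm hangs straight down.
toy_hinge_model <- function(m = 1.5, d = 0.3, axis = c(0, 0, 1),
                            hand_load = 0) {
  bodies <- list(
    body_segment("base", 0),
    body_segment("arm", m, com = c(0, -d, 0),
                 point_loads = if (hand_load > 0)
                   list(list(point = c(0, -2 * d, 0), mass = hand_load))
                 else list()))
  joints <- list(joint_spec("hinge", "hinge", "base", "arm",
                            axes = list(axis)))
  chain_model(bodies, joints, variant = "toy_hinge")
}

# random open chain of given depth with mixed joint kinds, deterministic in
# the seed; every body carries some mass so gravity checks are non-trivial
random_chain <- function(depth = 4, seed = 1) {
  set.seed(seed)
  kinds <- sample(c("hinge", "gimbal", "ball", "fixed"), depth, replace = TRUE)
  bodies <- list(body_segment("b0", 1))
  joints <- list()
  rand_axis <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (i in seq_len(depth)) {
    bodies[[i + 1]] <- body_segment(paste0("b", i), stats::runif(1, 0.5, 3),
                                    com = stats::rnorm(3, sd = 0.1))
    nd <- joint_dof_count(kinds[i])
    axes <- replicate(nd, rand_axis(), simplify = FALSE)
    # keep consecutive gimbal/ball axes well separated
    if (nd >= 2) {
      axes[[2]] <- unit3(axes[[2]] - sum(axes[[2]] * axes[[1]]) * axes[[1]])
    }
    if (nd == 3) {
      axes[[3]] <- unit3(pracma_cross(axes[[1]], axes[[2]]))
    }
    joints[[i]] <- joint_spec(
      paste0("j", i), kinds[i], paste0("b", i - 1), paste0("b", i),
      parent_offset = frame(rot_axis_angle(rand_axis(), stats::runif(1, -1, 1)),
                            stats::rnorm(3, sd = 0.2)),
      child_offset = frame(rot_axis_angle(rand_axis(), stats::runif(1, -1, 1)),
                           stats::rnorm(3, sd = 0.2)),
      axes = axes)
  }
  chain_model(bodies, joints, variant = "toy_random")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# planar model with two muscles acting across one hinge (x-y plane, axis z),
# used for the QP closed forms and the free-body JRF oracle
toy_planar_model <- function(m = 2, d = 0.25, f_max = c(500, 500),
                             att_y = c(-0.05, -0.08), att_x = c(0.05, 0.08)) {
  bodies <- list(
    body_segment("base", 0),
    body_segment("arm", m, com = c(0, -d, 0)))
  joints <- list(joint_spec("hinge", "hinge", "base", "arm",
                            axes = list(c(0, 0, 1))))
  muscles <- lapply(seq_along(f_max), function(i) {
    muscle_element(
      paste0("mu", i), "other", f_max[i], l_opt = 1, l_slack = 0,
      path = muscle_path(
        origin = list(body = "base", point = c(att_x[i], 0.10, 0)),
        insertion = list(body = "arm", point = c(0, att_y[i], 0))))
  })
  chain_model(bodies, joints, muscles = muscles, variant = "toy_planar",
              gh_joint = "hinge")
}

# brute-force activation-grid oracle for small static-optimization systems:
# exhaustive vectorised search over the activation box, penalised exactly
# like the solver's objective. Two stages reach an effective 1e-3 grid
# resolution: a coarse global sweep, then a full-resolution sweep of the
# neighbourhood of the coarse optimum (valid because the objective is
# convex, so the optimum cannot hide away from the coarse minimiser).
grid_qp_oracle <- function(M, tau, G, w_reserve = 1e4, res = 1e-3,
                           coarse = 0.02) {
  n <- ncol(M)
  sweep_best <- function(grids) {
    A <- as.matrix(expand.grid(grids))
    S <- matrix(tau, nrow(A), length(tau), byrow = TRUE) - A %*% t(M)
    obj <- rowSums(A^2) + w_reserve * rowSums((S / rep(G, each = nrow(S)))^2)
    i <- which.min(obj)
    list(obj = obj[i], a = as.numeric(A[i, ]))
  }
  # convexity bound: the grid argmin lies within
  # sqrt(kappa(H)) * sqrt(n)/2 * step of the true minimiser, so each stage's
  # refinement window is sized by the Hessian condition number
  H <- 2 * (diag(n) + w_reserve * crossprod(M / G))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  kappa <- sqrt(max(ev) / min(ev)) * sqrt(n) / 2
  cur <- sweep_best(replicate(n, seq(0, 1, by = coarse), simplify = FALSE))
  step <- coarse
  while (step > res) {
    window <- kappa * step + 10 * res
    step <- max(res, step / 5)
    grids <- lapply(seq_len(n), function(i) {
      seq(max(0, cur$a[i] - window), min(1, cur$a[i] + window), by = step)
    })
    cur <- sweep_best(grids)
  }
  cur
}
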