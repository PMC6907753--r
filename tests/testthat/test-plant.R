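test_that("spring interaction force follows the linear law and Newton's third law", {
  x <- initial_state(default_plant())
  ix <- state_index()
  x[ix$p1] <- c(0.01, 0)
  x[ix$p2] <- c(0, 0)
  f <- interaction_force(x, 150)
  expect_equal(f$F1, c(-1.5, 0))
  expect_equal(f$F2, c(1.5, 0))

  set.seed(7)
  for (r in 1:20) {
    xr <- rnorm(22, sd = 0.1)
    fr <- interaction_force(xr, runif(1, 0, 500))
    expect_identical(fr$F1, -fr$F2)     # exact, by construction
  }
  expect_equal(interaction_force(initial_state(default_plant()), 150)$F1,
               c(0, 0))                 # zero extension
  expect_error(interaction_force(x, -1), "k")
})

test_that("plant construction validates inputs and exposes the documented structure", {
  expect_error(build_plant(dyad_params(dt = -0.01)), "dt")
  bad <- dyad_params()
  bad$motor_noise_cov_1 <- matrix(c(1, 2, 0, 1), 2)  # not symmetric
  expect_error(build_plant(bad), "positive semi-definite")

  pl <- default_plant()
  ix <- pl$ix
  expect_length(ix$player1, 8)
  expect_length(ix$player2, 8)
  expect_equal(dim(pl$A), c(22, 22))
  expect_equal(dim(pl$B1), c(22, 2))
  # goal rows: identity in A, zero in B
  expect_equal(pl$A[ix$goal, ], diag(22)[ix$goal, ])
  expect_equal(pl$B1[ix$goal, ], matrix(0, 6, 2))
  # spring coupling blocks are symmetric across players (equal masses)
  expect_equal(pl$A[ix$v1, ix$p2], pl$A[ix$v2, ix$p1], tolerance = 1e-12)
  expect_equal(pl$A[ix$v1, ix$p1], pl$A[ix$v2, ix$p2], tolerance = 1e-12)
})

test_that("a decoupled plant leaves the unforced player and goal block untouched", {
  pl0 <- build_plant(dyad_params(spring_k = 0))
  x <- initial_state(pl0)
  x_start <- x
  for (t in 1:60) x <- step_dynamics(pl0, x, u1 = c(1, -0.5), u2 = c(0, 0))
  ix <- pl0$ix
  expect_identical(x[ix$player2], x_start[ix$player2])
  expect_identical(x[ix$goal], x_start[ix$goal])
  expect_gt(sum(abs(x[ix$player1] - x_start[ix$player1])), 0)
})

test_that("goal block is constant under random forced dynamics", {
  pl <- default_plant()
  set.seed(1)
  x <- initial_state(pl)
  g0 <- x[pl$ix$goal]
  for (t in 1:100) x <- step_dynamics(pl, x, rnorm(2), rnorm(2), noise = TRUE)
  expect_identical(x[pl$ix$goal], g0)
})

test_that("repeated stepping matches one-shot linear-system unrolling", {
  pl <- default_plant()
  set.seed(42)
  U1 <- matrix(rnorm(40), 20, 2)
  U2 <- matrix(rnorm(40), 20, 2)
  x <- x0 <- initial_state(pl)
  for (t in 1:20) x <- step_dynamics(pl, x, U1[t, ], U2[t, ])
  # oracle: x_T = A^T x0 + sum_k A^(T-1-k) (B1 u1_k + B2 u2_k)
  Apow <- diag(22)
  acc <- numeric(22)
  for (k in 20:1) {
    acc <- acc + Apow %*% (pl$B1 %*% U1[k, ] + pl$B2 %*% U2[k, ])
    Apow <- Apow %*% pl$A
  }
  oracle <- drop(Apow %*% x0 + acc)
  expect_equal(x, oracle, tolerance = 1e-10)
})

test_that("stepping is deterministic given a seed and at equilibrium", {
  pl <- default_plant()
  x <- initial_state(pl)  # p1 = p2, at rest
  x1 <- step_dynamics(pl, x, c(0, 0), c(0, 0))
  expect_equal(x1[pl$ix$p1], x[pl$ix$p1])
  expect_equal(x1[pl$ix$p2], x[pl$ix$p2])
  a <- step_dynamics(pl, x, c(1, 1), c(-1, 0), noise = TRUE, seed = 99)
  b <- step_dynamics(pl, x, c(1, 1), c(-1, 0), noise = TRUE, seed = 99)
  expect_identical(a, b)
  expect_error(step_dynamics(pl, x[1:10], c(0, 0), c(0, 0)), "22")
})

test_that("zero-order hold is exact for held inputs and Euler converges to it", {
  p1 <- dyad_params(dt = 0.01, horizon_T = 50)
  p2 <- dyad_params(dt = 0.005, horizon_T = 100)
  zoh1 <- build_plant(p1)
  zoh2 <- build_plant(p2)
  u1 <- c(0.5, -0.2); u2 <- c(-0.1, 0.4)
  xa <- initial_state(zoh1); xb <- initial_state(zoh2)
  for (t in 1:50) xa <- step_dynamics(zoh1, xa, u1, u2)
  for (t in 1:100) xb <- step_dynamics(zoh2, xb, u1, u2)
  expect_equal(xa, xb, tolerance = 1e-9)  # ZOH is exact at sample times

  # Euler error halves (at least) when dt halves
  eu1 <- build_plant(p1, method = "euler")
  eu2 <- build_plant(p2, method = "euler")
  xe1 <- initial_state(eu1); xe2 <- initial_state(eu2)
  for (t in 1:50) xe1 <- step_dynamics(eu1, xe1, u1, u2)
  for (t in 1:100) xe2 <- step_dynamics(eu2, xe2, u1, u2)
  err1 <- max(abs(xe1 - xa))
  err2 <- max(abs(xe2 - xa))
  expect_lt(err2, err1 / 1.8)
})

test_that("sensory models expose the documented channels per group", {
  pl <- default_plant()
  sH <- build_sensory_model("H", 1, pl)
  sVH <- build_sensory_model("VH", 1, pl)
  sPV <- build_sensory_model("PV", 1, pl)
  expect_equal(nrow(sH$H_obs), nrow(sVH$H_obs))
  expect_gt(nrow(sPV$H_obs), nrow(sH$H_obs))
  # H and VH share channels; only the force-noise magnitude differs
  expect_identical(sH$H_obs, sVH$H_obs)
  fi <- grep("force", sH$labels)
  expect_gt(sH$R_v[fi[1], fi[1]], sVH$R_v[fi[1], fi[1]])
  expect_error(build_sensory_model("X", 1, pl))

  # force channel is consistent with interaction_force before noise
  x <- initial_state(pl)
  x[pl$ix$p1] <- x[pl$ix$p1] + c(0.01, 0)
  y <- observe(sH, x, noise = FALSE)
  expect_equal(unname(y[fi]), interaction_force(x, pl$spring_k)$F1,
               tolerance = 1e-12)
})

test_that("observe is the noiseless projection plus seeded Gaussian noise", {
  pl <- default_plant()
  s <- build_sensory_model("PV", 2, pl)
  x <- initial_state(pl)
  y0 <- observe(s, x, noise = FALSE)
  expect_equal(unname(y0), drop(s$H_obs %*% x))
  expect_identical(observe(s, x, seed = 3), observe(s, x, seed = 3))

  # Monte-Carlo covariance check on the noise
  set.seed(5)
  draws <- t(replicate(20000, observe(s, x) - y0))
  emp <- cov(draws)
  expect_equal(unname(diag(emp)), diag(s$R_v), tolerance = 0.05)
  off <- emp[upper.tri(emp)]
  expect_lt(max(abs(off)), 4 * max(diag(s$R_v)) / sqrt(nrow(draws)))
})
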