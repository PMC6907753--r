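test_that("no-partner gains equal an independent LQR oracle", {
  pl <- small_plant(T = 60)
  c1 <- build_cost(1, pl)
  np <- solve_no_partner(pl, c1)
  oracle <- oracle_lqr(pl$A, pl$B1, c1$Q_seq, c1$R)
  for (t in c(1, 20, 59)) {
    expect_equal(np$L1_seq[[t]], oracle[[t]], tolerance = 1e-8)
  }
})

test_that("solve_nash reduces to the single-player LQR when the partner is absent", {
  pl <- small_plant(T = 60)
  c1 <- build_cost(1, pl)
  w0 <- default_cost_weights()
  w0$w_vp <- 0; w0$w_target <- 0; w0$w_stop <- 0; w0$w_force <- 0
  c2z <- build_cost(2, pl, w0)        # pure effort cost: optimal u2 = 0
  pl0 <- pl
  pl0$B2 <- matrix(0, 22, 2)          # player 2 cannot act
  ps <- solve_nash(pl0, c1, c2z)
  oracle <- oracle_lqr(pl$A, pl$B1, c1$Q_seq, c1$R)
  err <- max(vapply(seq_along(oracle),
                    function(t) max(abs(ps$L1_seq[[t]] - oracle[[t]])), 0))
  expect_lt(err, 1e-8)
})

test_that("a fully symmetric game yields label-swap-symmetric gains", {
  pl <- small_plant(T = 50)
  c1 <- build_cost(1, pl, via_time = 25)
  c2 <- build_cost(2, pl, via_time = 25)
  ps <- solve_nash(pl, c1, c2)
  perm <- swap_permutation()
  for (t in c(1, 25, 49)) {
    expect_equal(ps$L1_seq[[t]][, perm], ps$L2_seq[[t]], tolerance = 1e-8)
  }
})

test_that("Nash gains admit no unilateral improvement; corrupted gains do", {
  pl <- small_plant(T = 80)
  cs <- small_costs(pl)
  ps <- solve_nash(pl, cs[[1]], cs[[2]])
  rep <- verify_nash(pl, cs[[1]], cs[[2]], ps, n_perturb = 40, seed = 2)
  expect_lte(rep$max_improvement_1, 1e-6 * rep$J1)
  expect_lte(rep$max_improvement_2, 1e-6 * rep$J2)
  expect_lt(abs(rep$br_improvement_1), 1e-8 * rep$J1)
  expect_lt(abs(rep$br_improvement_2), 1e-8 * rep$J2)

  bad <- ps
  for (t in 30:50) bad$L2_seq[[t]] <- bad$L2_seq[[t]] * 1.5
  repb <- verify_nash(pl, cs[[1]], cs[[2]], bad, n_perturb = 5, seed = 2)
  expect_gt(repb$br_improvement_2, 0)

  rep0 <- verify_nash(pl, cs[[1]], cs[[2]], ps, n_perturb = 0)
  expect_identical(rep0$n_perturb, 0L)
  expect_true(is.na(rep0$max_improvement_1))
})

test_that("with no coupling and no force cost, Nash equals no-partner", {
  w <- default_cost_weights(); w$w_force <- 0
  pl <- small_plant(T = 60, spring_k = 0)
  c1 <- build_cost(1, pl, w); c2 <- build_cost(2, pl, w)
  ps <- solve_nash(pl, c1, c2)
  np1 <- solve_no_partner(pl, c1)
  np2 <- solve_no_partner(pl, c2)
  err <- max(mapply(function(a, b) max(abs(a - b)), ps$L1_seq, np1$L1_seq),
             mapply(function(a, b) max(abs(a - b)), ps$L2_seq, np2$L2_seq))
  expect_lt(err, 1e-9)
})

test_that("solve_nash matches a brute-force grid Nash on a one-step toy game", {
  # two scalar positions, one control step each: x' = x + [u1, u2]
  A <- diag(2)
  B1 <- matrix(c(1, 0), 2, 1)
  B2 <- matrix(c(0, 1), 2, 1)
  # each player wants own coordinate at a target but dislikes separation
  Q1 <- matrix(c(2, -0.5, -0.5, 0.5), 2)   # PSD coupling cost
  Q2 <- matrix(c(0.5, -0.5, -0.5, 2), 2)
  R <- matrix(0.8)
  toy_plant <- list(A = A, B1 = B1, B2 = B2, horizon_T = 2L)
  mk <- function(Q) structure(list(Q_seq = list(matrix(0, 2, 2), Q),
                                   R = R, T = 2L), class = "cost_spec")
  ps <- solve_nash(toy_plant, mk(Q1), mk(Q2))
  x0 <- c(1, -1)
  u_nash <- c(-drop(ps$L1_seq[[1]] %*% x0), -drop(ps$L2_seq[[1]] %*% x0))

  # brute force: iterate best responses on a fine action grid
  grid <- seq(-3, 3, by = 0.002)
  J <- function(pid, u1, u2) {
    x1 <- x0 + c(u1, u2)
    Q <- if (pid == 1) Q1 else Q2
    drop(x1 %*% Q %*% x1) + drop(R) * (if (pid == 1) u1 else u2)^2
  }
  u <- c(0, 0)
  for (it in 1:50) {
    u_new <- c(grid[which.min(vapply(grid, function(a) J(1, a, u[2]), 0))],
               grid[which.min(vapply(grid, function(a) J(2, u[1], a), 0))])
    if (max(abs(u_new - u)) < 1e-9) break
    u <- u_new
  }
  expect_equal(u_nash, u, tolerance = 0.005)  # within grid resolution
})

test_that("closed-loop rollouts are deterministic and reproduce study contrasts", {
  pl <- small_plant(T = 80)
  cs <- small_costs(pl)
  ps <- solve_nash(pl, cs[[1]], cs[[2]])
  r1 <- simulate_closed_loop(pl, ps)
  r2 <- simulate_closed_loop(pl, ps)
  expect_identical(r1$states, r2$states)

  # unconnected rollout: each player passes only the own via-point
  w0 <- default_cost_weights(); w0$w_force <- 0
  pl0 <- small_plant(T = 80, spring_k = 0)
  c10 <- build_cost(1, pl0, w0); c20 <- build_cost(2, pl0, w0)
  ps0 <- solve_nash(pl0, c10, c20)
  r0 <- simulate_closed_loop(pl0, ps0)
  g <- pl0$geometry
  expect_lt(compute_MD(r0$p1, g$vp1), 0.003)
  expect_lt(compute_MD(r0$p2, g$vp2), 0.003)
  expect_gt(compute_MD(r0$p1, g$vp2), 0.02)
  expect_gt(compute_MD(r0$p2, g$vp1), 0.02)
})

test_that("no-partner play shows role alternation absent under Nash", {
  pl <- default_plant()
  cs <- small_costs(pl)
  np <- policy_set(L1_seq = solve_no_partner(pl, cs[[1]])$L1_seq,
                   L2_seq = solve_no_partner(pl, cs[[2]])$L2_seq)
  ps <- solve_nash(pl, cs[[1]], cs[[2]])
  rn <- simulate_closed_loop(pl, np)
  rs <- simulate_closed_loop(pl, ps)
  g <- pl$geometry
  P1 <- compute_power(rn$F1, rn$v1)
  P2 <- compute_power(rn$F2, rn$v2)
  t2 <- crossing_time(rn$p2, g$vp2)
  w2 <- max(1, t2 - 30):t2
  # near vp2: player 2 leads (negative power), player 1 is pulled (positive)
  expect_gt(mean(P1[w2]), 0)
  expect_lt(mean(P2[w2]), 0)
  t1 <- crossing_time(rn$p1, g$vp1)
  w1 <- max(1, t1 - 30):t1
  expect_lt(mean(P1[w1]), 0)
  expect_gt(mean(P2[w1]), 0)
  # peak interaction power and force are larger under no-partner than Nash
  Ps1 <- compute_power(rs$F1, rs$v1); Ps2 <- compute_power(rs$F2, rs$v2)
  expect_gt(max(abs(c(P1, P2))), max(abs(c(Ps1, Ps2))))
  expect_gte(max(sqrt(rowSums(rn$F1^2))), max(sqrt(rowSums(rs$F1^2))))
})
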