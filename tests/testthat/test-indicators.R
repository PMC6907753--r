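test_that("Savitzky-Golay filtering reproduces polynomials and their derivatives", {
  dt <- 0.01
  t <- seq(0, 2, by = dt)
  pos <- cbind(0.1 * t^3 - 0.2 * t^2 + 0.05 * t, -0.05 * t^3 + 0.1 * t)
  out <- smooth_and_differentiate(pos, dt)
  core <- 20:(length(t) - 20)   # away from boundaries
  expect_equal(out$position[core, ], pos[core, ], tolerance = 1e-9)
  vel_true <- cbind(0.3 * t^2 - 0.4 * t + 0.05, -0.15 * t^2 + 0.1)
  expect_equal(out$velocity[core, ], vel_true[core, ], tolerance = 1e-7)
  acc_true <- cbind(0.6 * t - 0.4, -0.3 * t)
  expect_equal(out$acceleration[core, ], acc_true[core, ], tolerance = 1e-6)

  # constant position: zero velocity everywhere
  const <- matrix(0.02, 150, 2)
  outc <- smooth_and_differentiate(const, dt)
  expect_equal(max(abs(outc$velocity)), 0, tolerance = 1e-12)

  # smoothing reduces seeded white noise on a sine
  set.seed(6)
  clean <- cbind(sin(2 * pi * 0.5 * t), cos(2 * pi * 0.5 * t)) * 0.05
  noisy <- clean + matrix(rnorm(length(t) * 2, sd = 0.003), ncol = 2)
  outn <- smooth_and_differentiate(noisy, dt)
  expect_lt(var(c(outn$position[core, ] - clean[core, ])),
            var(c(noisy[core, ] - clean[core, ])))
  expect_error(smooth_and_differentiate(pos[1:10, ], dt), "window")
})

test_that("speed-threshold segmentation finds first and last crossings", {
  speed <- c(rep(0, 49), seq(0, 0.1, length.out = 52)[-1],
             rep(0.1, 49), seq(0.1, 0, length.out = 52)[-1], rep(0, 49))
  seg <- segment_movement(speed, threshold = 0.02)
  scan_start <- min(which(speed > 0.02))
  scan_end <- max(which(speed > 0.02))
  expect_identical(seg$start, scan_start)
  expect_identical(seg$end, scan_end)
  expect_error(segment_movement(rep(0, 100)), class = "no_movement")
  expect_error(segment_movement(c(-1, 1)), "non-negative")

  # minimum-jerk fixture speed against a brute-force scan
  rec <- make_fixture_trial(fixture_spec(tau = 0))
  sp <- smooth_and_differentiate(rec$p1, rec$dt)$speed
  seg2 <- segment_movement(sp)
  expect_identical(seg2$start, min(which(sp > 0.02)))
  expect_identical(seg2$end, max(which(sp > 0.02)))
})

test_that("score calibration matches the displayed saturation and midpoint", {
  p <- score_params()
  # d at the midpoint: raw logistic value is exactly 50
  path_mid <- matrix(c(p$d0, 0), 1, 2)   # distance d0 from a vp at origin
  expect_equal(compute_score(path_mid, NULL, c(0, 0), p, connected = FALSE,
                             rounded = FALSE), 50)
  path_100 <- matrix(c(0.005, 0), 1, 2)
  expect_equal(compute_score(path_100, NULL, c(0, 0), p, connected = FALSE), 100)
  path_0 <- matrix(c(0.02, 0), 1, 2)
  expect_equal(compute_score(path_0, NULL, c(0, 0), p, connected = FALSE), 0)

  # strictly decreasing in d and bounded in (0, 100)
  ds <- seq(0, 0.03, by = 0.001)
  scores <- vapply(ds, function(d)
    compute_score(matrix(c(d, 0), 1), NULL, c(0, 0), p, connected = FALSE,
                  rounded = FALSE), 0)
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores > 0 & scores < 100))

  # connected scoring adds c * mean inter-player distance
  own <- matrix(rep(c(0.004, 0), each = 10), 10, 2)
  partner <- own + matrix(rep(c(0.01, 0), each = 10), 10, 2)
  s_conn <- compute_score(own, partner, c(0, 0), p, connected = TRUE,
                          rounded = FALSE)
  d_expected <- 0.004 + 0.5 * 0.01
  expect_equal(s_conn, 100 / (1 + exp(p$h * (d_expected - p$d0))),
               tolerance = 1e-12)
  expect_error(score_params(d0 = 0.03), "between")
})

test_that("IF, MD and power match their brute-force definitions", {
  expect_equal(compute_IF(matrix(0, 10, 2)), 0)
  expect_equal(compute_IF(matrix(rep(c(3, 4), each = 7), 7, 2)), 5)
  set.seed(9)
  F <- matrix(rnorm(60), 30, 2)
  expect_equal(compute_IF(F), sum(sqrt(F[, 1]^2 + F[, 2]^2)) / 30,
               tolerance = 1e-12)

  path <- cbind(seq(-0.05, 0.05, length.out = 1001), 0)
  expect_equal(compute_MD(path, c(-0.03, -0.02)), 0.02, tolerance = 1e-6)
  expect_equal(compute_MD(rbind(c(1, 2)), c(1, 2)), 0)
  traj <- matrix(rnorm(40), 20, 2)
  vp <- c(0.3, -0.1)
  expect_equal(compute_MD(traj, vp),
               min(apply(traj, 1, function(r) sqrt(sum((r - vp)^2)))))

  expect_equal(compute_power(rbind(c(1, 0)), rbind(c(0.1, 0))), 0.1)
  expect_equal(compute_power(rbind(c(1, 0)), rbind(c(0, 2))), 0)
  v <- matrix(rnorm(20), 10, 2)
  expect_equal(compute_power(F[1:10, ], -v), -compute_power(F[1:10, ], v))
  expect_error(compute_power(F, v), "length")
})

test_that("LI averages power over the window before the crossing", {
  pw <- rep(0.2, 100)
  expect_equal(compute_LI(pw, 80), 0.2)
  expect_equal(compute_LI(pw, 40), 0.2)
  # truncated window is flagged
  li <- compute_LI(pw, 10)
  expect_true(isTRUE(attr(li, "truncated")))
  expect_error(compute_LI(pw, 0), "window")
  # hand-built ramp: window mean over the exact 30 samples
  ramp <- seq_len(100) / 100
  expect_equal(as.numeric(compute_LI(ramp, 60)), mean(ramp[31:60]))
})

test_that("lagged fixtures produce the leader-follower sign pattern, dose-dependently", {
  taus <- c(0.05, 0.1, 0.15)
  dli2 <- vapply(taus, function(tau) {
    rec <- make_fixture_trial(fixture_spec(tau = tau))
    trial_indicators(rec)$dLI_2
  }, 0)
  # player 2 leads: positive role index at their own via-point, growing in tau
  expect_true(all(dli2 > 0))
  expect_true(all(diff(dli2) > 0))
  rec15 <- make_fixture_trial(fixture_spec(tau = 0.15))
  ind15 <- trial_indicators(rec15)
  expect_gt(ind15$LI_12, 0)   # player 1 is pulled near vp2 (follower)
  expect_lt(ind15$LI_22, 0)   # player 2 moves against the coupling (leader)
  # ΔLI_2 is assembled as LI_12 - LI_22
  expect_equal(ind15$dLI_2, ind15$LI_12 - ind15$LI_22)

  # synchronous fixture: both paths identical, negligible power and role index
  rec0 <- make_fixture_trial(fixture_spec(tau = 0))
  expect_identical(rec0$p1, rec0$p2)
  ind0 <- trial_indicators(rec0)
  expect_lt(abs(ind0$dLI_1) + abs(ind0$dLI_2), 1e-8)
  # smoothing biases the path by a few tens of micrometers at the via-points
  expect_lt(ind0$MD_11, 1e-4)
  expect_lt(ind0$MD_22, 1e-4)
})

test_that("epoch aggregation matches a brute-force grouping oracle", {
  prot <- make_protocol("H", seed = 4)
  n <- nrow(prot$trials)
  set.seed(10)
  rows <- data.frame(trial = seq_len(n), IF = runif(n), score_1 = runif(n),
                     score_2 = runif(n), MD_12 = runif(n), MD_21 = runif(n),
                     dLI_1 = rnorm(n), dLI_2 = rnorm(n))
  agg <- aggregate_epochs(rows, prot)
  expect_equal(nrow(agg$epoch_means), 13)
  # oracle: per-epoch means excluding training catch trials
  for (ep in c(1, 2, 7, 13)) {
    keep <- prot$trials$epoch == ep &
      !(prot$trials$phase == "training" & prot$trials$catch)
    expect_equal(agg$epoch_means$IF[agg$epoch_means$epoch == ep],
                 mean(rows$IF[keep]))
  }
  expect_identical(agg$summary$time, c("early", "middle", "late"))
  expect_equal(agg$summary$epoch, c(2, 6, 11))
  # constant indicator: every epoch mean equals it
  rows$IF <- 0.7
  agg2 <- aggregate_epochs(rows, prot)
  expect_true(all(agg2$epoch_means$IF == 0.7))
})

test_that("indicators survive a CSV round trip", {
  rec <- make_fixture_trial(fixture_spec(tau = 0.1, noise_sd = 1e-4, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_trial_csv(rec, path, digits = 12)
  rec2 <- read_trial_csv(path, geometry = rec$geometry)
  expect_true(rec2$connected)
  i1 <- trial_indicators(rec)
  i2 <- trial_indicators(rec2)
  num <- vapply(i1, is.numeric, TRUE)
  expect_equal(unlist(i2[num]), unlist(i1[num]), tolerance = 1e-6)
  # extra z columns are tolerated and ignored
  df <- data.table::fread(path)
  df$p1z <- 0.01
  path3 <- tempfile(fileext = ".csv")
  data.table::fwrite(df, path3)
  rec3 <- read_trial_csv(path3, geometry = rec$geometry)
  expect_equal(trial_indicators(rec3)$IF, i1$IF, tolerance = 1e-6)
  unlink(c(path, path3))
})
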