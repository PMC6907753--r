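# Shared fixtures. Small horizons keep unit tests fast; the acceptance
# suite exercises the full default configuration.

default_plant <- function() build_plant()

small_plant <- function(T = 80, spring_k = 150, motor_sd = 0.3) {
  build_plant(dyad_params(horizon_T = T, spring_k = spring_k,
                          motor_noise_sd = motor_sd))
}

small_costs <- function(plant, weights = default_cost_weights()) {
  list(build_cost(1, plant, weights), build_cost(2, plant, weights))
}

# Independent single-player finite-horizon LQR oracle: textbook value
# recursion written without reference to the package internals.
oracle_lqr <- function(A, B, Q_seq, R) {
  T <- length(Q_seq)
  S <- Q_seq[[T]]
  gains <- vector("list", T - 1)
  for (t in (T - 1):1) {
    # u* = argmin u' R u + (A x + B u)' S (A x + B u) + x' Q x
    K <- solve(R + t(B) %*% S %*% B, t(B) %*% S %*% A)
    S <- Q_seq[[t]] + t(A) %*% S %*% A -
      t(A) %*% S %*% B %*% K
    S <- (S + t(S)) / 2
    gains[[t]] <- K
  }
  gains
}

# Index permutation mapping player 1 onto player 2 (blocks swapped, via
# points swapped, goal untouched).
swap_permutation <- function() {
  ix <- state_index()
  perm <- seq_len(22)
  perm[ix$player1] <- ix$player2
  perm[ix$player2] <- ix$player1
  perm[ix$vp1] <- ix$vp2
  perm[ix$vp2] <- ix$vp1
  perm
}

make_observer_bundle <- function(plant, group, player_id,
                                 profile = default_sensory_profile(),
                                 params = default_observer_params(),
                                 connected = TRUE, T = plant$horizon_T) {
  s <- build_sensory_model(group, player_id, plant, profile,
                           connected = connected)
  aug <- build_augmented(plant, player_id, params$a_u, params$sigma_eps)
  x0 <- initial_state(plant)
  sched <- kalman_gain_schedule(aug, s, init_observer_state(x0, params)$P, T)
  list(aug = aug, sensory = s, K_seq = sched$K_seq, C_seq = sched$C_seq,
       state = init_observer_state(x0, params))
}
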