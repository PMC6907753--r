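# Feedback controllers for the two-player linear-quadratic game.
#
# solve_nash runs the standard finite-horizon coupled Riccati recursion for
# discrete-time feedback-Nash equilibria: at each step the two players'
# stage-wise best responses form one joint linear system in the stacked gains
# (L1; L2), which is solved exactly. solve_no_partner drops the partner's
# input map and solves a plain LQR — the partner's force is then just noise
# to the player, and certainty-equivalent gains do not depend on its
# covariance.

#' Construct a policy set
#'
#' @param L1_seq,L2_seq Lists of 2 x n feedback gain matrices (length T-1), or
#'   \code{NULL} for an unfilled player.
#' @param f1_seq,f2_seq Optional lists of 2-D feedforward terms (length T-1).
#' @param scenario Solver label: \code{"nash"}, \code{"no_partner"} or
#'   \code{"best_response"}.
#' @param info Free-form solver metadata.
#' @return Object of class \code{policy_set}.
#' @export
policy_set <- function(L1_seq = NULL, L2_seq = NULL, f1_seq = NULL,
                       f2_seq = NULL, scenario = "nash", info = list()) {
  ps <- list(L1_seq = L1_seq, L2_seq = L2_seq, f1_seq = f1_seq,
             f2_seq = f2_seq, scenario = scenario, info = info)
  class(ps) <- "policy_set"
  ps
}

#' Feedback-Nash solution of the dyad game
#'
#' Backward coupled Riccati recursion for the finite-horizon two-player
#' linear-quadratic game. Returns time-varying gains \code{u_i(t) = -L_i(t) x(t)}
#' satisfying the Nash no-unilateral-improvement property (checkable with
#' \code{\link{verify_nash}}).
#'
#' @param plant A \code{dyad_plant}.
#' @param cost1,cost2 \code{cost_spec} objects sharing the plant horizon.
#' @return A \code{policy_set} with both players' gains.
#' @export
solve_nash <- function(plant, cost1, cost2) {
  T <- cost1$T
  if (cost2$T != T || plant$horizon_T != T) stop("plant and costs must share the horizon")
  A <- plant$A; B1 <- plant$B1; B2 <- plant$B2
  P1 <- cost1$Q_seq[[T]]
  P2 <- cost2$Q_seq[[T]]
  L1_seq <- vector("list", T - 1)
  L2_seq <- vector("list", T - 1)
  for (t in (T - 1):1) {
    M11 <- cost1$R + crossprod(B1, P1 %*% B1)
    M12 <- crossprod(B1, P1 %*% B2)
    M21 <- crossprod(B2, P2 %*% B1)
    M22 <- cost2$R + crossprod(B2, P2 %*% B2)
    M <- rbind(cbind(M11, M12), cbind(M21, M22))
    rhs <- rbind(crossprod(B1, P1 %*% A), crossprod(B2, P2 %*% A))
    L <- tryCatch(solve(M, rhs), error = function(e)
      stop(sprintf("stage-wise best-response system is singular at step %d", t)))
    m1 <- ncol(B1)
    L1 <- L[seq_len(m1), , drop = FALSE]
    L2 <- L[m1 + seq_len(ncol(B2)), , drop = FALSE]
    Acl <- A - B1 %*% L1 - B2 %*% L2
    P1 <- sym(cost1$Q_seq[[t]] + crossprod(L1, cost1$R %*% L1) +
                crossprod(Acl, P1 %*% Acl))
    P2 <- sym(cost2$Q_seq[[t]] + crossprod(L2, cost2$R %*% L2) +
                crossprod(Acl, P2 %*% Acl))
    L1_seq[[t]] <- L1
    L2_seq[[t]] <- L2
  }
  policy_set(L1_seq, L2_seq, scenario = "nash",
             info = list(P1_0 = P1, P2_0 = P2))
}

# Exact best response of player `pl` to the partner's fixed gain sequence:
# fold the partner's feedback into a time-varying drift and solve the
# resulting time-varying LQR. Returns the deviating player's optimal cost
# from x0.
best_response_cost <- function(plant, cost_i, policies, pl, x0) {
  T <- cost_i$T
  B_own <- if (pl == 1) plant$B1 else plant$B2
  B_oth <- if (pl == 1) plant$B2 else plant$B1
  L_oth <- if (pl == 1) policies$L2_seq else policies$L1_seq
  f_oth <- if (pl == 1) policies$f2_seq else policies$f1_seq
  P <- cost_i$Q_seq[[T]]
  L_seq <- vector("list", T - 1)
  A_seq <- vector("list", T - 1)
  for (t in (T - 1):1) {
    At <- plant$A - B_oth %*% L_oth[[t]]
    G <- cost_i$R + crossprod(B_own, P %*% B_own)
    L <- solve(G, crossprod(B_own, P %*% At))
    Acl <- At - B_own %*% L
    P <- sym(cost_i$Q_seq[[t]] + crossprod(L, cost_i$R %*% L) +
               crossprod(Acl, P %*% Acl))
    L_seq[[t]] <- L
    A_seq[[t]] <- At
  }
  X <- matrix(0, T, 22)
  U <- matrix(0, T - 1, 2)
  x <- x0
  for (t in 1:(T - 1)) {
    X[t, ] <- x
    u <- -drop(L_seq[[t]] %*% x)
    U[t, ] <- u
    u_oth <- -drop(L_oth[[t]] %*% x)
    if (!is.null(f_oth)) u_oth <- u_oth + f_oth[[t]]
    x <- drop(plant$A %*% x + B_own %*% u + B_oth %*% u_oth)
  }
  X[T, ] <- x
  evaluate_cost(X, U, cost_i)
}

# Finite-horizon LQR on (A, B, Q_seq, R); returns gains and value matrices.
lqr_finite_horizon <- function(A, B, Q_seq, R) {
  T <- length(Q_seq)
  P <- Q_seq[[T]]
  L_seq <- vector("list", T - 1)
  for (t in (T - 1):1) {
    G <- R + crossprod(B, P %*% B)
    L <- tryCatch(solve(G, crossprod(B, P %*% A)), error = function(e)
      stop(sprintf("LQR stage system is singular at step %d", t)))
    Acl <- A - B %*% L
    P <- sym(Q_seq[[t]] + crossprod(L, R %*% L) + crossprod(Acl, P %*% Acl))
    L_seq[[t]] <- L
  }
  list(L_seq = L_seq, P0 = P)
}

#' "No-partner" policy: the partner's control treated as noise
#'
#' Solves the single-player LQR obtained by dropping the partner's input map;
#' because the controller is certainty-equivalent, the assumed covariance of
#' the partner-as-noise input does not change the gains (it matters only to
#' observers and simulations).
#'
#' @param plant A \code{dyad_plant}.
#' @param cost_i The player's \code{cost_spec}.
#' @param player_id 1 or 2 (defaults to \code{cost_i$player_id}).
#' @return A \code{policy_set} with only this player's gains filled.
#' @export
solve_no_partner <- function(plant, cost_i, player_id = cost_i$player_id) {
  B <- if (player_id == 1) plant$B1 else plant$B2
  sol <- lqr_finite_horizon(plant$A, B, cost_i$Q_seq, cost_i$R)
  if (player_id == 1) {
    policy_set(L1_seq = sol$L_seq, scenario = "no_partner",
               info = list(P0 = sol$P0))
  } else {
    policy_set(L2_seq = sol$L_seq, scenario = "no_partner",
               info = list(P0 = sol$P0))
  }
}

# Noiseless rollout under a full policy set; returns states and controls.
rollout_noiseless <- function(plant, policies, x0) {
  T <- length(policies$L1_seq) + 1
  X <- matrix(0, T, 22)
  U1 <- matrix(0, T - 1, 2)
  U2 <- matrix(0, T - 1, 2)
  x <- x0
  for (t in 1:(T - 1)) {
    X[t, ] <- x
    u1 <- -drop(policies$L1_seq[[t]] %*% x)
    u2 <- -drop(policies$L2_seq[[t]] %*% x)
    if (!is.null(policies$f1_seq)) u1 <- u1 + policies$f1_seq[[t]]
    if (!is.null(policies$f2_seq)) u2 <- u2 + policies$f2_seq[[t]]
    U1[t, ] <- u1
    U2[t, ] <- u2
    x <- drop(plant$A %*% x + plant$B1 %*% u1 + plant$B2 %*% u2)
  }
  X[T, ] <- x
  list(states = X, u1 = U1, u2 = U2)
}

#' Check the Nash no-unilateral-improvement property
#'
#' Perturbs one player's gain sequence at random, simulates the noiseless
#' closed loop with the other player held fixed, and records the largest cost
#' decrease the deviating player achieves. For a feedback-Nash solution this
#' is non-positive up to solver tolerance.
#'
#' @param plant,cost1,cost2 The game.
#' @param policies A full \code{policy_set}.
#' @param n_perturb Random deviations per player.
#' @param magnitude Relative scale of the gain perturbations.
#' @param seed RNG seed.
#' @param x0 Initial state (defaults to \code{initial_state(plant)}).
#' @return List with per-player baseline costs, the maximum unilateral
#'   improvement over the random deviations (positive = the deviation lowered
#'   the deviator's cost), and \code{br_improvement_1/2}: the improvement
#'   achieved by the deviator's exact best response to the partner's fixed
#'   policy — zero up to solver tolerance at a Nash solution, strictly
#'   positive for any corrupted gain sequence.
#' @export
verify_nash <- function(plant, cost1, cost2, policies, n_perturb = 200,
                        magnitude = 0.01, seed = 1, x0 = initial_state(plant)) {
  base <- rollout_noiseless(plant, policies, x0)
  J1_0 <- evaluate_cost(base$states, base$u1, cost1)
  J2_0 <- evaluate_cost(base$states, base$u2, cost2)
  if (n_perturb == 0) {
    return(list(J1 = J1_0, J2 = J2_0, max_improvement_1 = NA_real_,
                max_improvement_2 = NA_real_, br_improvement_1 = NA_real_,
                br_improvement_2 = NA_real_, n_perturb = 0L))
  }
  best <- c(-Inf, -Inf)
  with_seed(seed, {
    for (pl in 1:2) {
      Lkey <- paste0("L", pl, "_seq")
      scale_ref <- mean(vapply(policies[[Lkey]], function(L) sqrt(mean(L^2)), 0))
      for (r in 1:n_perturb) {
        dL <- matrix(rnorm(2 * 22, sd = magnitude * scale_ref), 2, 22)
        # Perturb over a random contiguous window of steps, trying both signs
        # (antithetic pair), so any nonzero cost gradient along the drawn
        # direction is detected.
        T1 <- length(policies[[Lkey]])
        a <- sample.int(T1, 1)
        b <- sample(a:T1, 1)
        for (sgn in c(1, -1)) {
          pert <- policies
          for (t in a:b) pert[[Lkey]][[t]] <- pert[[Lkey]][[t]] + sgn * dL
          ro <- rollout_noiseless(plant, pert, x0)
          J_dev <- if (pl == 1) evaluate_cost(ro$states, ro$u1, cost1)
                   else evaluate_cost(ro$states, ro$u2, cost2)
          J_base <- if (pl == 1) J1_0 else J2_0
          best[pl] <- max(best[pl], J_base - J_dev)
        }
      }
    }
  })
  br1 <- J1_0 - best_response_cost(plant, cost1, policies, 1, x0)
  br2 <- J2_0 - best_response_cost(plant, cost2, policies, 2, x0)
  list(J1 = J1_0, J2 = J2_0,
       max_improvement_1 = best[1], max_improvement_2 = best[2],
       br_improvement_1 = br1, br_improvement_2 = br2,
       n_perturb = as.integer(n_perturb))
}

#' Simulate one closed-loop trial
#'
#' Rolls the dyad forward under the given policies. Without observers the
#' controllers act on the true state; with a pair of observers each player's
#' feedback is driven by their own state estimate and the partner-input
#' estimate time series is recorded.
#'
#' @param plant A \code{dyad_plant} (the true dynamics; pass a decoupled plant
#'   for disconnected trials).
#' @param policies Full \code{policy_set}.
#' @param x0 Initial state.
#' @param noise Logical; add motor (and, with observers, sensory) noise.
#' @param seed RNG seed for all noise in the trial.
#' @param observers Optional list of two observer bundles as built by
#'   \code{\link{make_observer}}.
#' @param force_k Spring stiffness used when recording interaction forces
#'   (defaults to the plant's; pass 0 for disconnected trials).
#' @return Object of class \code{trial_record}: matrices \code{p1, v1, p2,
#'   v2, u1, u2, F1, F2} (rows = time steps), estimate series
#'   \code{u_hat_of_2_by_1}, \code{u_hat_of_1_by_2} when observers are used,
#'   and the full state matrix \code{states}.
#' @export
simulate_closed_loop <- function(plant, policies, x0 = initial_state(plant),
                                 noise = FALSE, seed = NULL, observers = NULL,
                                 force_k = plant$spring_k) {
  T <- length(policies$L1_seq) + 1
  ix <- plant$ix
  X <- matrix(0, T, 22)
  U1 <- matrix(0, T - 1, 2); U2 <- matrix(0, T - 1, 2)
  Uh2 <- if (!is.null(observers)) matrix(0, T - 1, 2) else NULL
  Uh1 <- if (!is.null(observers)) matrix(0, T - 1, 2) else NULL
  Xf <- if (!is.null(observers))
    lapply(1:2, function(i) list(post = matrix(0, T - 1, 24),
                                 prior = matrix(0, T - 1, 24))) else NULL
  x <- x0
  run <- function() {
    obs <- observers
    for (t in 1:(T - 1)) {
      X[t, ] <<- x
      xhat1 <- if (is.null(obs)) x else obs[[1]]$state$X_hat[1:22]
      xhat2 <- if (is.null(obs)) x else obs[[2]]$state$X_hat[1:22]
      u1 <- -drop(policies$L1_seq[[t]] %*% xhat1)
      u2 <- -drop(policies$L2_seq[[t]] %*% xhat2)
      if (!is.null(policies$f1_seq)) u1 <- u1 + policies$f1_seq[[t]]
      if (!is.null(policies$f2_seq)) u2 <- u2 + policies$f2_seq[[t]]
      U1[t, ] <<- u1; U2[t, ] <<- u2
      x <<- step_dynamics(plant, x, u1, u2, noise = noise)
      if (max(abs(x)) > 1e6) stop(sprintf("state diverged at step %d", t))
      if (!is.null(obs)) {
        y1 <- observe(obs[[1]]$sensory, x, noise = noise)
        y2 <- observe(obs[[2]]$sensory, x, noise = noise)
        K1 <- if (!is.null(obs[[1]]$K_seq)) obs[[1]]$K_seq[[t]] else NULL
        K2 <- if (!is.null(obs[[2]]$K_seq)) obs[[2]]$K_seq[[t]] else NULL
        obs[[1]]$state <- observer_step(obs[[1]]$state, obs[[1]]$aug,
                                        obs[[1]]$sensory, y1, u1, K = K1, step = t)
        obs[[2]]$state <- observer_step(obs[[2]]$state, obs[[2]]$aug,
                                        obs[[2]]$sensory, y2, u2, K = K2, step = t)
        Uh2[t, ] <<- extract_partner_input(obs[[1]]$state)
        Uh1[t, ] <<- extract_partner_input(obs[[2]]$state)
        for (i in 1:2) {
          Xf[[i]]$post[t, ] <<- obs[[i]]$state$X_hat
          Xf[[i]]$prior[t, ] <<- obs[[i]]$state$X_minus
        }
      }
    }
    X[T, ] <<- x
  }
  with_seed(seed, run())
  Us2 <- Us1 <- NULL
  if (!is.null(observers)) {
    C1 <- observers[[1]]$C_seq
    C2 <- observers[[2]]$C_seq
    if (!is.null(C1)) Us2 <- smooth_partner_input(Xf[[1]]$post, Xf[[1]]$prior, C1)
    if (!is.null(C2)) Us1 <- smooth_partner_input(Xf[[2]]$post, Xf[[2]]$prior, C2)
  }
  forces <- t(apply(X, 1, function(xr) interaction_force(xr, force_k)$F1))
  rec <- list(states = X, dt = plant$dt,
              p1 = X[, ix$p1, drop = FALSE], v1 = X[, ix$v1, drop = FALSE],
              p2 = X[, ix$p2, drop = FALSE], v2 = X[, ix$v2, drop = FALSE],
              u1 = U1, u2 = U2,
              F1 = forces, F2 = -forces,
              u_hat_of_2_by_1 = Uh2, u_hat_of_1_by_2 = Uh1,
              u_hat_smoothed_of_2_by_1 = Us2, u_hat_smoothed_of_1_by_2 = Us1,
              geometry = plant$geometry, seed = seed,
              connected = force_k > 0)
  class(rec) <- "trial_record"
  rec
}
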