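# Fictitious-play learning loop. At each connected trial, every player
# solves a linear-quadratic best response against the partner-command
# trajectory their own observer estimated on the previous connected trial.
# The estimated command enters the player's internal plant as a drift carried
# by a constant dummy state, so the resulting policy has the usual feedback
# part plus a feedforward part reflecting the predicted partner action.

#' Best-response policy to an estimated partner-command trajectory
#'
#' Augments the plant with a constant dummy state whose coupling column
#' carries \code{B_-i u_hat(t)} (time-varying), and solves the finite-horizon
#' LQ problem on the 23-D augmented state. The feedback block over the
#' physical state is independent of the estimate; the dummy-state column is
#' returned as the feedforward term.
#'
#' @param plant A \code{dyad_plant}.
#' @param cost_i The player's \code{cost_spec}.
#' @param estimate (T-1) x 2 matrix of estimated partner commands, or
#'   \code{NULL}/all-zero for no estimate (policy then equals
#'   \code{\link{solve_no_partner}}).
#' @param player_id 1 or 2 (defaults to \code{cost_i$player_id}).
#' @return A \code{policy_set} with this player's feedback gains and
#'   feedforward terms filled.
#' @export
best_response_policy <- function(plant, cost_i, estimate = NULL,
                                 player_id = cost_i$player_id) {
  T <- cost_i$T
  if (is.null(estimate)) estimate <- matrix(0, T - 1, 2)
  if (nrow(estimate) != T - 1) stop(sprintf("'estimate' must have %d rows", T - 1))
  if (!all(is.finite(estimate))) stop("'estimate' must be finite")
  B_own <- if (player_id == 1) plant$B1 else plant$B2
  B_oth <- if (player_id == 1) plant$B2 else plant$B1
  # Augmented 23-D system: x_aug = [x; 1].
  B_aug <- rbind(B_own, 0)
  P <- rbind(cbind(cost_i$Q_seq[[T]], 0), 0)
  L_seq <- vector("list", T - 1)
  f_seq <- vector("list", T - 1)
  for (t in (T - 1):1) {
    drift <- drop(B_oth %*% estimate[t, ])
    At <- rbind(cbind(plant$A, drift), c(rep(0, 22), 1))
    G <- cost_i$R + crossprod(B_aug, P %*% B_aug)
    L <- tryCatch(solve(G, crossprod(B_aug, P %*% At)), error = function(e)
      stop(sprintf("best-response stage system is singular at step %d", t)))
    Acl <- At - B_aug %*% L
    Qt <- rbind(cbind(cost_i$Q_seq[[t]], 0), 0)
    P <- sym(Qt + crossprod(L, cost_i$R %*% L) + crossprod(Acl, P %*% Acl))
    L_seq[[t]] <- L[, 1:22, drop = FALSE]
    f_seq[[t]] <- -L[, 23]  # u = -L x - L[,23]; store as additive feedforward
  }
  if (player_id == 1) {
    policy_set(L1_seq = L_seq, f1_seq = f_seq, scenario = "best_response")
  } else {
    policy_set(L2_seq = L_seq, f2_seq = f_seq, scenario = "best_response")
  }
}

#' Fixed point of the best-response map
#'
#' The absorbing state of the fictitious-play trial loop: a pair of input
#' sequences each of which is the best response to the other held frozen —
#' the game's Nash equilibrium under the learner's (open-loop, trial-indexed)
#' information structure. By default it is computed exactly by the coupled
#' costate recursion for open-loop Nash equilibria of finite-horizon
#' linear-quadratic games; \code{method = "iterate"} instead runs the damped
#' mutual best-response iteration, which mirrors the noiseless learning loop
#' but converges slowly when the coupling is strong.
#'
#' @param plant A \code{dyad_plant}.
#' @param costs List of two \code{cost_spec}s.
#' @param method \code{"direct"} (coupled recursion) or \code{"iterate"}.
#' @param tol Convergence tolerance on the max input change (N; iterate
#'   method only).
#' @param max_iter Iteration cap (iterate method only).
#' @param damping Weight on the previous estimate in [0, 1) (iterate method
#'   only).
#' @return List with \code{u1}, \code{u2} ((T-1) x 2 input sequences),
#'   \code{policies} (full best-response \code{policy_set}), \code{states}
#'   (noiseless trajectory), \code{iterations}, \code{converged}, and
#'   \code{residual} — the largest input change over one further
#'   best-response round (the absorbing-state defect).
#' @export
fictitious_play_fixed_point <- function(plant, costs,
                                        method = c("direct", "iterate"),
                                        tol = 1e-9, max_iter = 500,
                                        damping = 0.5) {
  method <- match.arg(method)
  T <- plant$horizon_T
  x0 <- initial_state(plant)
  if (method == "direct") {
    A <- plant$A
    S1 <- plant$B1 %*% solve(costs[[1]]$R, t(plant$B1))
    S2 <- plant$B2 %*% solve(costs[[2]]$R, t(plant$B2))
    P1 <- costs[[1]]$Q_seq[[T]]
    P2 <- costs[[2]]$Q_seq[[T]]
    Lam_inv_A <- vector("list", T - 1)
    P1_seq <- vector("list", T)
    P2_seq <- vector("list", T)
    P1_seq[[T]] <- P1
    P2_seq[[T]] <- P2
    for (t in (T - 1):1) {
      Lam <- diag(22) + S1 %*% P1 + S2 %*% P2
      LiA <- solve(Lam, A)
      P1 <- costs[[1]]$Q_seq[[t]] + crossprod(A, P1 %*% LiA)
      P2 <- costs[[2]]$Q_seq[[t]] + crossprod(A, P2 %*% LiA)
      Lam_inv_A[[t]] <- LiA
      P1_seq[[t]] <- P1
      P2_seq[[t]] <- P2
    }
    X <- matrix(0, T, 22)
    u1 <- matrix(0, T - 1, 2)
    u2 <- matrix(0, T - 1, 2)
    x <- x0
    for (t in 1:(T - 1)) {
      X[t, ] <- x
      x1 <- drop(Lam_inv_A[[t]] %*% x)
      u1[t, ] <- -drop(solve(costs[[1]]$R, t(plant$B1) %*% (P1_seq[[t + 1]] %*% x1)))
      u2[t, ] <- -drop(solve(costs[[2]]$R, t(plant$B2) %*% (P2_seq[[t + 1]] %*% x1)))
      x <- x1
    }
    X[T, ] <- x
    it <- 1L
    converged <- TRUE
  } else {
    u1 <- matrix(0, T - 1, 2)
    u2 <- matrix(0, T - 1, 2)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      pols <- merge_policies(best_response_policy(plant, costs[[1]], u2),
                             best_response_policy(plant, costs[[2]], u1))
      ro <- rollout_noiseless(plant, pols, x0)
      ch <- max(abs(ro$u1 - u1), abs(ro$u2 - u2))
      u1 <- damping * u1 + (1 - damping) * ro$u1
      u2 <- damping * u2 + (1 - damping) * ro$u2
      if (ch < tol) { converged <- TRUE; break }
    }
  }
  pols <- merge_policies(best_response_policy(plant, costs[[1]], u2),
                         best_response_policy(plant, costs[[2]], u1))
  ro <- rollout_noiseless(plant, pols, x0)
  residual <- max(abs(ro$u1 - u1), abs(ro$u2 - u2))
  list(u1 = ro$u1, u2 = ro$u2, policies = pols, states = ro$states,
       iterations = it, converged = converged, residual = residual)
}

#' Merge two one-player policy sets into a full policy set
#'
#' @param ps1,ps2 \code{policy_set}s with player 1's and player 2's entries
#'   filled, respectively.
#' @param scenario Label stored on the merged set.
#' @return A full \code{policy_set}.
#' @export
merge_policies <- function(ps1, ps2, scenario = "best_response") {
  policy_set(L1_seq = ps1$L1_seq, L2_seq = ps2$L2_seq,
             f1_seq = ps1$f1_seq, f2_seq = ps2$f2_seq, scenario = scenario)
}

#' Simulate one trial of the protocol
#'
#' Noisy closed-loop rollout with each player driven by their own policy and
#' observer. For disconnected trials the true dynamics have the spring
#' removed and the recorded interaction force is identically zero, while each
#' player's internal model is the one supplied with their observer (a catch
#' trial is silent: the players still assume coupling).
#'
#' @param plant The true \code{dyad_plant} for this trial (pass the decoupled
#'   plant for disconnected trials).
#' @param policies Full \code{policy_set}.
#' @param observers List of two observer bundles (\code{\link{make_observer}}),
#'   or \code{NULL} for full-state feedback.
#' @param connected Logical flag recorded on the trial and used for the force
#'   series.
#' @param seed RNG seed for all trial noise.
#' @param noise Logical; default \code{TRUE}.
#' @return A \code{trial_record} (see \code{\link{simulate_closed_loop}}).
#' @export
run_trial <- function(plant, policies, observers = NULL, connected = TRUE,
                      seed = NULL, noise = TRUE) {
  rec <- simulate_closed_loop(plant, policies, x0 = initial_state(plant),
                              noise = noise, seed = seed,
                              observers = observers,
                              force_k = if (connected) plant$spring_k else 0)
  rec$connected <- connected
  rec
}

#' Run the full fictitious-play protocol for one dyad
#'
#' Baseline trials are solo movements on the decoupled plant. On each
#' training trial every player best-responds to the partner-command
#' trajectory estimated by their own observer on the previous connected trial
#' (zero for the first). Estimates are never updated from disconnected trials
#' (baseline, catch, after-effect), and after-effect trials reuse the last
#' training policies.
#'
#' @param protocol A \code{protocol_spec}.
#' @param plant The connected \code{dyad_plant}.
#' @param costs List of two \code{cost_spec} objects.
#' @param group Sensory group (defaults to the protocol's).
#' @param seed Master RNG seed; per-trial seeds are derived from it.
#' @param profile Sensory noise profile.
#' @param observer_params Observer priors.
#' @param estimate_memory How the partner estimate aggregates across
#'   connected trials: \code{"cumulative"} (default) best-responds to the
#'   empirical mean of all past estimated partner commands — the classical
#'   fictitious-play belief; a numeric lambda in [0, 1) applies exponential
#'   averaging with that memory factor (0 keeps only the most recent trial's
#'   estimate).
#' @return Object of class \code{dyad_session}: list with \code{records}
#'   (one \code{trial_record} per protocol trial), \code{estimates} (per-trial
#'   list of the two (T-1) x 2 estimate matrices used), the protocol, and the
#'   configuration.
#' @export
run_protocol <- function(protocol, plant, costs, group = protocol$group,
                         seed = 1, profile = default_sensory_profile(),
                         observer_params = default_observer_params(),
                         estimate_memory = "cumulative") {
  T <- plant$horizon_T
  params0 <- plant$params
  params0$spring_k <- 0
  plant_off <- build_plant(params0, plant$geometry, method = plant$method)
  x0 <- initial_state(plant)

  sens_on <- lapply(1:2, function(i)
    build_sensory_model(group, i, plant, profile, connected = TRUE))
  sens_off <- lapply(1:2, function(i)
    build_sensory_model(group, i, plant, profile, connected = FALSE))
  aug_on <- lapply(1:2, function(i)
    build_augmented(plant, i, observer_params$a_u, observer_params$sigma_eps))
  aug_off <- lapply(1:2, function(i)
    build_augmented(plant_off, i, observer_params$a_u, observer_params$sigma_eps))
  P0 <- init_observer_state(x0, observer_params)$P
  sched_on <- lapply(1:2, function(i)
    kalman_gain_schedule(aug_on[[i]], sens_on[[i]], P0, T))
  sched_off <- lapply(1:2, function(i)
    kalman_gain_schedule(aug_off[[i]], sens_off[[i]], P0, T))

  baseline_pol <- merge_policies(
    best_response_policy(plant_off, costs[[1]], NULL),
    best_response_policy(plant_off, costs[[2]], NULL),
    scenario = "no_partner")

  est <- list(matrix(0, T - 1, 2), matrix(0, T - 1, 2))  # est[[i]]: player i's estimate of partner
  n_est <- 0L  # connected trials aggregated so far
  trials <- protocol$trials
  records <- vector("list", nrow(trials))
  estimates <- vector("list", nrow(trials))
  policies <- NULL
  trial_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, nrow(trials)))

  for (r in seq_len(nrow(trials))) {
    tr <- trials[r, ]
    estimates[[r]] <- est
    if (tr$phase == "baseline") {
      obs <- lapply(1:2, function(i)
        list(aug = aug_off[[i]], sensory = sens_off[[i]],
             K_seq = sched_off[[i]]$K_seq, C_seq = sched_off[[i]]$C_seq,
             state = init_observer_state(x0, observer_params)))
      rec <- run_trial(plant_off, baseline_pol, obs, connected = FALSE,
                       seed = trial_seeds[r])
    } else {
      if (tr$phase == "training" || is.null(policies)) {
        policies <- merge_policies(
          best_response_policy(plant, costs[[1]], est[[1]]),
          best_response_policy(plant, costs[[2]], est[[2]]))
      }
      physically_on <- isTRUE(tr$connected)
      # Players assume coupling during training and after-effect; the true
      # plant and the force channel follow the physical connection.
      obs <- lapply(1:2, function(i) {
        sc <- if (physically_on) sched_on[[i]] else sched_off[[i]]
        list(aug = aug_on[[i]],
             sensory = if (physically_on) sens_on[[i]] else sens_off[[i]],
             K_seq = sc$K_seq, C_seq = sc$C_seq,
             state = init_observer_state(x0, observer_params))
      })
      rec <- run_trial(if (physically_on) plant else plant_off,
                       policies, obs, connected = physically_on,
                       seed = trial_seeds[r])
      if (physically_on) {
        new1 <- rec$u_hat_smoothed_of_2_by_1
        new2 <- rec$u_hat_smoothed_of_1_by_2
        n_est <- n_est + 1L
        lam <- if (identical(estimate_memory, "cumulative")) {
          1 - 1 / n_est   # running empirical mean of past play
        } else estimate_memory
        est <- list(lam * est[[1]] + (1 - lam) * new1,
                    lam * est[[2]] + (1 - lam) * new2)
      }
    }
    rec$trial <- tr$trial
    rec$phase <- tr$phase
    rec$catch <- tr$catch
    records[[r]] <- rec
  }
  session <- list(records = records, estimates = estimates,
                  protocol = protocol, group = group, seed = seed,
                  geometry = plant$geometry, dt = plant$dt)
  class(session) <- "dyad_session"
  session
}
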