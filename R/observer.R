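# Per-player state observer. Each player runs a Kalman filter on an
# augmented 24-D state [x; u_partner]: the dyad state plus the partner's
# 2-D force command, modeled a priori as a slowly decaying AR(1) process
# (low-pass filtered Gaussian noise). The filter combines an efference-copy
# prediction with the player's own sensory stream, so the quality of the
# partner-command estimate degrades as sensory noise grows.

#' Default observer priors
#'
#' \code{a_u} is the per-step decay of the partner-command prior and
#' \code{sigma_eps} the std dev (N) of its innovation per 10 ms step. The
#' default decay gives the prior a correlation time of several seconds —
#' the partner's command is treated as near-constant on the 2 s movement
#' timescale — which keeps the shrinkage bias of the command estimate well
#' below the sensory-driven fluctuation.
#'
#' @return Named list with \code{a_u}, \code{sigma_eps}, \code{p0_input}.
#' @export
default_observer_params <- function() {
  list(a_u = 0.998,      # partner-command AR(1) decay per step
       sigma_eps = 0.5,  # partner-command innovation std, N
       p0_input = 25)    # prior variance on the initial partner command, N^2
}

#' Build the partner-augmented model for one player
#'
#' Augmented transition
#' \code{[[A, B_-i a_u], [0, a_u I]]} with own-input map \code{[B_i; 0]} and
#' process noise \code{blkdiag(B_i Sigma_eta B_i', Sigma_eps)}.
#'
#' @param plant A \code{dyad_plant}.
#' @param player_id 1 or 2 (the estimating player).
#' @param a_u Partner-command decay, strictly inside (0, 1).
#' @param sigma_eps Std dev of the partner-command innovation (N), or a full
#'   2 x 2 covariance via \code{Sigma_eps}.
#' @param Sigma_eps Optional explicit 2 x 2 PSD covariance.
#' @return Object of class \code{augmented_model} with \code{A_aug} (24 x 24),
#'   \code{B_aug} (24 x 2), \code{Sigma_w}, and index bookkeeping.
#' @export
build_augmented <- function(plant, player_id, a_u = default_observer_params()$a_u,
                            sigma_eps = default_observer_params()$sigma_eps,
                            Sigma_eps = NULL) {
  stopifnot(player_id %in% 1:2)
  if (a_u <= 0 || a_u >= 1) stop("'a_u' must lie strictly inside (0, 1)")
  if (is.null(Sigma_eps)) Sigma_eps <- diag(sigma_eps^2, 2)
  stopifnot_psd(Sigma_eps, "Sigma_eps")
  B_own <- if (player_id == 1) plant$B1 else plant$B2
  B_oth <- if (player_id == 1) plant$B2 else plant$B1
  Sig_eta <- if (player_id == 1) plant$params$motor_noise_cov_1 else plant$params$motor_noise_cov_2
  A_aug <- rbind(cbind(plant$A, B_oth * a_u),
                 cbind(matrix(0, 2, 22), diag(a_u, 2)))
  B_aug <- rbind(B_own, matrix(0, 2, 2))
  Sigma_w <- matrix(0, 24, 24)
  Sigma_w[1:22, 1:22] <- B_own %*% Sig_eta %*% t(B_own)
  Sigma_w[23:24, 23:24] <- Sigma_eps
  aug <- list(player_id = player_id, A_aug = A_aug, B_aug = B_aug,
              Sigma_w = Sigma_w, a_u = a_u, Sigma_eps = Sigma_eps,
              n_state = 22L, n_input = 2L)
  class(aug) <- "augmented_model"
  aug
}

# Extend a player's observation matrix with zero columns over the
# partner-command block (measurements never read the command directly).
augmented_H <- function(sensory) {
  cbind(sensory$H_obs, matrix(0, nrow(sensory$H_obs), 2))
}

#' Kalman gain schedule for the augmented observer
#'
#' Forward Riccati covariance recursion over the horizon; returns the
#' time-varying gains and prior/posterior covariances.
#'
#' @param aug An \code{augmented_model}.
#' @param sensory The player's \code{sensory_model}.
#' @param P0 Initial 24 x 24 covariance.
#' @param T Number of steps.
#' @return List with \code{K_seq} (list of 24 x m gains), \code{C_seq}
#'   (Rauch-Tung-Striebel smoother gains, used to reconstruct the partner
#'   input over a completed trial), \code{P_post} (final posterior
#'   covariance) and \code{P_prior_last}.
#' @export
kalman_gain_schedule <- function(aug, sensory, P0, T) {
  stopifnot_psd(P0, "P0")
  H <- augmented_H(sensory)
  Rv <- sensory$R_v
  A <- aug$A_aug
  P <- sym(P0)
  K_seq <- vector("list", T - 1)
  P_post_seq <- vector("list", T - 1)
  P_prior_seq <- vector("list", T - 1)
  for (t in 1:(T - 1)) {
    Pm <- sym(A %*% P %*% t(A) + aug$Sigma_w)
    S <- H %*% Pm %*% t(H) + Rv
    K <- tryCatch(t(solve(S, H %*% Pm)), error = function(e)
      stop(sprintf("innovation covariance is singular at step %d", t)))
    P <- sym(Pm - K %*% H %*% Pm)
    K_seq[[t]] <- K
    P_prior_seq[[t]] <- Pm
    P_post_seq[[t]] <- P
  }
  C_seq <- vector("list", T - 2)
  for (t in 1:(T - 2)) {
    C_seq[[t]] <- t(solve(P_prior_seq[[t + 1]], A %*% P_post_seq[[t]]))
  }
  list(K_seq = K_seq, C_seq = C_seq, P_post = P, P_prior_last = Pm)
}

#' Initialize an observer state
#'
#' The kinematic and goal blocks start at the true start state (positions and
#' displayed goals are known); the partner-command block starts at zero with
#' a large prior variance.
#'
#' @param x0 True initial dyad state.
#' @param params Observer priors (\code{\link{default_observer_params}}).
#' @param kin_var Prior variance on the kinematic blocks.
#' @return Object of class \code{observer_state} with \code{X_hat} (24-D) and
#'   \code{P} (24 x 24).
#' @export
init_observer_state <- function(x0, params = default_observer_params(),
                                kin_var = 1e-6) {
  P <- diag(kin_var, 24)
  P[23, 23] <- P[24, 24] <- params$p0_input
  st <- list(X_hat = c(x0, 0, 0), P = P, step = 0L)
  class(st) <- "observer_state"
  st
}

#' One predict + correct cycle of the augmented observer
#'
#' Prediction propagates the posterior through the augmented dynamics with
#' the player's own command (efference copy); correction applies the Kalman
#' gain to the innovation. Deterministic given its inputs.
#'
#' @param obs An \code{observer_state}.
#' @param aug The player's \code{augmented_model}.
#' @param sensory The player's \code{sensory_model}.
#' @param y Measurement vector.
#' @param u_own The player's own 2-D command at this step.
#' @param K Optional precomputed gain for this step (skips the covariance
#'   update, used with \code{\link{kalman_gain_schedule}}).
#' @param step Step counter stored in the returned state.
#' @return Updated \code{observer_state}.
#' @export
observer_step <- function(obs, aug, sensory, y, u_own, K = NULL, step = obs$step + 1L) {
  H <- augmented_H(sensory)
  if (length(y) != nrow(H)) stop("measurement dimension mismatch")
  Xm <- drop(aug$A_aug %*% obs$X_hat + aug$B_aug %*% u_own)
  if (is.null(K)) {
    Pm <- sym(aug$A_aug %*% obs$P %*% t(aug$A_aug) + aug$Sigma_w)
    S <- H %*% Pm %*% t(H) + sensory$R_v
    K <- t(solve(S, H %*% Pm))
    P <- sym(Pm - K %*% H %*% Pm)
  } else {
    P <- obs$P
  }
  innov <- y - drop(H %*% Xm)
  st <- list(X_hat = Xm + drop(K %*% innov), X_minus = Xm, P = P,
             step = as.integer(step))
  class(st) <- "observer_state"
  st
}

#' Smooth the partner-input estimate over a completed trial
#'
#' Fixed-interval (Rauch-Tung-Striebel) smoothing of the stored filter
#' means: after the trial, measurements from the whole movement inform the
#' partner's command at every step, removing the causal filter's onset
#' transient and tracking lag. This retrospective estimate is what feeds the
#' next trial's best response.
#'
#' @param X_post (T-1) x 24 matrix of posterior filter means.
#' @param X_prior (T-1) x 24 matrix of prior (predicted) means.
#' @param C_seq Smoother gains from \code{\link{kalman_gain_schedule}}.
#' @return (T-1) x 2 matrix of smoothed partner-command estimates.
#' @export
smooth_partner_input <- function(X_post, X_prior, C_seq) {
  n <- nrow(X_post)
  Xs <- X_post
  for (t in (n - 1):1) {
    Xs[t, ] <- X_post[t, ] + drop(C_seq[[t]] %*% (Xs[t + 1, ] - X_prior[t + 1, ]))
  }
  Xs[, 23:24, drop = FALSE]
}

#' Extract the estimated partner command
#'
#' @param obs An \code{observer_state}.
#' @return 2-D vector: the current estimate of the partner's force command (N).
#' @export
extract_partner_input <- function(obs) {
  obs$X_hat[23:24]
}

#' Bundle an observer for closed-loop simulation
#'
#' Packs the augmented model, sensory model, precomputed gain schedule and
#' initial state for one player, as consumed by
#' \code{\link{simulate_closed_loop}} and \code{\link{run_trial}}.
#'
#' @param plant A \code{dyad_plant}.
#' @param player_id 1 or 2.
#' @param sensory The player's \code{sensory_model}.
#' @param x0 True initial state.
#' @param params Observer priors.
#' @return List with elements \code{aug}, \code{sensory}, \code{state}.
#' @export
make_observer <- function(plant, player_id, sensory, x0 = initial_state(plant),
                          params = default_observer_params()) {
  aug <- build_augmented(plant, player_id, a_u = params$a_u,
                         sigma_eps = params$sigma_eps)
  list(aug = aug, sensory = sensory,
       state = init_observer_state(x0, params))
}
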