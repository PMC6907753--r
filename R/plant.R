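# Dyad plant: two point masses coupled by a linear spring, each driven through
# a cascade of two first-order muscle-activation filters, discretized at dt.
#
# State layout (22-dimensional):
#   p1 (2) | v1 (2) | a1 (4: stage-1 xy, stage-2 xy) |
#   p2 (2) | v2 (2) | a2 (4)                          |
#   g  (2) | vp1 (2) | vp2 (2)                          <- constant goal block
# The stage-2 activation states are the muscle force actually applied to the
# mass; the goal block carries the displayed target and both via-points so
# that tracking costs stay linear-quadratic in the state.

#' Index map of the dyad state vector
#'
#' Returns the positions of each named block inside the 22-dimensional dyad
#' state: per-player position, velocity and activation states, plus the
#' constant goal block (target and the two via-points).
#'
#' @return Named list of integer index vectors.
#' @export
state_index <- function() {
  list(
    p1 = 1:2, v1 = 3:4, a1 = 5:8,
    p2 = 9:10, v2 = 11:12, a2 = 13:16,
    g = 17:18, vp1 = 19:20, vp2 = 21:22,
    player1 = 1:8, player2 = 9:16, goal = 17:22
  )
}

#' Default dyad plant parameters
#'
#' Point-mass dyad with a 150 N/m coupling spring, sampled at 100 Hz over a
#' 2 s horizon. Muscle activation is a cascade of two 40 ms first-order lags
#' per axis; motor noise is additive Gaussian on each player's force command.
#'
#' @param mass_per_player Mass of each player's point mass (kg).
#' @param spring_k Coupling spring stiffness (N/m).
#' @param dt Sampling step (s).
#' @param tau Time constants of the two activation stages (s, length 2).
#' @param motor_noise_sd Std dev of additive motor noise on each force axis (N).
#' @param horizon_T Number of time steps in one movement.
#' @return List of class \code{dyad_params}.
#' @export
dyad_params <- function(mass_per_player = 1.0, spring_k = 150, dt = 0.01,
                        tau = c(0.04, 0.04), motor_noise_sd = 0.3,
                        horizon_T = 200) {
  if (mass_per_player <= 0) stop("'mass_per_player' must be > 0")
  if (spring_k < 0) stop("'spring_k' must be >= 0")
  if (dt <= 0) stop("'dt' must be > 0")
  if (horizon_T < 2) stop("'horizon_T' must be >= 2")
  Sig <- diag(motor_noise_sd^2, 2)
  p <- list(mass_per_player = mass_per_player, spring_k = spring_k, dt = dt,
            tau = tau, motor_noise_cov_1 = Sig, motor_noise_cov_2 = Sig,
            horizon_T = as.integer(horizon_T))
  class(p) <- "dyad_params"
  p
}

#' Default workspace geometry
#'
#' Start and target 10 cm apart on the horizontal axis, via-point 1 below the
#' midline near the start, via-point 2 above the midline near the target
#' (units: m).
#'
#' @param start,target,vp1,vp2 2-D positions (m).
#' @return Named list with entries \code{start}, \code{target}, \code{vp1},
#'   \code{vp2}.
#' @export
default_geometry <- function(start = c(-0.05, 0), target = c(0.05, 0),
                             vp1 = c(-0.03, -0.02), vp2 = c(0.03, 0.02)) {
  g <- list(start = start, target = target, vp1 = vp1, vp2 = vp2)
  stopifnot(all(lengths(g) == 2L))
  g
}

# Continuous-time dynamics matrices for the coupled dyad.
continuous_matrices <- function(params) {
  ix <- state_index()
  m <- params$mass_per_player
  k <- params$spring_k
  t1 <- params$tau[1]; t2 <- params$tau[2]
  Ac <- matrix(0, 22, 22)
  I2 <- diag(2)
  for (pl in 1:2) {
    p <- ix[[paste0("p", pl)]]; v <- ix[[paste0("v", pl)]]
    a <- ix[[paste0("a", pl)]]
    s1 <- a[1:2]; s2 <- a[3:4]
    po <- ix[[paste0("p", 3 - pl)]]
    Ac[p, v] <- I2
    Ac[v, s2] <- I2 / m                 # muscle force on the mass
    Ac[v, p] <- Ac[v, p] - (k / m) * I2 # spring: -k (p_i - p_-i) / m
    Ac[v, po] <- Ac[v, po] + (k / m) * I2
    Ac[s1, s1] <- -I2 / t1
    Ac[s2, s1] <- I2 / t2
    Ac[s2, s2] <- -I2 / t2
  }
  Bc <- matrix(0, 22, 4)
  Bc[ix$a1[1:2], 1:2] <- I2 / t1
  Bc[ix$a2[1:2], 3:4] <- I2 / t1
  list(Ac = Ac, Bc = Bc)
}

#' Build the discrete-time dyad plant
#'
#' Discretizes the coupled two-mass spring plant with muscle-activation
#' cascades, either by exact zero-order hold (default) or forward Euler.
#' The goal block (target + via-points) is carried as constant state.
#'
#' @param params A \code{\link{dyad_params}} object.
#' @param geometry A \code{\link{default_geometry}}-style list; stored so the
#'   plant knows its start state.
#' @param method \code{"zoh"} (exact matrix-exponential discretization) or
#'   \code{"euler"}.
#' @return Object of class \code{dyad_plant} with transition matrix \code{A}
#'   (22 x 22), input maps \code{B1}, \code{B2} (22 x 2), motor noise
#'   covariances, and the state index map.
#' @export
build_plant <- function(params = dyad_params(), geometry = default_geometry(),
                        method = c("zoh", "euler")) {
  method <- match.arg(method)
  if (!inherits(params, "dyad_params")) stop("'params' must be a dyad_params object")
  stopifnot_psd(params$motor_noise_cov_1, "motor_noise_cov_1")
  stopifnot_psd(params$motor_noise_cov_2, "motor_noise_cov_2")
  cm <- continuous_matrices(params)
  dt <- params$dt
  if (method == "zoh") {
    M <- rbind(cbind(cm$Ac, cm$Bc), matrix(0, 4, 26))
    E <- as.matrix(Matrix::expm(M * dt))
    A <- E[1:22, 1:22, drop = FALSE]
    B <- E[1:22, 23:26, drop = FALSE]
  } else {
    A <- diag(22) + cm$Ac * dt
    B <- cm$Bc * dt
  }
  ix <- state_index()
  # Goal block is exactly constant regardless of discretization round-off.
  A[ix$goal, ] <- 0
  A[cbind(ix$goal, ix$goal)] <- 1
  B[ix$goal, ] <- 0
  plant <- list(A = A, B1 = B[, 1:2, drop = FALSE], B2 = B[, 3:4, drop = FALSE],
                params = params, geometry = geometry, ix = ix,
                spring_k = params$spring_k, dt = dt,
                horizon_T = params$horizon_T, method = method)
  class(plant) <- "dyad_plant"
  plant
}

#' Initial dyad state for a trial
#'
#' Both players at the start position, at rest, with the goal block filled
#' from the plant geometry.
#'
#' @param plant A \code{dyad_plant}.
#' @return Numeric state vector of length 22.
#' @export
initial_state <- function(plant) {
  ix <- plant$ix
  g <- plant$geometry
  x <- numeric(22)
  x[ix$p1] <- g$start
  x[ix$p2] <- g$start
  x[ix$g] <- g$target
  x[ix$vp1] <- g$vp1
  x[ix$vp2] <- g$vp2
  x
}

#' Advance the dyad state one step
#'
#' Computes \code{A x + B1 (u1 + eta1) + B2 (u2 + eta2)} with additive
#' Gaussian motor noise.
#'
#' @param plant A \code{dyad_plant}.
#' @param x State vector (length 22).
#' @param u1,u2 2-D force commands (N).
#' @param noise If \code{TRUE}, draw motor noise from the plant covariances;
#'   if \code{FALSE}, noiseless. Alternatively a list with elements
#'   \code{eta1}, \code{eta2} giving explicit noise draws.
#' @param seed Optional RNG seed for the noise draw.
#' @return New state vector of length 22.
#' @export
step_dynamics <- function(plant, x, u1, u2, noise = FALSE, seed = NULL) {
  if (length(x) != 22) stop("state 'x' must have length 22")
  if (length(u1) != 2 || length(u2) != 2) stop("controls must be 2-D")
  if (!all(is.finite(c(x, u1, u2)))) stop("state and controls must be finite")
  if (is.list(noise)) {
    e1 <- noise$eta1; e2 <- noise$eta2
  } else if (isTRUE(noise)) {
    e <- with_seed(seed, rbind(rmvn(1, plant$params$motor_noise_cov_1),
                               rmvn(1, plant$params$motor_noise_cov_2)))
    e1 <- e[1, ]; e2 <- e[2, ]
  } else {
    e1 <- c(0, 0); e2 <- c(0, 0)
  }
  drop(plant$A %*% x + plant$B1 %*% (u1 + e1) + plant$B2 %*% (u2 + e2))
}

#' Spring interaction force on both players
#'
#' \code{F1 = -k (p1 - p2)}, \code{F2 = -k (p2 - p1)}; the two are exactly
#' equal and opposite.
#'
#' @param x Dyad state (length 22) or a list with \code{p1}, \code{p2}.
#' @param k Spring stiffness (N/m).
#' @return List with 2-D vectors \code{F1}, \code{F2} (N).
#' @export
interaction_force <- function(x, k) {
  if (k < 0) stop("'k' must be >= 0")
  if (is.list(x)) {
    p1 <- x$p1; p2 <- x$p2
  } else {
    ix <- state_index()
    p1 <- x[ix$p1]; p2 <- x[ix$p2]
  }
  F1 <- -k * (p1 - p2)
  list(F1 = F1, F2 = -F1)
}

#' Default per-channel sensory noise standard deviations
#'
#' Own position and velocity are common to all groups. The force channel is
#' noisy for the haptic group (weak spring, unreliable percept) and much less
#' so when the force vector is also displayed (VH). The partner-visible group
#' additionally sees the partner cursor with visual-grade precision.
#'
#' @return Named list of noise std devs with units in the names' doc.
#' @export
default_sensory_profile <- function() {
  list(pos = 0.002,        # own position (vision of own cursor + proprioception), m
       vel = 0.01,         # own velocity, m/s
       goal = 0.001,       # displayed target / own via-point, m
       force_H = 1.0,      # interaction force, haptic only, N
       force_VH = 0.3,     # interaction force with on-screen vector, N
       partner_pos = 0.001)  # partner cursor (PV only), m
}

#' Build a per-group sensory model for one player
#'
#' Channels: own position, own velocity, own via-point, target, interaction
#' force (reads \code{k (p_-i - p_i)} off the state). The PV group
#' additionally observes the partner position.
#'
#' @param group One of \code{"H"}, \code{"VH"}, \code{"PV"}.
#' @param player_id 1 or 2.
#' @param plant A \code{dyad_plant} (supplies spring stiffness and index map).
#' @param profile Noise std devs, as from \code{\link{default_sensory_profile}}.
#' @param connected If \code{FALSE}, the force rows are zeroed (no physical
#'   coupling, so the force channel genuinely reads zero).
#' @return Object of class \code{sensory_model} with observation matrix
#'   \code{H_obs}, noise covariance \code{R_v} and channel labels.
#' @export
build_sensory_model <- function(group = c("H", "VH", "PV"), player_id, plant,
                                profile = default_sensory_profile(),
                                connected = TRUE) {
  group <- match.arg(group)
  stopifnot(player_id %in% 1:2)
  ix <- plant$ix
  own_p <- ix[[paste0("p", player_id)]]
  own_v <- ix[[paste0("v", player_id)]]
  own_vp <- ix[[paste0("vp", player_id)]]
  oth_p <- ix[[paste0("p", 3 - player_id)]]
  k <- plant$spring_k
  rows <- list()
  sds <- c()
  labels <- c()
  add <- function(cols, coefs, sd, label) {
    R <- matrix(0, 2, 22)
    for (j in seq_along(cols)) R[cbind(1:2, cols[[j]])] <- coefs[j]
    rows[[length(rows) + 1]] <<- R
    sds <<- c(sds, rep(sd, 2))
    labels <<- c(labels, paste0(label, c("_x", "_y")))
  }
  add(list(own_p), 1, profile$pos, "own_pos")
  add(list(own_v), 1, profile$vel, "own_vel")
  add(list(own_vp), 1, profile$goal, "own_vp")
  add(list(ix$g), 1, profile$goal, "target")
  sd_force <- if (group == "VH") profile$force_VH else profile$force_H
  kf <- if (connected) k else 0
  add(list(own_p, oth_p), c(-kf, kf), sd_force, "force")
  if (group == "PV") add(list(oth_p), 1, profile$partner_pos, "partner_pos")
  H_obs <- do.call(rbind, rows)
  model <- list(group = group, player_id = player_id, H_obs = H_obs,
                R_v = diag(sds^2, length(sds)), labels = labels,
                connected = connected)
  class(model) <- "sensory_model"
  model
}

#' Draw one sensory measurement
#'
#' Returns \code{H_obs \%*\% x + v} with \code{v} drawn from the model's noise
#' covariance; deterministic given \code{seed}.
#'
#' @param sensory A \code{sensory_model}.
#' @param x Dyad state (length 22).
#' @param noise Logical; \code{FALSE} returns the noiseless projection.
#' @param seed Optional RNG seed.
#' @return Measurement vector.
#' @export
observe <- function(sensory, x, noise = TRUE, seed = NULL) {
  if (length(x) != 22) stop("state 'x' must have length 22")
  y <- drop(sensory$H_obs %*% x)
  if (noise) y <- y + drop(with_seed(seed, rmvn(1, sensory$R_v)))
  setNames(y, sensory$labels)
}
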