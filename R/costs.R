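# Quadratic task costs. Each player's goal — pass through the own via-point,
# reach the target and stop, keep the coupling force low, spend little effort
# — is encoded as time-varying state-cost matrices Q(t) plus a constant
# control weight R. Tracking terms use the goal block of the state, so every
# term is an exact quadratic form in the 22-D state.

#' Default cost weights
#'
#' Weights were calibrated once so that noiseless Nash trajectories under the
#' default plant pass within 5 mm of both via-points and stop within 5 mm of
#' the target.
#'
#' @param w_vp Via-point weight (cost per m^2 at the via time).
#' @param w_target Terminal target weight (per m^2).
#' @param w_stop Terminal stopping weight (per (m/s)^2).
#' @param w_force Running player-separation weight (per m^2 per step); the
#'   interaction force is proportional to the separation, so this penalizes
#'   the coupling force.
#' @param w_effort Control effort weight (per N^2 per step).
#' @return Named list of weights.
#' @export
default_cost_weights <- function(w_vp = 1e4, w_target = 1e4, w_stop = 10,
                                 w_force = 30, w_effort = 1e-4) {
  list(w_vp = w_vp, w_target = w_target, w_stop = w_stop,
       w_force = w_force, w_effort = w_effort)
}

# Quadratic form w * || S x ||^2 as a 22x22 matrix, where S selects a
# difference of state blocks: sum_j coef_j * x[cols_j].
block_diff_quad <- function(cols, coefs, w) {
  S <- matrix(0, 2, 22)
  for (j in seq_along(cols)) S[cbind(1:2, cols[[j]])] <- coefs[j]
  w * crossprod(S)
}

#' Build one player's cost specification
#'
#' Assembles the per-step state-cost matrices: via-point term at
#' \code{via_time}, target + stopping terms at the final step, and a running
#' separation (interaction-force) penalty at every step. \code{R = w_effort I}.
#'
#' @param player_id 1 or 2.
#' @param plant A \code{dyad_plant}.
#' @param weights As from \code{\link{default_cost_weights}}.
#' @param via_time Step index at which the via-point term applies; defaults to
#'   0.35 T for player 1 (via-point near the start) and 0.65 T for player 2.
#' @param T Horizon (defaults to the plant horizon).
#' @return Object of class \code{cost_spec} with fields \code{Q_seq} (list of
#'   T symmetric PSD matrices), \code{R}, \code{T}, \code{via_time}.
#' @export
build_cost <- function(player_id, plant, weights = default_cost_weights(),
                       via_time = NULL, T = plant$horizon_T) {
  stopifnot(player_id %in% 1:2)
  w <- weights
  if (any(unlist(w) < 0)) stop("cost weights must be non-negative")
  if (w$w_effort <= 0) stop("'w_effort' must be > 0")
  if (is.null(via_time)) {
    via_time <- as.integer(round(if (player_id == 1) 0.35 * T else 0.65 * T))
  }
  if (via_time <= 0 || via_time >= T) stop("'via_time' must lie strictly inside (0, T)")
  ix <- plant$ix
  own_p <- ix[[paste0("p", player_id)]]
  own_v <- ix[[paste0("v", player_id)]]
  own_vp <- ix[[paste0("vp", player_id)]]
  Q_run <- block_diff_quad(list(ix$p1, ix$p2), c(1, -1), w$w_force)
  Q_via <- block_diff_quad(list(own_p, own_vp), c(1, -1), w$w_vp)
  Q_end <- block_diff_quad(list(own_p, ix$g), c(1, -1), w$w_target) +
    block_diff_quad(list(own_v), 1, w$w_stop)
  Q_seq <- vector("list", T)
  for (t in 1:T) {
    Q <- Q_run
    if (t == via_time) Q <- Q + Q_via
    if (t == T) Q <- Q + Q_end
    Q_seq[[t]] <- Q
  }
  spec <- list(player_id = player_id, Q_seq = Q_seq, R = diag(w$w_effort, 2),
               T = as.integer(T), via_time = as.integer(via_time),
               weights = w)
  class(spec) <- "cost_spec"
  spec
}

#' Evaluate a quadratic cost on a trajectory
#'
#' Computes \code{sum_{t=1}^{T-1} [x(t)' Q(t) x(t) + u(t)' R u(t)] +
#' x(T)' Q(T) x(T)}.
#'
#' @param states T x 22 matrix of states (rows are time steps) or a list of
#'   state vectors.
#' @param controls (T-1) x 2 matrix of the player's force commands.
#' @param spec A \code{cost_spec}.
#' @return Non-negative scalar cost.
#' @export
evaluate_cost <- function(states, controls, spec) {
  if (is.list(states)) states <- do.call(rbind, states)
  controls <- rbind(controls)  # keeps a single control row a matrix
  T <- spec$T
  if (nrow(states) != T) stop(sprintf("'states' must have %d rows", T))
  if (nrow(controls) != T - 1) stop(sprintf("'controls' must have %d rows", T - 1))
  J <- 0
  for (t in 1:(T - 1)) {
    x <- states[t, ]
    u <- controls[t, ]
    J <- J + drop(x %*% spec$Q_seq[[t]] %*% x) + drop(u %*% spec$R %*% u)
  }
  xT <- states[T, ]
  J + drop(xT %*% spec$Q_seq[[T]] %*% xT)
}
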