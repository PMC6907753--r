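# Behavioral indicator pipeline, applied identically to simulated and
# recorded trials: Savitzky-Golay smoothing and differentiation, 2 cm/s
# speed-threshold segmentation, the 0-100 logistic score, average
# interaction-force magnitude (IF), minimum via-point distances (MD_ij),
# interaction power (P_i) and leadership indices (LI_ij, DeltaLI).
# All quantities are planar: only X and Y components enter.

#' Score calibration parameters
#'
#' The logistic score \code{100 / (1 + exp(h (d_i - d0)))} cannot literally
#' attain 0 or 100; the midpoint \code{d0} is set by symmetry between the
#' saturation distances and the slope \code{h} so that the displayed
#' (integer-rounded) score is 100 at \code{d_i = 0.005} m and 0 at
#' \code{d_i = 0.02} m.
#'
#' @param h Logistic slope (1/m).
#' @param d0 Logistic midpoint (m).
#' @param c_connected Partner-distance weight in connected trials.
#' @param d_max_score Distance at or below which the rounded score is 100 (m).
#' @param d_min_score Distance at or above which the rounded score is 0 (m).
#' @return Named list of class \code{score_params}.
#' @export
score_params <- function(h = 800, d0 = 0.0125, c_connected = 0.5,
                         d_max_score = 0.005, d_min_score = 0.02) {
  if (h <= 0) stop("'h' must be > 0")
  if (!(d_max_score < d0 && d0 < d_min_score))
    stop("'d0' must lie between the saturation distances")
  p <- list(h = h, d0 = d0, c_connected = c_connected,
            d_max_score = d_max_score, d_min_score = d_min_score)
  class(p) <- "score_params"
  p
}

#' Savitzky-Golay smoothing and differentiation
#'
#' 4th-order Savitzky-Golay filter over a 370 ms window (37 samples at
#' 100 Hz); velocities and accelerations come from the same local polynomial
#' fits.
#'
#' @param pos n x 2 matrix of sampled planar positions (m).
#' @param dt Sampling step (s).
#' @param order Polynomial order.
#' @param window_s Window length (s); converted to an odd sample count.
#' @return List with n x 2 matrices \code{position}, \code{velocity},
#'   \code{acceleration} and the scalar \code{speed} series.
#' @export
smooth_and_differentiate <- function(pos, dt = 0.01, order = 4,
                                     window_s = 0.37) {
  pos <- as.matrix(pos)
  n_win <- round(window_s / dt)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (nrow(pos) < n_win)
    stop(sprintf("series has %d samples; at least %d (one filter window) required",
                 nrow(pos), n_win))
  filt <- function(m) apply(pos, 2, function(col)
    signal::sgolayfilt(col, p = order, n = n_win, m = m, ts = dt))
  p <- filt(0)
  v <- filt(1)
  a <- filt(2)
  list(position = p, velocity = v, acceleration = a,
       speed = sqrt(rowSums(v^2)))
}

#' Movement segmentation by speed threshold
#'
#' Start is the first up-crossing and end the last down-crossing of the
#' speed threshold (default 2 cm/s).
#'
#' @param speed Non-negative scalar series (m/s).
#' @param threshold Speed threshold (m/s).
#' @return List with integer \code{start}, \code{end}; signals a condition of
#'   class \code{no_movement} if the speed never exceeds the threshold.
#' @export
segment_movement <- function(speed, threshold = 0.02) {
  if (any(speed < 0)) stop("'speed' must be non-negative")
  above <- speed > threshold
  if (!any(above)) {
    stop(structure(class = c("no_movement", "error", "condition"),
                   list(message = "speed never crosses the threshold: no movement detected",
                        call = sys.call())))
  }
  list(start = which(above)[1], end = max(which(above)))
}

#' Trial score
#'
#' \code{d_i = d_VPi + c d12} with \code{d_VPi} the minimum distance of the
#' player's path from their own via-point and \code{d12} the average
#' inter-player distance over the movement window; \code{c} is
#' \code{c_connected} when connected and 0 otherwise. The returned score is
#' the logistic \code{100 / (1 + exp(h (d_i - d0)))}; displayed scores are
#' integer-rounded.
#'
#' @param traj_i Movement-window positions of the scored player (n x 2, m).
#' @param partner_traj Partner positions over the same window (n x 2).
#' @param own_vp The player's via-point (2-D, m).
#' @param params A \code{\link{score_params}} object.
#' @param connected Logical.
#' @param rounded Return the displayed integer score (default) or the raw
#'   logistic value.
#' @return Score in [0, 100].
#' @export
compute_score <- function(traj_i, partner_traj, own_vp,
                          params = score_params(), connected = TRUE,
                          rounded = TRUE) {
  traj_i <- rbind(as.matrix(traj_i))
  if (nrow(traj_i) == 0) stop("empty movement window")
  d_vp <- compute_MD(traj_i, own_vp)
  cc <- if (connected) params$c_connected else 0
  d12 <- if (cc > 0) {
    partner_traj <- rbind(as.matrix(partner_traj))
    mean(sqrt(rowSums((traj_i - partner_traj)^2)))
  } else 0
  d <- d_vp + cc * d12
  s <- 100 / (1 + exp(params$h * (d - params$d0)))
  if (rounded) round(s) else s
}

#' Average interaction-force magnitude
#'
#' \code{IF = mean over the window of ||F(t)||}, planar components only.
#'
#' @param forces n x 2 matrix of interaction forces (N) over the movement
#'   window.
#' @return Scalar IF (N).
#' @export
compute_IF <- function(forces) {
  forces <- rbind(as.matrix(forces))
  if (nrow(forces) == 0) stop("empty movement window")
  mean(sqrt(rowSums(forces^2)))
}

#' Minimum via-point distance
#'
#' \code{MD_ij = min over t of ||x_i(t) - x_VPj||}.
#'
#' @param traj n x 2 matrix of positions (m).
#' @param vp 2-D via-point (m).
#' @return Scalar distance (m).
#' @export
compute_MD <- function(traj, vp) {
  traj <- rbind(as.matrix(traj))
  if (nrow(traj) == 0) stop("empty movement window")
  min(sqrt(rowSums(sweep(traj, 2, vp)^2)))
}

#' Interaction power
#'
#' Per-sample scalar product of the interaction force on a player with that
#' player's velocity. Negative power: the player moves against the coupling
#' (leader); positive: the player is pulled by it (follower).
#'
#' @param F_i n x 2 force series (N).
#' @param v_i n x 2 velocity series (m/s).
#' @return Scalar series (W).
#' @export
compute_power <- function(F_i, v_i) {
  F_i <- rbind(as.matrix(F_i)); v_i <- rbind(as.matrix(v_i))
  if (nrow(F_i) != nrow(v_i)) stop("force and velocity series differ in length")
  rowSums(F_i * v_i)
}

#' Via-point crossing time
#'
#' Operational definition: the sample (within the movement window) at which
#' the via-point's homologous player is nearest to it.
#'
#' @param traj_homologous Positions of the homologous player over the
#'   movement window (n x 2).
#' @param vp The via-point (2-D).
#' @return Integer index into the window.
#' @export
crossing_time <- function(traj_homologous, vp) {
  traj_homologous <- rbind(as.matrix(traj_homologous))
  which.min(sqrt(rowSums(sweep(traj_homologous, 2, vp)^2)))
}

#' Leadership index
#'
#' Mean interaction power over the 300 ms window ending at the via-point
#' crossing time; both players' LI at a via-point share the window defined by
#' the homologous player's crossing.
#'
#' @param power_i Power series over the movement window (W).
#' @param t_cross Crossing sample index (within the same window).
#' @param dt Sampling step (s).
#' @param window_s Averaging window (s).
#' @return Scalar LI (W). If the crossing falls less than one window after
#'   movement start the window is truncated and a \code{"truncated"}
#'   attribute is set.
#' @export
compute_LI <- function(power_i, t_cross, dt = 0.01, window_s = 0.3) {
  if (t_cross < 1 || t_cross > length(power_i))
    stop("crossing time outside the movement window")
  n_win <- round(window_s / dt)
  a <- t_cross - n_win + 1
  truncated <- a < 1
  li <- mean(power_i[max(1, a):t_cross])
  if (truncated) attr(li, "truncated") <- TRUE
  li
}

#' All indicators for one trial
#'
#' Runs the full pipeline on a \code{trial_record} (or equivalent list of
#' series): smooth + differentiate both players' positions, segment the
#' movement on the dyad mean speed, then compute score, IF, MD_ij, LI_ij and
#' the per-via-point role indices
#' \code{DeltaLI_1 = LI_21 - LI_11}, \code{DeltaLI_2 = LI_12 - LI_22}.
#'
#' @param rec A \code{trial_record} (fields \code{p1}, \code{p2}, \code{F1},
#'   \code{F2}, \code{dt}, \code{geometry}, \code{connected}).
#' @param params Score calibration.
#' @param threshold Segmentation speed threshold (m/s).
#' @return One-row data frame (an indicator row).
#' @export
trial_indicators <- function(rec, params = score_params(), threshold = 0.02) {
  dt <- rec$dt
  g <- rec$geometry
  s1 <- smooth_and_differentiate(rec$p1, dt)
  s2 <- smooth_and_differentiate(rec$p2, dt)
  speed <- (s1$speed + s2$speed) / 2
  seg <- segment_movement(speed, threshold)
  idx <- seg$start:seg$end
  p1 <- s1$position[idx, , drop = FALSE]; v1 <- s1$velocity[idx, , drop = FALSE]
  p2 <- s2$position[idx, , drop = FALSE]; v2 <- s2$velocity[idx, , drop = FALSE]
  F1 <- rbind(as.matrix(rec$F1))[idx, , drop = FALSE]
  F2 <- rbind(as.matrix(rec$F2))[idx, , drop = FALSE]
  P1 <- compute_power(F1, v1)
  P2 <- compute_power(F2, v2)
  tc1 <- crossing_time(p1, g$vp1)   # vp1's homologous player is player 1
  tc2 <- crossing_time(p2, g$vp2)
  LI11 <- compute_LI(P1, tc1, dt); LI21 <- compute_LI(P2, tc1, dt)
  LI12 <- compute_LI(P1, tc2, dt); LI22 <- compute_LI(P2, tc2, dt)
  connected <- isTRUE(rec$connected)
  data.frame(
    trial = if (!is.null(rec$trial)) rec$trial else NA_integer_,
    connected = connected,
    catch = isTRUE(rec$catch),
    phase = if (!is.null(rec$phase)) rec$phase else NA_character_,
    duration = length(idx) * dt,
    score_1 = compute_score(p1, p2, g$vp1, params, connected),
    score_2 = compute_score(p2, p1, g$vp2, params, connected),
    IF = compute_IF(F1),
    MD_11 = compute_MD(p1, g$vp1), MD_12 = compute_MD(p1, g$vp2),
    MD_21 = compute_MD(p2, g$vp1), MD_22 = compute_MD(p2, g$vp2),
    LI_11 = as.numeric(LI11), LI_21 = as.numeric(LI21),
    LI_12 = as.numeric(LI12), LI_22 = as.numeric(LI22),
    dLI_1 = as.numeric(LI21) - as.numeric(LI11),
    dLI_2 = as.numeric(LI12) - as.numeric(LI22)
  )
}

#' Indicators for a whole session
#'
#' @param session A \code{dyad_session} from \code{\link{run_protocol}}.
#' @param params Score calibration.
#' @return Data frame with one row per trial.
#' @export
session_indicators <- function(session, params = score_params()) {
  rows <- lapply(session$records, trial_indicators, params = params)
  do.call(rbind, rows)
}

#' Per-epoch aggregation of indicator rows
#'
#' 12-trial epoch means; catch trials are excluded from connected-phase
#' (training) means. The early/middle/late summary takes the first, middle
#' and last training epochs.
#'
#' @param rows Data frame of indicator rows (one per trial, in protocol
#'   order).
#' @param protocol The \code{protocol_spec} the rows cover.
#' @param cols Indicator columns to aggregate.
#' @return List with \code{epoch_means} (one row per epoch) and
#'   \code{summary} (early / middle / late rows).
#' @export
aggregate_epochs <- function(rows, protocol,
                             cols = c("score_1", "score_2", "IF", "MD_12",
                                      "MD_21", "dLI_1", "dLI_2")) {
  tr <- protocol$trials
  if (nrow(rows) != nrow(tr)) stop("rows do not cover the protocol")
  rows$epoch <- tr$epoch
  rows$phase <- tr$phase
  keep <- !(tr$phase == "training" & tr$catch)
  sub <- rows[keep, c("epoch", "phase", cols)]
  em <- aggregate(sub[cols], by = list(epoch = sub$epoch), FUN = mean)
  em$phase <- protocol$phases[em$epoch]
  te <- protocol$training_epochs
  pick <- c(early = te[1], middle = te[ceiling(length(te) / 2)],
            late = te[length(te)])
  summary <- em[match(pick, em$epoch), ]
  summary$time <- names(pick)
  list(epoch_means = em, summary = summary)
}
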