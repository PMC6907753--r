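# Synthetic inputs: model-free fixture trials with a controllable
# leader-follower structure (minimum-jerk paths through both via-points,
# one player time-shifted), and full model-generated group datasets laid
# out as per-indicator matrices (one row per dyad, one column per trial).

# Minimum-jerk interpolation through waypoints: classic smooth polynomial
# with zero velocity and acceleration at each waypoint.
min_jerk_path <- function(waypoints, times, t) {
  n_seg <- nrow(waypoints) - 1
  out <- matrix(0, length(t), 2)
  for (j in seq_along(t)) {
    tt <- min(max(t[j], times[1]), times[length(times)])
    k <- findInterval(tt, times, rightmost.closed = TRUE)
    k <- min(k, n_seg)
    s <- (tt - times[k]) / (times[k + 1] - times[k])
    blend <- 10 * s^3 - 15 * s^4 + 6 * s^5
    out[j, ] <- waypoints[k, ] + (waypoints[k + 1, ] - waypoints[k, ]) * blend
  }
  out
}

#' Fixture specification for indicator-pipeline tests
#'
#' @param tau Time shift (s) by which player 2 leads player 1 along the
#'   common path; 0 gives perfectly synchronous movement.
#' @param noise_sd Additive kinematic noise std (m).
#' @param duration Movement duration (s).
#' @param rate Sample rate (Hz).
#' @param pad Still time appended before and after the movement (s).
#' @param seed RNG seed for the noise.
#' @return List of class \code{fixture_spec}.
#' @export
fixture_spec <- function(tau = 0, noise_sd = 0, duration = 2, rate = 100,
                         pad = 0.3, seed = 1) {
  if (duration <= 0 || rate <= 0) stop("duration and rate must be > 0")
  f <- list(tau = tau, noise_sd = noise_sd, duration = duration, rate = rate,
            pad = pad, seed = seed)
  class(f) <- "fixture_spec"
  f
}

#' Generate a model-free fixture trial
#'
#' Both players traverse the same minimum-jerk path start -> vp1 -> vp2 ->
#' target, with player 2 shifted earlier by \code{tau} (player 2 leads).
#' Interaction forces follow the spring law on the generated positions, so
#' for \code{tau > 0} the leader does negative interaction power and the
#' follower positive power near every via-point, with magnitude increasing
#' in \code{tau}.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param geometry Workspace geometry (\code{\link{default_geometry}}).
#' @param k Spring stiffness (N/m).
#' @return A \code{trial_record}-compatible list.
#' @export
make_fixture_trial <- function(spec = fixture_spec(),
                               geometry = default_geometry(), k = 150) {
  dt <- 1 / spec$rate
  tt <- seq(0, spec$duration + 2 * spec$pad, by = dt)
  t_move <- tt - spec$pad
  wp <- rbind(geometry$start, geometry$vp1, geometry$vp2, geometry$target)
  times <- c(0, 0.35, 0.65, 1) * spec$duration
  p1 <- min_jerk_path(wp, times, t_move)
  p2 <- min_jerk_path(wp, times, t_move + spec$tau)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(rnorm(length(tt) * 4, sd = spec$noise_sd),
                              ncol = 4))
    p1 <- p1 + noise[, 1:2]
    p2 <- p2 + noise[, 3:4]
  }
  F1 <- -k * (p1 - p2)
  rec <- list(p1 = p1, p2 = p2, F1 = F1, F2 = -F1, dt = dt,
              geometry = geometry, connected = TRUE, seed = spec$seed,
              fixture = spec)
  class(rec) <- "trial_record"
  rec
}

#' Generate a per-group synthetic dataset
#'
#' Runs the fictitious-play protocol for \code{n_dyads} dyads with distinct
#' derived seeds, computes the indicator rows for every trial, and (if
#' \code{out_dir} is given) writes raw trial CSVs plus one matrix file per
#' indicator with one row per dyad and one column per trial, alongside a JSON
#' sidecar with the configuration digest.
#'
#' @param group \code{"H"}, \code{"VH"} or \code{"PV"}.
#' @param n_dyads Number of simulated dyads.
#' @param seed Master seed.
#' @param plant,costs Model configuration (defaults from
#'   \code{\link{build_plant}} and \code{\link{build_cost}}).
#' @param protocol Protocol template; per-dyad catch placement is re-seeded.
#' @param out_dir Output directory, or \code{NULL} to skip writing.
#' @param write_raw Write per-trial CSVs (can be disabled to save space).
#' @param indicators Indicator columns to export as matrices.
#' @return Invisibly, a list with \code{indicator_matrices} (named list of
#'   n_dyads x n_trials matrices), \code{sessions}, and \code{config}.
#' @export
generate_group_dataset <- function(group = c("H", "VH", "PV"), n_dyads = 5,
                                   seed = 42, plant = build_plant(),
                                   costs = list(build_cost(1, plant),
                                                build_cost(2, plant)),
                                   protocol = NULL, out_dir = NULL,
                                   write_raw = !is.null(out_dir),
                                   indicators = c("score_1", "score_2", "IF",
                                                  "MD_12", "MD_21",
                                                  "dLI_1", "dLI_2")) {
  group <- match.arg(group)
  dyad_seeds <- with_seed(seed, sample.int(2^31 - 2, n_dyads))
  sessions <- vector("list", n_dyads)
  rows <- vector("list", n_dyads)
  for (d in seq_len(n_dyads)) {
    prot <- if (is.null(protocol)) make_protocol(group, seed = dyad_seeds[d])
            else protocol
    sessions[[d]] <- run_protocol(prot, plant, costs, group = group,
                                  seed = dyad_seeds[d])
    rows[[d]] <- session_indicators(sessions[[d]])
  }
  n_trials <- nrow(rows[[1]])
  mats <- lapply(indicators, function(col)
    do.call(rbind, lapply(rows, function(r) r[[col]])))
  names(mats) <- indicators
  config <- list(group = group, n_dyads = n_dyads, seed = seed,
                 dyad_seeds = dyad_seeds,
                 spring_k = plant$spring_k, dt = plant$dt,
                 horizon_T = plant$horizon_T,
                 weights = costs[[1]]$weights,
                 sensory_profile = default_sensory_profile(),
                 n_trials = n_trials)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (col in indicators) {
      data.table::fwrite(data.table::as.data.table(mats[[col]]),
                         file.path(out_dir, sprintf("%s_%s.csv", col, group)),
                         col.names = FALSE)
    }
    if (write_raw) {
      for (d in seq_len(n_dyads)) {
        ddir <- file.path(out_dir, sprintf("dyad%02d", d))
        dir.create(ddir, showWarnings = FALSE)
        for (r in seq_along(sessions[[d]]$records)) {
          write_trial_csv(sessions[[d]]$records[[r]],
                          file.path(ddir, sprintf("trial%03d.csv", r)))
        }
      }
    }
    jsonlite::write_json(config, file.path(out_dir, sprintf("config_%s.json", group)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(indicator_matrices = mats, sessions = sessions,
                 config = config))
}
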