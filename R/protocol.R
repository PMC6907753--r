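# Experimental protocol structure: 13 epochs of 12 trials — one baseline
# epoch (disconnected), ten training epochs (connected, with two silent
# catch trials each), and two after-effect epochs (disconnected).

#' Build a protocol specification
#'
#' @param group Sensory group label: \code{"H"}, \code{"VH"} or \code{"PV"}.
#' @param seed RNG seed governing catch-trial placement.
#' @param n_baseline,n_training,n_after Epoch counts per phase.
#' @param trials_per_epoch Movements per epoch.
#' @param catch_per_epoch Catch trials drawn uniformly without replacement in
#'   each training epoch.
#' @return Object of class \code{protocol_spec}: a data frame \code{trials}
#'   with columns \code{trial}, \code{epoch}, \code{phase}, \code{connected},
#'   \code{catch}, plus the structural fields.
#' @export
make_protocol <- function(group = c("H", "VH", "PV"), seed = 1,
                          n_baseline = 1, n_training = 10, n_after = 2,
                          trials_per_epoch = 12, catch_per_epoch = 2) {
  group <- match.arg(group)
  phases <- c(rep("baseline", n_baseline), rep("training", n_training),
              rep("after_effect", n_after))
  n_epochs <- length(phases)
  trials <- data.frame(
    trial = seq_len(n_epochs * trials_per_epoch),
    epoch = rep(seq_len(n_epochs), each = trials_per_epoch),
    phase = rep(phases, each = trials_per_epoch),
    stringsAsFactors = FALSE
  )
  trials$connected <- trials$phase == "training"
  trials$catch <- FALSE
  with_seed(seed, {
    for (ep in which(phases == "training")) {
      idx <- which(trials$epoch == ep)
      catch_idx <- sample(idx, catch_per_epoch)
      trials$catch[catch_idx] <- TRUE
      trials$connected[catch_idx] <- FALSE
    }
  })
  spec <- list(trials = trials, group = group, seed = seed,
               trials_per_epoch = as.integer(trials_per_epoch),
               n_epochs = as.integer(n_epochs),
               training_epochs = which(phases == "training"),
               phases = phases)
  class(spec) <- "protocol_spec"
  spec
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> group %s: %d epochs x %d trials (%d total), %d catch trials\n",
              x$group, x$n_epochs, x$trials_per_epoch, nrow(x$trials),
              sum(x$trials$catch)))
  invisible(x)
}
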