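# Trial CSV input/output. The raw format matches the recorded-data layout:
# one row per 10 ms sample with columns t, p1x, p1y, p2x, p2y, f1x, f1y,
# f2x, f2y; optional z columns are accepted and ignored (the analysis is
# planar).

#' Write one trial to CSV
#'
#' @param rec A \code{trial_record}.
#' @param path Output file path.
#' @param digits Number of significant digits to keep.
#' @return The path, invisibly.
#' @export
write_trial_csv <- function(rec, path, digits = 9) {
  n <- nrow(rbind(as.matrix(rec$p1)))
  df <- data.frame(
    t = signif((seq_len(n) - 1) * rec$dt, digits),
    p1x = signif(rec$p1[, 1], digits), p1y = signif(rec$p1[, 2], digits),
    p2x = signif(rec$p2[, 1], digits), p2y = signif(rec$p2[, 2], digits),
    f1x = signif(rec$F1[, 1], digits), f1y = signif(rec$F1[, 2], digits),
    f2x = signif(rec$F2[, 1], digits), f2y = signif(rec$F2[, 2], digits)
  )
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read one trial from CSV
#'
#' Accepts the columns written by \code{\link{write_trial_csv}}; extra
#' columns (for instance z components) are ignored.
#'
#' @param path CSV file path.
#' @param geometry Workspace geometry to attach (needed by the indicator
#'   pipeline).
#' @param connected Whether the trial was mechanically connected; by default
#'   inferred from the force columns being non-zero.
#' @return A \code{trial_record}-compatible list.
#' @export
read_trial_csv <- function(path, geometry = default_geometry(),
                           connected = NULL) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("t", "p1x", "p1y", "p2x", "p2y", "f1x", "f1y", "f2x", "f2y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  dt <- stats::median(diff(df$t))
  F1 <- as.matrix(df[, c("f1x", "f1y")])
  if (is.null(connected)) connected <- any(F1 != 0)
  rec <- list(p1 = as.matrix(df[, c("p1x", "p1y")]),
              p2 = as.matrix(df[, c("p2x", "p2y")]),
              F1 = F1, F2 = as.matrix(df[, c("f2x", "f2y")]),
              dt = dt, geometry = geometry, connected = connected)
  class(rec) <- "trial_record"
  rec
}
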