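#' Write a simulation to CSV
#'
#' Serializes a \code{hemo_sim} as two CSV files with a fixed column
#' schema: \code{<prefix>_snapshots.csv}, one row per cell per snapshot
#' (\code{t} in minutes, positions in micrometres, areas in um^2, marker
#' intensities in arbitrary units), and \code{<prefix>_events.csv}, the
#' ground-truth log (one row per event).
#'
#' @param sim A \code{hemo_sim}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- sim$trajectory
  snaps <- do.call(rbind, lapply(seq_along(tr$times), function(i) {
    cells <- tr$states[[i]]
    if (nrow(cells) == 0L) return(NULL)
    cbind(t = tr$times[i], cells)
  }))
  p1 <- file.path(dir, paste0(prefix, "_snapshots.csv"))
  p2 <- file.path(dir, paste0(prefix, "_events.csv"))
  utils::write.csv(snaps, p1, row.names = FALSE)
  utils::write.csv(sim$log, p2, row.names = FALSE)
  invisible(c(snapshots = p1, events = p2))
}
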