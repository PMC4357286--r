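#' Synthesize a flow-cytometry-style event table from cluster states
#'
#' Emulates the acquisition of bled hemocytes: cells are sampled with
#' replacement from one or more cluster states (both compartments; larvae
#' are disrupted before bleeding so sessile and circulating cells are
#' sampled alike), forward scatter follows cell area, fluorescence channels
#' follow the marker intensities under lognormal measurement noise, and a
#' configurable fraction of doublets (high pulse width) and debris (low
#' FSC/SSC) is mixed in to exercise the gating stage. A \code{dead_fraction}
#' of events receives a propidium-iodide signal above threshold.
#'
#' @param states A \code{cluster_state} or list of them.
#' @param n_events Number of events to synthesize (> 0).
#' @param dead_fraction Proportion of events that are PI-positive.
#' @param doublet_fraction,debris_fraction Contamination proportions.
#' @param noise_cv Lognormal coefficient of variation of every measured
#'   channel (0 = noise-free).
#' @param fsc_scale FSC units per um^2 of cell area.
#' @param auto_green Autofluorescence floor of the green channel.
#' @param seed Optional seed.
#' @return Data frame with columns \code{FSC}, \code{SSC}, \code{FL_green},
#'   \code{FL_red}, \code{FL_PI}, \code{pulse_width} plus truth columns
#'   (\code{truth_cls}, \code{truth_dead}, \code{truth_doublet},
#'   \code{truth_debris}) used only for validation.
#' @export
synth_flow_events <- function(states, n_events = 10000, dead_fraction = 0,
                              doublet_fraction = 0.02, debris_fraction = 0.05,
                              noise_cv = 0.15, fsc_scale = 10,
                              auto_green = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(states, "cluster_state")) states <- list(states)
  cells <- do.call(rbind, lapply(states, function(s) s$cells))
  cells <- cells[cells$alive, , drop = FALSE]
  if (is.null(cells) || nrow(cells) == 0L) stop("empty state: no cells to sample")
  if (n_events <= 0) stop("'n_events' must be > 0")
  if (dead_fraction < 0 || dead_fraction > 1)
    stop("'dead_fraction' must lie in [0, 1]")

  lognoise <- function(n) if (noise_cv > 0)
    stats::rlnorm(n, -noise_cv^2 / 2, noise_cv) else rep(1, n)

  kind <- sample(c("single", "doublet", "debris"), n_events, replace = TRUE,
                 prob = c(1 - doublet_fraction - debris_fraction,
                          doublet_fraction, debris_fraction))
  idx1 <- sample.int(nrow(cells), n_events, replace = TRUE)
  idx2 <- sample.int(nrow(cells), n_events, replace = TRUE)  # doublet partner
  area <- cells$area[idx1]
  green <- auto_green + cells$lz_gfp[idx1]
  red <- cells$hml_red[idx1]
  dbl <- kind == "doublet"
  area[dbl] <- area[dbl] + cells$area[idx2[dbl]]
  green[dbl] <- green[dbl] + cells$lz_gfp[idx2[dbl]]
  red[dbl] <- red[dbl] + cells$hml_red[idx2[dbl]]

  FSC <- fsc_scale * area * lognoise(n_events)
  SSC <- 500 * lognoise(n_events)
  FL_green <- green * lognoise(n_events)
  FL_red <- red * lognoise(n_events)
  pulse_width <- stats::rnorm(n_events, 1, 0.05)
  pulse_width[dbl] <- stats::rnorm(sum(dbl), 1.9, 0.1)

  deb <- kind == "debris"
  FSC[deb] <- stats::runif(sum(deb), 5, 120)
  SSC[deb] <- stats::runif(sum(deb), 5, 120)
  FL_green[deb] <- auto_green * lognoise(sum(deb))
  FL_red[deb] <- stats::runif(sum(deb), 0, 30)

  dead <- stats::runif(n_events) < dead_fraction
  FL_PI <- ifelse(dead, 1000, 10) * lognoise(n_events)

  data.frame(FSC = FSC, SSC = SSC, FL_green = FL_green, FL_red = FL_red,
             FL_PI = FL_PI, pulse_width = pmax(pulse_width, 0),
             truth_cls = cells$cls[idx1], truth_dead = dead,
             truth_doublet = dbl, truth_debris = deb,
             stringsAsFactors = FALSE)
}

#' Gate configuration for flow-cytometry event tables
#'
#' Fixed rectangular gates (not auto-fit), for reproducibility: a
#' scatter gate removing debris, a pulse-width singlet gate removing
#' doublets, a PI threshold above which events are scored dead or dying,
#' and a green threshold defining Lz+ events.
#'
#' @param fsc_range,ssc_range Numeric length-2 inclusion intervals.
#' @param pulse_width_max Singlet gate upper bound.
#' @param pi_threshold PI-positive (dead) threshold.
#' @param green_threshold Lz+ threshold on \code{FL_green}.
#' @return A list of class \code{flow_gates}.
#' @export
flow_gates <- function(fsc_range = c(150, 1e4), ssc_range = c(150, 1e4),
                       pulse_width_max = 1.5, pi_threshold = 200,
                       green_threshold = 60) {
  structure(list(fsc_range = fsc_range, ssc_range = ssc_range,
                 pulse_width_max = pulse_width_max,
                 pi_threshold = pi_threshold,
                 green_threshold = green_threshold),
            class = "flow_gates")
}

#' Gate a flow-cytometry event table
#'
#' Applies, in order: the rectangular FSC/SSC hemocyte gate, the
#' pulse-width singlet gate, and the PI viability threshold (PI-positive
#' events are considered dead or dying). Lz+ events are viable singlets
#' whose green fluorescence exceeds the green threshold.
#'
#' @param events Data frame with columns \code{FSC}, \code{SSC},
#'   \code{FL_green}, \code{FL_PI}, \code{pulse_width}.
#' @param gates A [flow_gates()] configuration.
#' @return List with \code{gated} (viable singlet events) and
#'   \code{summary}: counts at each gate, \code{viable_fraction} (among
#'   singlets), \code{lz_pos_fraction} and \code{lz_ratio} (Lz+/Lz-) among
#'   viable singlets.
#' @export
gate_flow_events <- function(events, gates = flow_gates()) {
  need <- c("FSC", "SSC", "FL_green", "FL_PI", "pulse_width")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  in_scatter <- events$FSC >= gates$fsc_range[1] &
    events$FSC <= gates$fsc_range[2] &
    events$SSC >= gates$ssc_range[1] & events$SSC <= gates$ssc_range[2]
  singlet <- in_scatter & events$pulse_width <= gates$pulse_width_max
  viable <- singlet & events$FL_PI < gates$pi_threshold
  gated <- events[viable, , drop = FALSE]
  lz_pos <- gated$FL_green > gates$green_threshold
  n_singlet <- sum(singlet)
  summary <- list(
    n_total = nrow(events),
    n_in_scatter_gate = sum(in_scatter),
    n_singlet = n_singlet,
    n_viable = sum(viable),
    viable_fraction = if (n_singlet > 0) sum(viable) / n_singlet else NA_real_,
    dead_fraction = if (n_singlet > 0) 1 - sum(viable) / n_singlet else NA_real_,
    lz_pos_fraction = if (nrow(gated) > 0) mean(lz_pos) else NA_real_,
    lz_ratio = if (sum(!lz_pos) > 0) sum(lz_pos) / sum(!lz_pos) else NA_real_)
  list(gated = gated, summary = summary)
}

#' Synthesize hemocytometer counts
#'
#' Counts of diluted hemolymph loaded in a Neubauer chamber: the number of
#' cells over one 1-mm^2 square is Poisson with mean
#' \code{concentration / (dilution * 1e4)} (0.1 uL of diluted suspension
#' above each square), consistent with the conversion
#' counted cells x 10^5 = cells/ml at the standard 1:10 dilution.
#'
#' @param concentration True hemolymph concentration, cells/ml (>= 0).
#' @param dilution Dilution factor (default 10).
#' @param n_squares Number of 1-mm^2 squares counted.
#' @param seed Optional seed.
#' @return Integer vector of per-square counts.
#' @export
synth_hemocytometer <- function(concentration, dilution = 10, n_squares = 1,
                                seed = NULL) {
  if (concentration < 0) stop("'concentration' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(n_squares, concentration / (dilution * 1e4))
}

#' Convert hemocytometer counts to cells/ml
#'
#' Implements the printed conversion: counted cells x 10^5 cells/ml (for
#' the standard 1:10 dilution; the factor generalizes as
#' \code{dilution * 1e4}).
#'
#' @param counted Cells counted in 1-mm^2 squares (vector: averaged).
#' @param dilution Dilution factor (default 10).
#' @return Estimated concentration, cells/ml.
#' @export
hemocytometer_concentration <- function(counted, dilution = 10) {
  if (any(counted < 0)) stop("'counted' must be >= 0")
  mean(counted) * dilution * 1e4
}
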