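#' Simulation parameters for a sessile hemocyte cluster
#'
#' Bundles every tunable rate and constant of the discrete-time cluster
#' simulator. All per-3-hr quantities are proportions over the canonical
#' 3-hr observation window used in the live-imaging protocol and are
#' converted internally to per-step probabilities on the imaging grid via
#' [per_step_probability()].
#'
#' @param p_div_3h Per-plasmatocyte division proportion per 3 hr. Default
#'   0.07: roughly 7 percent of Hml+Lz- cells divide within a 3-hr window.
#' @param p_diff_3h Target mean per-plasmatocyte differentiation proportion
#'   per 3 hr (about 3.5 percent). This is the calibration target for
#'   [calibrate_beta()]; the mechanistic rate actually used in the hazard is
#'   \code{beta_contact}.
#' @param beta_contact Per-(Lz- contact) induction hazard contribution per
#'   3 hr. The per-cell induction hazard over a 3-hr window is
#'   \code{beta_contact * k_eff} where \code{k_eff} is the Serrate-weighted
#'   number of plasmatocyte contacts.
#' @param dt Step length in minutes; must divide 180 evenly. Default 1.5 min,
#'   the frame interval of the time-lapse protocol.
#' @param tau_mat Maturation time constant in minutes for the saturating
#'   rise of the Lz>GFP reporter after induction.
#' @param gfp_max Asymptotic GFP intensity (arbitrary units) of a fully
#'   mature crystal cell.
#' @param gfp_high_threshold GFP intensity separating GFP-low induced cells
#'   (INDUCED_CC) from GFP-high mature crystal cells (MATURE_CC).
#' @param k_detach Per-3-hr proportion of sessile cells entering circulation.
#' @param k_attach Per-3-hr proportion of circulating cells re-attaching.
#'   The default 0.99 corresponds to 90 percent of detached cells re-sessile
#'   within 90 min, matching the observed cluster re-establishment time after
#'   physical disruption.
#' @param contact_radius_factor Two sessile cells are scored as contacting
#'   when their centre distance is at most this factor times the sum of
#'   their disk radii. Values slightly above 1 account for membrane
#'   interdigitation seen in projected stacks.
#' @param p_death_3h Per-cell death proportion per 3 hr; 0 by default (no
#'   apoptosis differences were detected between conditions).
#' @param area_gain Relative area increase of a fully mature crystal cell
#'   over its area at induction (area couples linearly to GFP).
#' @param tau_regrow Time constant (min) for daughter cells to regrow to
#'   the parental target area after division.
#' @param hml_red Mean nuclear DsRed intensity (arbitrary units) of Hml+
#'   cells.
#' @param cc_mature_fraction Fraction of the initial crystal cells seeded as
#'   GFP-high mature cells (the rest are GFP-low induced cells).
#' @param seed Optional integer seed threaded through all stochastic draws.
#'
#' @return An object of class \code{sim_params} (a validated list).
#' @seealso [per_step_probability()], [simulate_cluster()], [calibrate_beta()]
#' @export
sim_params <- function(p_div_3h = 0.07,
                       p_diff_3h = 0.035,
                       beta_contact = 0.0195,
                       dt = 1.5,
                       tau_mat = 240,
                       gfp_max = 200,
                       gfp_high_threshold = 120,
                       k_detach = 0.01,
                       k_attach = 0.99,
                       contact_radius_factor = 1.33,
                       p_death_3h = 0,
                       area_gain = 1,
                       tau_regrow = 60,
                       hml_red = 150,
                       cc_mature_fraction = 0.5,
                       seed = NULL) {
  p <- list(p_div_3h = p_div_3h, p_diff_3h = p_diff_3h,
            beta_contact = beta_contact, dt = dt, tau_mat = tau_mat,
            gfp_max = gfp_max, gfp_high_threshold = gfp_high_threshold,
            k_detach = k_detach, k_attach = k_attach,
            contact_radius_factor = contact_radius_factor,
            p_death_3h = p_death_3h, area_gain = area_gain,
            tau_regrow = tau_regrow, hml_red = hml_red,
            cc_mature_fraction = cc_mature_fraction, seed = seed)
  for (nm in c("p_div_3h", "p_diff_3h", "k_detach", "k_attach",
               "p_death_3h", "cc_mature_fraction")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single proportion in [0, 1]", nm))
  }
  if (!is.numeric(dt) || dt <= 0 || abs(180 / dt - round(180 / dt)) > 1e-9)
    stop("'dt' must be a positive step length (minutes) dividing 180 evenly")
  if (beta_contact < 0) stop("'beta_contact' must be >= 0")
  if (tau_mat <= 0 || tau_regrow <= 0) stop("time constants must be positive")
  if (gfp_high_threshold <= 0 || gfp_high_threshold >= gfp_max)
    stop("'gfp_high_threshold' must lie strictly between 0 and 'gfp_max'")
  if (contact_radius_factor <= 0) stop("'contact_radius_factor' must be > 0")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Hemocyte cluster simulation parameters\n")
  cat(sprintf("  division     : %.3f / 3 hr   (dt = %.2f min)\n",
              x$p_div_3h, x$dt))
  cat(sprintf("  induction    : beta_contact = %.4f / (contact . 3 hr),",
              x$beta_contact))
  cat(sprintf(" target %.3f / 3 hr\n", x$p_diff_3h))
  cat(sprintf("  maturation   : tau = %.0f min, GFP max %.0f, high threshold %.0f\n",
              x$tau_mat, x$gfp_max, x$gfp_high_threshold))
  cat(sprintf("  exchange     : detach %.3f, attach %.3f / 3 hr\n",
              x$k_detach, x$k_attach))
  invisible(x)
}

#' Convert a per-window proportion to a per-step probability
#'
#' Solves \code{(1 - p_step)^(180/dt) = 1 - p_window} so that a Bernoulli
#' draw applied at every step of length \code{dt} minutes reproduces the
#' stated proportion over a 3-hr window. This geometric-hazard conversion is
#' used for every rate expressed per 3 hr.
#'
#' @param p_window Proportion over a 3-hr window, in \[0, 1\].
#' @param dt Step length in minutes; must divide 180 evenly.
#' @return Per-step probability.
#' @examples
#' per_step_probability(0.07, 1.5)   # ~6.046e-4
#' per_step_probability(0.035, 180)  # 0.035 (dt equals the window)
#' @export
per_step_probability <- function(p_window, dt) {
  if (any(p_window < 0 | p_window > 1, na.rm = TRUE) || anyNA(p_window))
    stop("'p_window' must lie in [0, 1]")
  if (length(dt) != 1L || dt <= 0 || abs(180 / dt - round(180 / dt)) > 1e-9)
    stop("'dt' must divide 180 evenly")
  1 - (1 - p_window)^(dt / 180)
}

#' Rescale an observed proportion to a reference window
#'
#' Inverse companion of [per_step_probability()]: a proportion observed over
#' \code{duration} minutes is converted to the equivalent proportion over
#' \code{window} minutes under a constant geometric hazard (not by linear
#' scaling).
#'
#' @param p_obs Observed proportion over \code{duration}.
#' @param duration Observation window, minutes.
#' @param window Reference window, minutes (default 180).
#' @return Proportion per reference window.
#' @export
rescale_proportion <- function(p_obs, duration, window = 180) {
  if (any(p_obs < 0 | p_obs > 1)) stop("'p_obs' must lie in [0, 1]")
  if (duration <= 0) stop("'duration' must be positive")
  1 - (1 - p_obs)^(window / duration)
}

#' A perturbation applied to a simulated cluster
#'
#' RNAi knockdowns are modelled as multiplicative efficacy losses on the
#' receiving (Notch) or sending (Serrate) side of the contact hazard;
#' physical cluster disruption as scheduled detachment of every sessile
#' cell.
#'
#' @param kind One of \code{"NOTCH_RNAI"}, \code{"SERRATE_RNAI_ALL"},
#'   \code{"SERRATE_RNAI_LZ_ONLY"}, \code{"DELTA_RNAI"},
#'   \code{"DISRUPTION"}.
#' @param efficacy Knockdown efficacy in \[0, 1\]; 1 silences the target
#'   completely. Ignored for \code{DISRUPTION}.
#' @param schedule For \code{DISRUPTION} only: strictly increasing vector of
#'   times (minutes) at which the cluster is disrupted.
#' @return An object of class \code{perturbation}.
#' @export
perturbation <- function(kind, efficacy = 1, schedule = NULL) {
  kinds <- c("NOTCH_RNAI", "SERRATE_RNAI_ALL", "SERRATE_RNAI_LZ_ONLY",
             "DELTA_RNAI", "DISRUPTION")
  kind <- match.arg(kind, kinds)
  if (efficacy < 0 || efficacy > 1) stop("'efficacy' must lie in [0, 1]")
  if (kind == "DISRUPTION") {
    if (is.null(schedule) || length(schedule) == 0L)
      stop("DISRUPTION requires a non-empty 'schedule'")
    if (any(diff(schedule) <= 0) || any(schedule < 0))
      stop("DISRUPTION 'schedule' must be strictly increasing and non-negative")
  } else if (!is.null(schedule)) {
    stop("'schedule' is only meaningful for DISRUPTION")
  }
  structure(list(kind = kind, efficacy = efficacy, schedule = schedule),
            class = "perturbation")
}

#' Per-step induction probability of a plasmatocyte
#'
#' The lateral-induction hazard is linear in the Serrate-weighted number of
#' contacting Lz- cells: over a 3-hr window the induction probability is
#' \code{min(1, notch_eff * beta_contact * k_eff)}, converted to the step
#' grid with [per_step_probability()]. It is exactly zero without contacts
#' or without Notch, and strictly increasing in \code{k_eff} below
#' saturation.
#'
#' @param cell A single-row data frame (or list) with at least \code{cls}
#'   and \code{notch_eff}; must be a plasmatocyte.
#' @param k_eff Serrate-weighted count of contacting Lz- cells (each Lz-
#'   neighbour contributes its \code{serrate_eff}).
#' @param params A [sim_params()] object.
#' @param dt Step length in minutes (defaults to \code{params$dt}).
#' @return Per-step induction probability.
#' @export
induction_probability <- function(cell, k_eff, params, dt = params$dt) {
  if (!identical(as.character(cell$cls), "PLASMATOCYTE"))
    stop("induction_probability() is defined for plasmatocytes only; ",
         "crystal cells are not re-induced")
  if (k_eff < 0) stop("'k_eff' must be >= 0")
  hazard_window <- min(1, cell$notch_eff * params$beta_contact * k_eff)
  per_step_probability(hazard_window, dt)
}

#' Serialize simulation parameters to YAML or JSON
#'
#' @param params A [sim_params()] object.
#' @param path Output path; format chosen from the extension
#'   (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  x <- unclass(params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else stop("unrecognised extension; use .yaml or .json")
  invisible(path)
}

#' Read simulation parameters from YAML or JSON
#'
#' @param path File written by [write_params()] (or hand-edited).
#' @return A validated [sim_params()] object.
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else stop("unrecognised extension; use .yaml or .json")
  x <- x[intersect(names(x), names(formals(sim_params)))]
  do.call(sim_params, x)
}
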