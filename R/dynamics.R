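new_events <- function(t = numeric(0), kind = character(0),
                       cell_id = integer(0), cell_id2 = NA_integer_) {
  if (length(t) == 0L)
    return(data.frame(t = numeric(0), kind = character(0),
                      cell_id = integer(0), cell_id2 = integer(0),
                      stringsAsFactors = FALSE))
  data.frame(t = t, kind = kind, cell_id = cell_id, cell_id2 = cell_id2,
             stringsAsFactors = FALSE)
}

# Serrate-weighted plasmatocyte contact count for every cell, from an edge
# list; returns a vector aligned with rows of `cells`.
edge_k_eff <- function(cells, edges) {
  k_eff <- numeric(nrow(cells))
  if (is.null(edges) || nrow(edges) == 0L) return(k_eff)
  r1 <- match(edges[, 1], cells$id)
  r2 <- match(edges[, 2], cells$id)
  s1 <- cells$cls[r2] == "PLASMATOCYTE"   # neighbour of r1 is Lz-
  s2 <- cells$cls[r1] == "PLASMATOCYTE"
  at <- c(r1[s1], r2[s2])
  w <- c(cells$serrate_eff[r2[s1]], cells$serrate_eff[r1[s2]])
  if (length(at) > 0L) {
    agg <- rowsum(w, group = at)
    k_eff[as.integer(rownames(agg))] <- agg[, 1]
  }
  k_eff
}

# Deterministic daughter placement: smallest non-overlapping offset from the
# parent, ties broken by smallest angle.
place_daughter <- function(cells, parent_row, r_daughter, geometry) {
  alive_sess <- cells$alive & cells$compartment == "SESSILE"
  ox <- cells$x[alive_sess]; oy <- cells$y[alive_sess]
  orad <- cell_radius(cells$area[alive_sess])
  px <- cells$x[parent_row]; py <- cells$y[parent_row]
  sep0 <- cell_radius(cells$area[parent_row]) + r_daughter
  angles <- seq(0, 2 * pi, length.out = 33L)[-33L]
  for (sep in seq(sep0, sep0 + 8, by = 0.25)) {
    for (ang in angles) {
      x <- px + sep * cos(ang); y <- py + sep * sin(ang)
      if (x - r_daughter < 0 || y - r_daughter < 0 ||
          x + r_daughter > geometry$field_um ||
          y + r_daughter > geometry$field_um) next
      if (all((ox - x)^2 + (oy - y)^2 >= (orad + r_daughter)^2))
        return(c(x, y))
    }
  }
  # Crowded fallback: accept the least-overlapping position at contact range.
  best <- NULL; best_clear <- -Inf
  for (ang in angles) {
    x <- px + sep0 * cos(ang); y <- py + sep0 * sin(ang)
    clear <- min(sqrt((ox - x)^2 + (oy - y)^2) - (orad + r_daughter))
    if (clear > best_clear) { best_clear <- clear; best <- c(x, y) }
  }
  best
}

# Random non-overlapping position for a re-attaching cell.
place_attach <- function(cells, r_new, geometry, tries = 200L) {
  alive_sess <- cells$alive & cells$compartment == "SESSILE"
  ox <- cells$x[alive_sess]; oy <- cells$y[alive_sess]
  orad <- cell_radius(cells$area[alive_sess])
  for (i in seq_len(tries)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- geometry$cluster_radius * sqrt(stats::runif(1))
    x <- geometry$center[1] + rad * cos(ang)
    y <- geometry$center[2] + rad * sin(ang)
    if (x - r_new < 0 || y - r_new < 0 ||
        x + r_new > geometry$field_um || y + r_new > geometry$field_um) next
    if (length(ox) == 0L ||
        all((ox - x)^2 + (oy - y)^2 >= (orad + r_new)^2))
      return(c(x, y))
  }
  NULL
}

#' Disrupt a cluster
#'
#' Models the physical rolling of a larva between cover slides: every
#' sessile cell is forced into circulation and the contact graph is
#' emptied. Total cell count is conserved; subsequent steps re-attach cells
#' at the rate set by \code{k_attach} (default kinetics re-establish about
#' 90 percent of the cluster within 90 min).
#'
#' @param state A \code{cluster_state}.
#' @return The disrupted \code{cluster_state}.
#' @export
apply_disruption <- function(state) {
  sess <- state$cells$compartment == "SESSILE" & state$cells$alive
  state$cells$compartment[sess] <- "CIRCULATION"
  state$edges <- cbind(id1 = integer(0), id2 = integer(0))
  state
}

#' Advance a cluster by one time step
#'
#' One step of length \code{params$dt} minutes: plasmatocyte divisions
#' (Bernoulli per sessile plasmatocyte; daughters placed adjacent with
#' halved areas that regrow), contact-dependent inductions via
#' [induction_probability()], crystal-cell maturation (GFP rises toward its
#' asymptote, area grows with GFP, phagocytic capacity decays, GFP-high
#' cells flip to \code{MATURE_CC}), optional death, sessile/circulating
#' exchange, scheduled disruptions, and a contact-graph rebuild. Crystal
#' cells never divide.
#'
#' @param state A \code{cluster_state}.
#' @param params A [sim_params()] object.
#' @param perturbations List of [perturbation()] objects.
#' @return List with elements \code{state} (advanced state) and
#'   \code{events} (ground-truth event rows for this step).
#' @export
step_cluster <- function(state, params, perturbations = list()) {
  perturbations <- normalize_perturbations(perturbations)
  cells <- state$cells
  dt <- params$dt
  t_new <- state$t + dt
  ev_t <- numeric(0); ev_k <- character(0); ev_c <- integer(0); ev_c2 <- integer(0)
  log_ev <- function(t, kind, id, id2 = NA_integer_) {
    ev_t <<- c(ev_t, t); ev_k <<- c(ev_k, kind)
    ev_c <<- c(ev_c, id); ev_c2 <<- c(ev_c2, id2)
  }

  # Driver-restricted Serrate knockdown tracks Lz state dynamically.
  for (p in perturbations) {
    if (p$kind == "SERRATE_RNAI_LZ_ONLY")
      cells$serrate_eff[cells$cls != "PLASMATOCYTE"] <- 1 - p$efficacy
  }

  if (nrow(cells) > 0L) {
    alive <- cells$alive
    sessile <- alive & cells$compartment == "SESSILE"
    plasma <- cells$cls == "PLASMATOCYTE"

    ## --- induction hazard (uses the pre-step contact graph) -------------
    k_eff <- edge_k_eff(cells, state$edges)
    hz <- pmin(1, cells$notch_eff * params$beta_contact * k_eff)
    p_ind <- per_step_probability(hz, dt)
    p_ind[!(sessile & plasma)] <- 0
    induced <- stats::runif(nrow(cells)) < p_ind

    ## --- divisions (plasmatocytes only) ---------------------------------
    p_div <- per_step_probability(params$p_div_3h, dt)
    dividing <- sessile & plasma & (stats::runif(nrow(cells)) < p_div)
    induced[dividing] <- FALSE   # a cell cannot divide and be induced at once

    ## --- death (off by default) -----------------------------------------
    died <- rep(FALSE, nrow(cells))
    if (params$p_death_3h > 0) {
      p_die <- per_step_probability(params$p_death_3h, dt)
      died <- alive & (stats::runif(nrow(cells)) < p_die)
      dividing[died] <- FALSE; induced[died] <- FALSE
    }

    ## --- apply divisions -------------------------------------------------
    if (any(dividing)) {
      for (i in which(dividing)) {
        half <- cells$area[i] / 2
        cells$area[i] <- half
        r_d <- cell_radius(half)
        pos <- place_daughter(cells, i, r_d, state$geometry)
        daughter <- cells[i, ]
        daughter$id <- state$next_id
        daughter$area <- half
        daughter$x <- pos[1]; daughter$y <- pos[2]
        state$next_id <- state$next_id + 1L
        cells <- rbind(cells, daughter)
        log_ev(t_new, "DIVISION", cells$id[i], daughter$id)
      }
      # recompute index helpers after growth
      alive <- cells$alive
      sessile <- alive & cells$compartment == "SESSILE"
      induced <- c(induced, rep(FALSE, nrow(cells) - length(induced)))
      died <- c(died, rep(FALSE, nrow(cells) - length(died)))
    }

    ## --- apply inductions -------------------------------------------------
    if (any(induced)) {
      idx <- which(induced)
      cells$cls[idx] <- "INDUCED_CC"
      cells$t_induced[idx] <- 0
      for (i in idx) log_ev(t_new, "INDUCTION", cells$id[i])
    }

    ## --- deaths ----------------------------------------------------------
    if (any(died)) {
      cells$alive[died] <- FALSE
      for (i in which(died)) log_ev(t_new, "DEATH", cells$id[i])
    }

    ## --- maturation and regrowth -----------------------------------------
    cc <- cells$alive & cells$cls != "PLASMATOCYTE"
    if (any(cc)) {
      cells$t_induced[cc] <- cells$t_induced[cc] + dt
      lz <- maturation_gfp(cells$t_induced[cc], params)
      cells$lz_gfp[cc] <- lz
      # area relaxes toward the homeostatic target scaled by maturation;
      # a recently divided daughter therefore regrows while it matures,
      # and area never drops below its induction-time value
      target <- cells$area0[cc] * (1 + params$area_gain * lz / params$gfp_max)
      cells$area[cc] <- cells$area[cc] +
        (target - cells$area[cc]) * (1 - exp(-dt / params$tau_regrow))
      cells$phago[cc] <- 1 - lz / params$gfp_max
      flip <- cc & cells$cls == "INDUCED_CC" &
        cells$lz_gfp >= params$gfp_high_threshold
      cells$cls[flip] <- "MATURE_CC"
    }
    pl <- cells$alive & cells$cls == "PLASMATOCYTE"
    cells$area[pl] <- cells$area[pl] +
      (cells$area0[pl] - cells$area[pl]) * (1 - exp(-dt / params$tau_regrow))

    ## --- compartment exchange --------------------------------------------
    sessile <- cells$alive & cells$compartment == "SESSILE"
    circ <- cells$alive & cells$compartment == "CIRCULATION"
    if (params$k_detach > 0 && any(sessile)) {
      p_det <- per_step_probability(params$k_detach, dt)
      det <- sessile & (stats::runif(nrow(cells)) < p_det)
      if (any(det)) {
        cells$compartment[det] <- "CIRCULATION"
        for (i in which(det)) log_ev(t_new, "DETACH", cells$id[i])
      }
    }
    if (params$k_attach > 0 && any(circ)) {
      p_att <- per_step_probability(params$k_attach, dt)
      att <- circ & (stats::runif(nrow(cells)) < p_att)
      for (i in which(att)) {
        pos <- place_attach(cells, cell_radius(cells$area[i]), state$geometry)
        if (!is.null(pos)) {
          cells$x[i] <- pos[1]; cells$y[i] <- pos[2]
          cells$compartment[i] <- "SESSILE"
          log_ev(t_new, "ATTACH", cells$id[i])
        }
      }
    }
  }

  state$cells <- cells
  state$t <- t_new

  ## --- scheduled disruptions ---------------------------------------------
  for (p in perturbations) {
    if (p$kind == "DISRUPTION" &&
        any(p$schedule > t_new - dt & p$schedule <= t_new)) {
      sess_ids <- state$cells$id[state$cells$compartment == "SESSILE" &
                                   state$cells$alive]
      state <- apply_disruption(state)
      for (id in sess_ids) log_ev(t_new, "DETACH", id)
    }
  }

  state$edges <- build_contact_graph(state, params)
  list(state = state,
       events = new_events(ev_t, ev_k, ev_c, ev_c2))
}

normalize_perturbations <- function(perturbations) {
  if (inherits(perturbations, "perturbation")) return(list(perturbations))
  if (is.null(perturbations)) return(list())
  stopifnot(all(vapply(perturbations, inherits, TRUE, "perturbation")))
  perturbations
}

apply_static_perturbations <- function(state, perturbations) {
  for (p in perturbations) {
    if (p$kind == "NOTCH_RNAI")
      state$cells$notch_eff <- 1 - p$efficacy
    if (p$kind == "SERRATE_RNAI_ALL")
      state$cells$serrate_eff <- 1 - p$efficacy
    if (p$kind == "SERRATE_RNAI_LZ_ONLY")
      state$cells$serrate_eff[state$cells$cls != "PLASMATOCYTE"] <-
        1 - p$efficacy
    # DELTA_RNAI: Delta is not the operative ligand for crystal-cell
    # induction; the knockdown is carried but does not enter the hazard.
  }
  state
}

#' Simulate a sessile hemocyte cluster
#'
#' Iterates [step_cluster()] over \code{duration} minutes from a freshly
#' initialized (or supplied) cluster, recording a full state snapshot every
#' \code{snapshot_interval} minutes and every division/induction/exchange
#' event in a ground-truth log.
#'
#' @param params A [sim_params()] object.
#' @param duration Simulated time, minutes; must be a multiple of
#'   \code{params$dt}.
#' @param perturbations A [perturbation()] or list of them.
#' @param n_plasma,n_cc Initial cell counts (defaults mirror a typical
#'   imaged field: 50 plasmatocytes, 6 crystal cells).
#' @param geometry A [cluster_geometry()].
#' @param snapshot_interval Minutes between recorded snapshots (default:
#'   every step, i.e. one snapshot per movie frame).
#' @param seed Integer seed; if \code{NULL}, \code{params$seed} is used; if
#'   both are \code{NULL} the current RNG state is used as-is.
#' @param init_state Optional pre-built \code{cluster_state} to start from.
#' @return An object of class \code{hemo_sim}: list with
#'   \code{trajectory} (class \code{trajectory}: \code{times},
#'   \code{states}, \code{snapshot_interval}, \code{params},
#'   \code{geometry}) and \code{log} (ground-truth event data frame with
#'   columns \code{t}, \code{kind}, \code{cell_id}, \code{cell_id2}).
#' @export
simulate_cluster <- function(params = sim_params(), duration = 180,
                             perturbations = list(), n_plasma = 50, n_cc = 6,
                             geometry = cluster_geometry(),
                             snapshot_interval = params$dt,
                             seed = NULL, init_state = NULL) {
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  if (abs(duration / params$dt - round(duration / params$dt)) > 1e-9)
    stop("'duration' must be a multiple of params$dt")
  if (abs(snapshot_interval / params$dt -
          round(snapshot_interval / params$dt)) > 1e-9)
    stop("'snapshot_interval' must be a multiple of params$dt")
  perturbations <- normalize_perturbations(perturbations)
  state <- if (is.null(init_state))
    init_cluster(n_plasma, n_cc, geometry, params) else init_state
  state <- apply_static_perturbations(state, perturbations)
  state$edges <- build_contact_graph(state, params)

  n_steps <- round(duration / params$dt)
  snap_every <- round(snapshot_interval / params$dt)
  times <- state$t
  states <- list(state$cells)
  logs <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    res <- step_cluster(state, params, perturbations)
    state <- res$state
    logs[[s]] <- res$events
    if (s %% snap_every == 0L) {
      times <- c(times, state$t)
      states <- c(states, list(state$cells))
    }
  }
  log <- do.call(rbind, logs)
  if (is.null(log)) log <- new_events()
  trajectory <- structure(list(times = times, states = states,
                               snapshot_interval = snapshot_interval,
                               params = params, geometry = state$geometry),
                          class = "trajectory")
  structure(list(trajectory = trajectory, log = log, params = params,
                 perturbations = perturbations, final_state = state,
                 seed = seed),
            class = "hemo_sim")
}

#' @export
print.hemo_sim <- function(x, ...) {
  tab <- table(x$log$kind)
  cat(sprintf("hemo_sim: %.0f min, %d snapshots; events: %s\n",
              max(x$trajectory$times), length(x$trajectory$states),
              if (nrow(x$log)) paste(sprintf("%s %d", names(tab), tab),
                                     collapse = ", ") else "none"))
  invisible(x)
}

#' Ground-truth log as a data frame with frame indices
#'
#' @param sim A \code{hemo_sim}.
#' @param frame_interval_min Minutes per movie frame (default: the
#'   simulation snapshot interval).
#' @return The event log with an added 0-based \code{frame} column.
#' @export
truth_log <- function(sim, frame_interval_min = sim$trajectory$snapshot_interval) {
  log <- sim$log
  log$frame <- as.integer(round(log$t / frame_interval_min))
  log
}

#' Calibrate the per-contact induction hazard
#'
#' Finds \code{beta_contact} such that the mean simulated per-plasmatocyte
#' 3-hr induction proportion matches a target (default: the 3.5 percent
#' aggregate differentiation proportion) by bisection over replicate
#' simulations run with fixed seeds, so the objective is deterministic and
#' monotone in beta up to Monte-Carlo granularity.
#'
#' @param params A [sim_params()] object (its \code{beta_contact} is
#'   ignored).
#' @param target_p_diff_3h Target proportion in (0, 1); 0 returns beta 0.
#' @param n_reps Replicate simulations per objective evaluation.
#' @param tol Relative tolerance on the recovered proportion.
#' @param lower,upper Bisection bracket for beta.
#' @param n_plasma,n_cc,geometry Cluster design (defaults: one imaged field).
#' @param seed Base seed; replicate r uses \code{seed + r}.
#' @param max_iter Maximum bisection iterations.
#' @return The calibrated \code{beta_contact} (scalar), with the achieved
#'   proportion in attribute \code{"achieved"}.
#' @export
calibrate_beta <- function(params = sim_params(), target_p_diff_3h = params$p_diff_3h,
                           n_reps = 24, tol = 0.1, lower = 0, upper = 0.2,
                           n_plasma = 50, n_cc = 6,
                           geometry = cluster_geometry(), seed = 1,
                           max_iter = 14) {
  if (target_p_diff_3h < 0 || target_p_diff_3h >= 1)
    stop("'target_p_diff_3h' must lie in [0, 1)")
  if (target_p_diff_3h == 0) return(structure(0, achieved = 0))
  measure <- function(beta) {
    p <- params; p$beta_contact <- beta
    mean(vapply(seq_len(n_reps), function(r) {
      sim <- simulate_cluster(p, duration = 180, n_plasma = n_plasma,
                              n_cc = n_cc, geometry = geometry,
                              snapshot_interval = 180, seed = seed + r)
      ind <- sim$log[sim$log$kind == "INDUCTION", ]
      sum(ind$cell_id <= n_plasma) / n_plasma   # baseline plasmatocytes only
    }, numeric(1)))
  }
  f_hi <- measure(upper)
  if (f_hi < target_p_diff_3h)
    stop(sprintf("non-bracketing search range: p(upper=%.3g) = %.4f < target %.4f",
                 upper, f_hi, target_p_diff_3h))
  lo <- lower; hi <- upper; mid <- NA; fm <- NA
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- measure(mid)
    if (abs(fm - target_p_diff_3h) <= tol * target_p_diff_3h) break
    if (fm < target_p_diff_3h) lo <- mid else hi <- mid
  }
  structure(mid, achieved = fm)
}
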