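scenario_names <- c("development", "rnai", "disruption", "contacts", "videos")

rep_seed <- function(seed, r, arm = 0L) seed + 7919L * r + 104729L * arm

#' Simulate, render and quantify a set of time-lapse fields
#'
#' The in-silico counterpart of the live-imaging experiment: each field
#' starts with \code{n_plasma} plasmatocytes and \code{n_cc} crystal
#' cells, is simulated for \code{duration} minutes on the imaging grid,
#' rendered into a two-channel movie, and pushed through the full
#' detection/tracking/event-calling pipeline. Division and differentiation
#' proportions are pooled over fields.
#'
#' @param n_fields Number of fields (videos).
#' @param params A [sim_params()].
#' @param duration Minutes per video.
#' @param n_plasma,n_cc Initial composition per field.
#' @param geometry A [cluster_geometry()].
#' @param config An [imaging_config()]; default noise-free rendering.
#' @param seed Base seed; field i uses a derived seed.
#' @param score Also score called events against the ground-truth log.
#' @return List: \code{per_field} (data frame), \code{division_rate},
#'   \code{differentiation_rate} (pooled \code{rate_estimate}s),
#'   \code{scores} (per-field event-matching summaries if \code{score}).
#' @export
quantify_fields <- function(n_fields = 13, params = sim_params(),
                            duration = 180, n_plasma = 50, n_cc = 6,
                            geometry = cluster_geometry(),
                            config = imaging_config(noise_gaussian_sd = 0),
                            seed = 1, score = TRUE) {
  frame_min <- config$frame_interval / 60
  ind_par <- induction_params()
  per <- vector("list", n_fields)
  scores <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    sim <- simulate_cluster(params, duration = duration, n_plasma = n_plasma,
                            n_cc = n_cc, geometry = geometry,
                            snapshot_interval = frame_min,
                            seed = rep_seed(seed, i))
    movie <- render_movie(sim, config, seed = rep_seed(seed, i, 1L))
    q <- quantify_movie(movie)
    truth <- truth_log(sim, frame_min)
    last <- dim(movie$data)[4] - 1L
    per[[i]] <- data.frame(
      field = i,
      n0_total = q$n0_total, n0_plasma = q$n0_plasma,
      divisions_called = nrow(q$divisions),
      inductions_called = nrow(q$inductions),
      divisions_truth = sum(truth$kind == "DIVISION"),
      inductions_truth = sum(truth$kind == "INDUCTION"))
    if (score) {
      # structural dead times: a division in the final frame leaves a
      # 1-frame daughter track; an induction needs the GFP rise (~3 frames
      # at the maturation time constant) plus m persistent frames
      sc_div <- score_events(q$divisions,
                             truth$frame[truth$kind == "DIVISION"],
                             window = 2, last_frame = last,
                             dead_frames = division_params()$min_daughter_len - 1L)
      sc_ind <- score_events(q$inductions,
                             truth$frame[truth$kind == "INDUCTION"],
                             window = 15, last_frame = last,
                             dead_frames = ind_par$m + 2L)
      scores[[i]] <- data.frame(field = i,
                                f1_division = sc_div$f1,
                                f1_induction = sc_ind$f1,
                                tp_div = sc_div$tp, fp_div = sc_div$fp,
                                fn_div = sc_div$fn, tp_ind = sc_ind$tp,
                                fp_ind = sc_ind$fp, fn_ind = sc_ind$fn)
    }
  }
  per <- do.call(rbind, per)
  div <- pool_rates(per$divisions_called, per$n0_plasma, duration,
                    lag = (division_params()$min_daughter_len - 1) * frame_min)
  dif <- pool_rates(per$inductions_called, per$n0_plasma, duration,
                    lag = (ind_par$m + 2) * frame_min)
  list(per_field = per, division_rate = div, differentiation_rate = dif,
       scores = if (score) do.call(rbind, scores) else NULL)
}

#' Run one of the canonical experiment scenarios
#'
#' Binds simulation, rendering, quantification and statistics into the
#' study's four experiment designs plus the video pipeline:
#' \describe{
#'   \item{development}{24-hr trajectories of class counts; fold changes of
#'     Lz- and Lz+ cells over the horizon.}
#'   \item{rnai}{Crystal-cell counts under Notch/Serrate/Delta knockdowns
#'     versus control, compared with [compare_groups()]. Expected pattern:
#'     Notch and pan-hemocyte Serrate knockdown reduce Lz+ counts; Delta
#'     and Lz-restricted Serrate knockdown do not.}
#'   \item{disruption}{10-hr paired runs with cluster disruption every
#'     90 min versus control; both arms get a final disruption before
#'     sampling; Lz+ fraction measured by flow-style gating.}
#'   \item{contacts}{Lz+ probability versus plasmatocyte contact count,
#'     pooled over fields, with the weighted linear fit.}
#'   \item{videos}{Render + quantify + rate estimation with truth scoring
#'     (see [quantify_fields()]).}
#' }
#'
#' @param name Scenario name.
#' @param seed Base seed; every stochastic draw derives from it.
#' @param replicates Replicate count (scenario-specific default if
#'   \code{NULL}).
#' @param params A [sim_params()].
#' @param duration Minutes (scenario-specific default if \code{NULL}).
#' @param efficacy RNAi efficacy (rnai scenario).
#' @param n_larvae Larvae pooled per flow sample (disruption scenario).
#' @param ... Passed to the scenario worker ([quantify_fields()] for
#'   \code{videos}).
#' @return A list of class \code{scenario_result} with \code{name},
#'   \code{config} (resolved parameters and seeds), \code{tables} (named
#'   data frames), \code{summary} (named list).
#' @export
run_scenario <- function(name, seed = 1, replicates = NULL,
                         params = sim_params(), duration = NULL,
                         efficacy = 0.9, n_larvae = 8, ...) {
  if (!name %in% scenario_names)
    stop("unknown scenario '", name, "'; valid: ",
         paste(scenario_names, collapse = ", "))
  res <- switch(name,
    development = scenario_development(seed, replicates %||% 10,
                                       params, duration %||% 1440),
    rnai = scenario_rnai(seed, replicates %||% 12, params,
                         duration %||% 720, efficacy),
    disruption = scenario_disruption(seed, replicates %||% 20, params,
                                     duration %||% 600, n_larvae),
    contacts = scenario_contacts(seed, replicates %||% 40, params,
                                 duration %||% 180, ...),
    videos = scenario_videos(seed, replicates %||% 13, params,
                             duration %||% 180, ...))
  res$name <- name
  res$config$seed <- seed
  res$config$params <- unclass(params)
  structure(res, class = "scenario_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario '%s' (seed %s): tables %s\n", x$name,
              x$config$seed, paste(names(x$tables), collapse = ", ")))
  utils::str(x$summary, max.level = 1, give.attr = FALSE)
  invisible(x)
}

scenario_development <- function(seed, replicates, params, duration) {
  rows <- list(); folds <- list()
  for (r in seq_len(replicates)) {
    sim <- simulate_cluster(params, duration = duration,
                            snapshot_interval = 180,
                            seed = rep_seed(seed, r))
    tr <- sim$trajectory
    cnt <- do.call(rbind, lapply(seq_along(tr$times), function(i) {
      cells <- tr$states[[i]]
      data.frame(replicate = r, t = tr$times[i],
                 lz_minus = sum(cells$alive & cells$cls == "PLASMATOCYTE"),
                 lz_plus = sum(cells$alive & cells$cls != "PLASMATOCYTE"))
    }))
    rows[[r]] <- cnt
    folds[[r]] <- data.frame(
      replicate = r,
      lz_minus_fold = fold_change(cnt$lz_minus),
      lz_plus_fold = fold_change(cnt$lz_plus))
  }
  counts <- do.call(rbind, rows)
  folds <- do.call(rbind, folds)
  list(config = list(replicates = replicates, duration = duration),
       tables = list(counts = counts, folds = folds),
       summary = list(mean_lz_minus_fold = mean(folds$lz_minus_fold),
                      mean_lz_plus_fold = mean(folds$lz_plus_fold)))
}

rnai_groups <- function(efficacy) list(
  control = list(),
  notch = list(perturbation("NOTCH_RNAI", efficacy)),
  serrate_all = list(perturbation("SERRATE_RNAI_ALL", efficacy)),
  serrate_lz = list(perturbation("SERRATE_RNAI_LZ_ONLY", efficacy)),
  delta = list(perturbation("DELTA_RNAI", efficacy)))

scenario_rnai <- function(seed, replicates, params, duration, efficacy) {
  groups <- rnai_groups(efficacy)
  rows <- list()
  for (g in seq_along(groups)) {
    for (r in seq_len(replicates)) {
      sim <- simulate_cluster(params, duration = duration,
                              perturbations = groups[[g]],
                              snapshot_interval = duration,
                              seed = rep_seed(seed, r, g))
      cells <- sim$final_state$cells
      rows[[length(rows) + 1L]] <- data.frame(
        group = names(groups)[g], replicate = r,
        lz_plus = sum(cells$alive & cells$cls != "PLASMATOCYTE" &
                        cells$compartment == "SESSILE"),
        inductions = sum(sim$log$kind == "INDUCTION"))
    }
  }
  counts <- do.call(rbind, rows)
  cmp <- compare_groups(counts$lz_plus,
                        factor(counts$group, levels = names(groups)))
  list(config = list(replicates = replicates, duration = duration,
                     efficacy = efficacy),
       tables = list(counts = counts),
       summary = list(comparison = cmp,
                      means = tapply(counts$lz_plus, counts$group, mean)))
}

scenario_disruption <- function(seed, replicates, params, duration,
                                n_larvae) {
  sched_treat <- seq(90, duration, by = 90)
  sched_ctrl <- duration       # final disruption before sampling, both arms
  rows <- list()
  for (r in seq_len(replicates)) {
    for (arm in c("control", "treated")) {
      sched <- if (arm == "treated") sched_treat else sched_ctrl
      states <- lapply(seq_len(n_larvae), function(l) {
        sim <- simulate_cluster(
          params, duration = duration,
          perturbations = perturbation("DISRUPTION", schedule = sched),
          snapshot_interval = duration,
          seed = rep_seed(seed, r * 100L + l, if (arm == "treated") 1L else 2L))
        sim$final_state
      })
      ev <- synth_flow_events(states, n_events = 4000, dead_fraction = 0.05,
                              seed = rep_seed(seed, r,
                                              if (arm == "treated") 3L else 4L))
      gt <- gate_flow_events(ev)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = r, arm = arm, lz_fraction = gt$summary$lz_pos_fraction,
        viable_fraction = gt$summary$viable_fraction)
    }
  }
  tab <- do.call(rbind, rows)
  wide <- stats::reshape(tab[, c("pair", "arm", "lz_fraction")],
                         idvar = "pair", timevar = "arm", direction = "wide")
  frac_lower <- mean(wide$lz_fraction.treated < wide$lz_fraction.control)
  list(config = list(replicates = replicates, duration = duration,
                     n_larvae = n_larvae,
                     schedule_treated = sched_treat,
                     schedule_control = sched_ctrl),
       tables = list(lz_fractions = tab),
       summary = list(
         mean_treated = mean(tab$lz_fraction[tab$arm == "treated"]),
         mean_control = mean(tab$lz_fraction[tab$arm == "control"]),
         fraction_pairs_lower = frac_lower))
}

scenario_contacts <- function(seed, replicates, params, duration,
                              design = c("snapshot", "cohort"),
                              n_cc = 6) {
  # snapshot: contacts and Lz status scored on the same (final) image, as
  # in scoring a fixed projected stack. cohort: contacts scored at entry
  # (t = 0) and Lz status at the end of the window -- the cleaner design
  # for recovering the per-contact hazard, free of class-change migration
  # across contact bins.
  design <- match.arg(design)
  counts <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    sim <- simulate_cluster(params, duration = duration, n_cc = n_cc,
                            snapshot_interval = duration,
                            seed = rep_seed(seed, r))
    cc <- if (design == "snapshot") {
      count_contacts(sim$final_state, params)
    } else {
      st0 <- structure(list(cells = sim$trajectory$states[[1]],
                            geometry = sim$trajectory$geometry),
                       class = "cluster_state")
      cc0 <- count_contacts(st0, params)
      fin <- sim$final_state$cells
      cc0$cls <- fin$cls[match(cc0$id, fin$id)]
      cc0
    }
    cc$field <- r
    cc
  }))
  curve <- lz_vs_contacts(counts)
  list(config = list(replicates = replicates, duration = duration,
                     design = design, n_cc = n_cc),
       tables = list(contacts = counts, bins = curve$bins),
       summary = list(slope = curve$slope, intercept = curve$intercept,
                      slope_origin = curve$slope_origin,
                      size_gate = curve$size_gate))
}

scenario_videos <- function(seed, replicates, params, duration, ...) {
  qf <- quantify_fields(n_fields = replicates, params = params,
                        duration = duration, seed = seed, ...)
  list(config = list(replicates = replicates, duration = duration),
       tables = list(per_field = qf$per_field, scores = qf$scores),
       summary = list(
         division_rate = qf$division_rate,
         differentiation_rate = qf$differentiation_rate,
         mean_f1_division = mean(qf$scores$f1_division, na.rm = TRUE),
         mean_f1_induction = mean(qf$scores$f1_induction, na.rm = TRUE)))
}

#' Write a scenario result bundle to disk
#'
#' Writes every table as CSV, a JSON summary containing the fully resolved
#' configuration and seeds (sufficient to reproduce the run), and a PNG
#' overview figure.
#'
#' @param bundle A \code{scenario_result}.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  if (!inherits(bundle, "scenario_result") || length(bundle$tables) == 0L)
    stop("empty or invalid bundle")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(bundle$tables)) {
    p <- file.path(out_dir, paste0(bundle$name, "_", nm, ".csv"))
    utils::write.csv(bundle$tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summ <- lapply(bundle$summary, function(x) {
    if (inherits(x, "rate_estimate")) unclass(x)
    else if (inherits(x, "group_comparison"))
      list(test = x$test, path = x$path, p.value = x$p.value,
           pairwise = x$pairwise)
    else x
  })
  pj <- file.path(out_dir, paste0(bundle$name, "_summary.json"))
  jsonlite::write_json(list(name = bundle$name, config = bundle$config,
                            summary = summ),
                       pj, auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  paths <- c(paths, pj)
  pf <- file.path(out_dir, paste0(bundle$name, "_figure.png"))
  grDevices::png(pf, width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot_scenario(bundle)
  paths <- c(paths, pf)
  invisible(paths)
}

plot_scenario <- function(bundle) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old), add = TRUE)
  switch(bundle$name,
    development = {
      counts <- bundle$tables$counts
      agg_m <- tapply(counts$lz_minus, counts$t, mean)
      agg_p <- tapply(counts$lz_plus, counts$t, mean)
      t <- as.numeric(names(agg_m))
      graphics::matplot(t / 60, cbind(agg_m, agg_p), type = "b", pch = 16,
                        lty = 1, col = c("grey30", "forestgreen"),
                        xlab = "time (hr)", ylab = "mean cells / field",
                        main = "Class counts during development")
      graphics::legend("topleft", c("Hml+Lz-", "Hml+Lz+"),
                       col = c("grey30", "forestgreen"), pch = 16)
    },
    rnai = {
      counts <- bundle$tables$counts
      graphics::boxplot(lz_plus ~ group, data = counts,
                        ylab = "sessile Lz+ cells",
                        main = "Crystal cells under RNAi")
    },
    disruption = {
      tab <- bundle$tables$lz_fractions
      graphics::boxplot(lz_fraction ~ arm, data = tab,
                        ylab = "Lz+ fraction (viable singlets)",
                        main = "Cluster disruption")
    },
    contacts = {
      bins <- bundle$tables$bins
      graphics::plot(bins$k, bins$fraction, pch = 16, cex = sqrt(bins$n) / 4,
                     xlab = "plasmatocyte contacts",
                     ylab = "fraction Lz+",
                     main = "Lz+ probability vs contact count")
      graphics::abline(bundle$summary$intercept, bundle$summary$slope,
                       col = "firebrick")
    },
    videos = {
      per <- bundle$tables$per_field
      graphics::barplot(rbind(per$divisions_called, per$inductions_called),
                        beside = TRUE, names.arg = per$field,
                        col = c("grey40", "forestgreen"),
                        xlab = "field", ylab = "events",
                        main = "Called events per video")
      graphics::legend("topright", c("divisions", "inductions"),
                       fill = c("grey40", "forestgreen"))
    },
    graphics::plot.new())
}
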