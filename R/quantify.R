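#' Detection parameters for nucleus segmentation
#'
#' @param threshold_sigma Threshold above the estimated background in robust
#'   noise sigmas.
#' @param threshold_floor Minimum absolute threshold above background
#'   (intensity units); takes over on (near-)noise-free images.
#' @param min_px Minimum region size, pixels.
#' @param green_radius Radius (px) of the central disk over which the green
#'   mean grey value is measured. Kept small so that the cytoplasmic green
#'   of a large neighbouring crystal cell does not bleed into the
#'   measurement of an adjacent nucleus in the projected image.
#' @param watershed Split touching nuclei by an intensity watershed.
#' @param watershed_tolerance Minimum peak-to-saddle intensity drop for two
#'   local maxima to count as separate nuclei.
#' @return A list of class \code{detection_params}.
#' @export
detection_params <- function(threshold_sigma = 5, threshold_floor = 20,
                             min_px = 4, green_radius = 1.6,
                             watershed = TRUE, watershed_tolerance = 8) {
  structure(list(threshold_sigma = threshold_sigma,
                 threshold_floor = threshold_floor, min_px = min_px,
                 green_radius = green_radius, watershed = watershed,
                 watershed_tolerance = watershed_tolerance),
            class = "detection_params")
}

#' Detect nuclei in one red-channel frame
#'
#' Background-subtracted thresholding of the nuclear red channel with
#' optional distance-map watershed splitting of touching nuclei (as after a
#' division). For every detection the green mean grey value is measured
#' over a small disk centred on the nuclear centroid.
#'
#' @param red 2-D red-channel intensity matrix.
#' @param green Matching green-channel matrix (optional).
#' @param params A [detection_params()].
#' @param pixel_size Micrometres per pixel (for the area conversion).
#' @return Data frame, one row per nucleus: \code{x}, \code{y} (0-based
#'   pixel centroids), \code{red_total} (background-subtracted integrated
#'   intensity), \code{area_px}, \code{area_um2}, \code{green_mean},
#'   \code{green_bg} (frame-level green background estimate). Empty frame
#'   gives zero rows.
#' @export
detect_nuclei <- function(red, green = NULL, params = detection_params(),
                          pixel_size = 1) {
  bg <- stats::median(red)
  sigma <- stats::mad(red)
  thr <- bg + max(params$threshold_sigma * sigma, params$threshold_floor)
  mask <- red > thr
  empty <- data.frame(x = numeric(0), y = numeric(0), red_total = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      green_mean = numeric(0), green_bg = numeric(0))
  if (!any(mask)) return(empty)
  storage.mode(mask) <- "double"
  labels <- if (params$watershed) {
    # watershed on the background-subtracted intensity splits the merged
    # masks of adjacent nuclei (e.g. right after a division)
    EBImage::watershed(EBImage::Image(pmax(red - bg, 0) * mask),
                       tolerance = params$watershed_tolerance, ext = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  labels <- as.matrix(EBImage::imageData(labels))
  idx <- which(labels > 0)
  if (length(idx) == 0L) return(empty)
  lab <- labels[idx]
  # matrix index -> 0-based pixel coordinates: row = y, column = x
  ij <- arrayInd(idx, dim(labels))
  py <- ij[, 1] - 1; px <- ij[, 2] - 1
  w <- pmax(red[idx] - bg, 0)
  sw <- rowsum(w, lab); keep_n <- rowsum(rep(1L, length(lab)), lab)
  ok <- keep_n[, 1] >= params$min_px & sw[, 1] > 0
  if (!any(ok)) return(empty)
  cx <- (rowsum(w * px, lab) / sw)[ok, 1]
  cy <- (rowsum(w * py, lab) / sw)[ok, 1]
  red_total <- sw[ok, 1]
  area_px <- keep_n[ok, 1]
  green_mean <- rep(NA_real_, sum(ok)); green_bg <- rep(NA_real_, sum(ok))
  if (!is.null(green)) {
    gbg <- stats::median(green)
    n <- nrow(green)
    r <- params$green_radius
    off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    for (k in seq_along(cx)) {
      yy <- round(cy[k]) + off$dy + 1L
      xx <- round(cx[k]) + off$dx + 1L
      inb <- yy >= 1L & yy <= n & xx >= 1L & xx <= ncol(green)
      green_mean[k] <- mean(green[cbind(yy[inb], xx[inb])])
      green_bg[k] <- gbg
    }
  }
  data.frame(x = unname(cx), y = unname(cy), red_total = unname(red_total),
             area_px = unname(area_px),
             area_um2 = unname(area_px) * pixel_size^2,
             green_mean = green_mean, green_bg = green_bg)
}

#' Linking parameters
#'
#' @param max_disp Maximum frame-to-frame displacement, px (the gate).
#' @param max_gap Frames a track may go undetected and still be bridged.
#' @return A list of class \code{link_params}.
#' @export
link_params <- function(max_disp = 4, max_gap = 2) {
  structure(list(max_disp = max_disp, max_gap = max_gap),
            class = "link_params")
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour assignment frame to frame under a maximum
#' displacement gate; unmatched detections start new tracks; gaps up to
#' \code{max_gap} frames are bridged. Ties are broken deterministically by
#' (distance, then lower track id).
#'
#' @param detections Data frame of per-frame detections with columns
#'   \code{frame} (0-based), \code{x}, \code{y} and any measurement columns.
#' @param params A [link_params()].
#' @return List of class \code{track_set}: \code{detections} (input plus
#'   \code{track_id}) and \code{tracks} (one row per track:
#'   \code{track_id}, \code{start_frame}, \code{end_frame}, \code{n},
#'   \code{parent_id}, \code{induction_frame}).
#' @export
link_tracks <- function(detections, params = link_params()) {
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  # active track bookkeeping
  tr_id <- integer(0); tr_x <- numeric(0); tr_y <- numeric(0)
  tr_last <- integer(0)
  next_tr <- 1L
  for (f in frames) {
    rows <- which(det$frame == f)
    cand <- which(tr_last >= f - 1L - params$max_gap & tr_last < f)
    if (length(cand) > 0L && length(rows) > 0L) {
      d <- sqrt(outer(det$x[rows], tr_x[cand], "-")^2 +
                  outer(det$y[rows], tr_y[cand], "-")^2)
      pairs <- which(d <= params$max_disp, arr.ind = TRUE)
      if (nrow(pairs) > 0L) {
        ord <- order(d[pairs], tr_id[cand[pairs[, 2]]])
        used_det <- rep(FALSE, length(rows))
        used_tr <- rep(FALSE, length(cand))
        for (p in ord) {
          i <- pairs[p, 1]; j <- pairs[p, 2]
          if (used_det[i] || used_tr[j]) next
          used_det[i] <- TRUE; used_tr[j] <- TRUE
          r <- rows[i]
          det$track_id[r] <- tr_id[cand[j]]
          tr_x[cand[j]] <- det$x[r]; tr_y[cand[j]] <- det$y[r]
          tr_last[cand[j]] <- f
        }
      }
    }
    new_rows <- rows[is.na(det$track_id[rows])]
    for (r in new_rows) {
      det$track_id[r] <- next_tr
      tr_id <- c(tr_id, next_tr)
      tr_x <- c(tr_x, det$x[r]); tr_y <- c(tr_y, det$y[r])
      tr_last <- c(tr_last, f)
      next_tr <- next_tr + 1L
    }
  }
  spl <- split(seq_len(nrow(det)), det$track_id)
  tracks <- data.frame(
    track_id = as.integer(names(spl)),
    start_frame = vapply(spl, function(i) min(det$frame[i]), numeric(1)),
    end_frame = vapply(spl, function(i) max(det$frame[i]), numeric(1)),
    n = lengths(spl),
    parent_id = NA_integer_, induction_frame = NA_integer_,
    row.names = NULL)
  tracks <- tracks[order(tracks$track_id), ]
  structure(list(detections = det, tracks = tracks), class = "track_set")
}

#' Division-calling parameters
#'
#' @param r_div Maximum distance (px) between a starting daughter track and
#'   the parent's last-or-current position.
#' @param w Look-back window, frames, for the parent position.
#' @param min_daughter_len Minimum length of a track accepted as daughter.
#' @return A list of class \code{division_params}.
#' @export
division_params <- function(r_div = 7, w = 2, min_daughter_len = 2) {
  structure(list(r_div = r_div, w = w, min_daughter_len = min_daughter_len),
            class = "division_params")
}

#' Call division events from linked tracks
#'
#' A division is called when a new track begins within \code{r_div} px of
#' an existing track's last-or-current position within a window of \code{w}
#' frames; daughters are assigned the nearest such parent. Multiple
#' daughters of one parent at one frame collapse into a single event.
#'
#' @param track_set A [link_tracks()] result.
#' @param params A [division_params()].
#' @return Data frame of events: \code{frame}, \code{parent_track},
#'   \code{daughter_track}, \code{x}, \code{y} (daughter start position).
#' @export
call_divisions <- function(track_set, params = division_params()) {
  det <- track_set$detections
  tracks <- track_set$tracks
  out <- data.frame(frame = integer(0), parent_track = integer(0),
                    daughter_track = integer(0), x = numeric(0),
                    y = numeric(0))
  starters <- tracks[tracks$start_frame > min(tracks$start_frame) &
                       tracks$n >= params$min_daughter_len, , drop = FALSE]
  if (nrow(starters) == 0L) return(out)
  for (i in seq_len(nrow(starters))) {
    f0 <- starters$start_frame[i]
    tid <- starters$track_id[i]
    r0 <- which(det$track_id == tid & det$frame == f0)
    x0 <- det$x[r0]; y0 <- det$y[r0]
    # parent candidates: other tracks alive just before f0
    cand <- tracks[tracks$track_id != tid & tracks$start_frame < f0 &
                     tracks$end_frame >= f0 - params$w, , drop = FALSE]
    if (nrow(cand) == 0L) next
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(nrow(cand))) {
      rows <- which(det$track_id == cand$track_id[j] &
                      det$frame >= f0 - params$w & det$frame <= f0)
      if (length(rows) == 0L) next
      r <- rows[which.max(det$frame[rows])]
      dd <- sqrt((det$x[r] - x0)^2 + (det$y[r] - y0)^2)
      if (dd < best_d) { best_d <- dd; best <- cand$track_id[j] }
    }
    if (!is.na(best) && best_d <= params$r_div)
      out <- rbind(out, data.frame(frame = f0, parent_track = best,
                                   daughter_track = tid, x = x0, y = y0))
  }
  if (nrow(out) > 1L) {
    key <- paste(out$parent_track, out$frame)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out
}

#' Induction-calling parameters
#'
#' @param c_sigma Threshold above the green background in estimated sigmas
#'   of the green mean-grey measurement.
#' @param floor Minimum absolute threshold above background.
#' @param m Persistence: frames the green signal must stay above threshold,
#'   and the number of initial green-negative frames a track must show
#'   before an induction can be called on it.
#' @return A list of class \code{induction_params}.
#' @export
induction_params <- function(c_sigma = 5, floor = 3, m = 3) {
  structure(list(c_sigma = c_sigma, floor = floor, m = m),
            class = "induction_params")
}

# Robust estimate of the measurement noise of green_mean from within-track
# successive differences (zero on noise-free renders).
green_noise_sigma <- function(det) {
  difs <- unlist(lapply(split(det$green_mean, det$track_id), function(g) {
    if (length(g) < 2L) return(numeric(0))
    diff(g)
  }), use.names = FALSE)
  if (length(difs) < 10L) return(0)
  stats::mad(difs) / sqrt(2)
}

#' Green threshold used for induction calling
#'
#' @param track_set A [link_tracks()] result carrying \code{green_mean} and
#'   \code{green_bg}.
#' @param params An [induction_params()].
#' @return Scalar intensity threshold.
#' @export
green_threshold <- function(track_set, params = induction_params()) {
  det <- track_set$detections
  bg <- stats::median(det$green_bg, na.rm = TRUE)
  bg + max(params$c_sigma * green_noise_sigma(det), params$floor)
}

#' Call induction events from linked tracks
#'
#' An induction is called at the first frame where the green mean grey
#' value exceeds the threshold for at least \code{m} consecutive frames, in
#' a track that was green-negative for its first \code{m} frames. At most
#' one induction per track.
#'
#' @param track_set A [link_tracks()] result with green measurements.
#' @param params An [induction_params()].
#' @param threshold Optional fixed threshold; default from
#'   [green_threshold()].
#' @return Data frame of events: \code{frame}, \code{track_id}, \code{x},
#'   \code{y}.
#' @export
call_inductions <- function(track_set, params = induction_params(),
                            threshold = NULL) {
  det <- track_set$detections
  if (is.null(threshold)) threshold <- green_threshold(track_set, params)
  out <- data.frame(frame = integer(0), track_id = integer(0),
                    x = numeric(0), y = numeric(0))
  for (tid in track_set$tracks$track_id) {
    rows <- which(det$track_id == tid)
    rows <- rows[order(det$frame[rows])]
    g <- det$green_mean[rows]
    if (length(g) < 2L * params$m) next
    pos <- g > threshold
    if (any(pos[seq_len(params$m)])) next   # not green-negative at start
    runs <- rle(pos)
    ends <- cumsum(runs$lengths)
    hit <- which(runs$values & runs$lengths >= params$m)
    if (length(hit) == 0L) next
    first <- ends[hit[1]] - runs$lengths[hit[1]] + 1L
    r <- rows[first]
    out <- rbind(out, data.frame(frame = det$frame[r], track_id = tid,
                                 x = det$x[r], y = det$y[r]))
  }
  out
}

#' A per-3-hr rate estimate with binomial uncertainty
#'
#' Converts an event count over an observation window into a proportion per
#' the canonical 3-hr window using the geometric-hazard rescaling of
#' [rescale_proportion()] (not linear scaling).
#'
#' @param n_events Number of events observed.
#' @param n_initial Initial at-risk cell count (> 0).
#' @param duration Observation duration, minutes.
#' @param window Reference window, minutes (default 180).
#' @param lag Detection dead time, minutes, subtracted from the effective
#'   duration (e.g. the persistence requirement of induction calling).
#' @return Object of class \code{rate_estimate}: \code{proportion} (per
#'   window), \code{se} (binomial), \code{n_events}, \code{n_initial},
#'   \code{duration}, \code{window}.
#' @export
estimate_rate <- function(n_events, n_initial, duration, window = 180,
                          lag = 0) {
  if (n_initial <= 0) stop("zero denominator: 'n_initial' must be > 0")
  if (duration - lag <= 0) stop("effective duration must be positive")
  p_obs <- min(n_events / n_initial, 1)
  p_win <- rescale_proportion(p_obs, duration - lag, window)
  se <- sqrt(p_win * (1 - p_win) / n_initial)
  structure(list(proportion = p_win, se = se, n_events = n_events,
                 n_initial = n_initial, duration = duration,
                 window = window, lag = lag),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.4f per %.0f min (%d/%d events, SE %.4f)\n",
              x$proportion, x$window, x$n_events, x$n_initial, x$se))
  invisible(x)
}

#' Pool per-field event counts into one rate estimate
#'
#' The pooled estimate is the event-weighted mean of the per-field
#' estimates: total events over total initial cells.
#'
#' @param n_events Vector of per-field event counts.
#' @param n_initial Vector of per-field initial counts.
#' @param duration,window,lag As in [estimate_rate()].
#' @return A \code{rate_estimate}.
#' @export
pool_rates <- function(n_events, n_initial, duration, window = 180, lag = 0) {
  estimate_rate(sum(n_events), sum(n_initial), duration, window, lag)
}

#' Lz+ probability versus plasmatocyte contact count
#'
#' For each contact count k, the fraction of size-gated cells that are Lz+
#' among those with k plasmatocyte contacts, with an ordinary
#' least-squares line through (k, fraction) weighted by bin counts. The
#' size gate (default: the maximum plasmatocyte area in the sample)
#' restricts the comparison to cells within the plasmatocyte size range.
#'
#' @param counts A [count_contacts()] data frame (or one with columns
#'   \code{cls}, \code{area}, \code{k_plasma}, \code{compartment}).
#' @param size_gate Maximum area included; \code{NULL} uses the maximum
#'   plasmatocyte area.
#' @return List of class \code{lz_contact_curve}: \code{bins} (k, n,
#'   n_lz_pos, fraction), \code{slope}, \code{intercept}, \code{fit} (the
#'   \code{lm} object), \code{size_gate}.
#' @export
lz_vs_contacts <- function(counts, size_gate = NULL) {
  if (is.null(size_gate)) {
    pa <- counts$area[counts$cls == "PLASMATOCYTE"]
    if (length(pa) == 0L) stop("no plasmatocytes to define the size gate")
    size_gate <- max(pa)
  }
  sub <- counts[counts$area <= size_gate &
                  counts$compartment == "SESSILE", , drop = FALSE]
  if (nrow(sub) == 0L) stop("all bins empty after size gating")
  ks <- sort(unique(sub$k_plasma))
  bins <- do.call(rbind, lapply(ks, function(k) {
    s <- sub[sub$k_plasma == k, ]
    data.frame(k = k, n = nrow(s),
               n_lz_pos = sum(s$cls != "PLASMATOCYTE"),
               fraction = mean(s$cls != "PLASMATOCYTE"))
  }))
  fit <- stats::lm(fraction ~ k, data = bins, weights = bins$n)
  # through-origin slope: the model's functional form has zero intercept
  # (no lateral induction without contacts), and this estimator is far more
  # stable at the event counts of a 3-hr window
  slope0 <- sum(bins$n * bins$k * bins$fraction) / sum(bins$n * bins$k^2)
  structure(list(bins = bins,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_origin = slope0,
                 fit = fit, size_gate = size_gate),
            class = "lz_contact_curve")
}

#' @export
print.lz_contact_curve <- function(x, ...) {
  cat(sprintf("Lz+ fraction vs contacts: slope %.4f, intercept %.4f (%d bins, %d cells)\n",
              x$slope, x$intercept, nrow(x$bins), sum(x$bins$n)))
  invisible(x)
}

#' Run the full measurement pipeline on a movie
#'
#' Detect nuclei in every frame, link tracks, call divisions and
#' inductions, and estimate per-3-hr division and differentiation
#' proportions. The division denominator is the number of green-negative
#' tracks present at frame 0; induction rates use an effective duration
#' shortened by the persistence dead time of the induction caller.
#'
#' @param movie A \code{hemo_movie}.
#' @param det_params,lnk_params,div_params,ind_params Pipeline stage
#'   parameter objects.
#' @return List of class \code{movie_quant}: \code{detections},
#'   \code{track_set}, \code{divisions}, \code{inductions},
#'   \code{n0_total}, \code{n0_plasma}, \code{division_rate},
#'   \code{differentiation_rate}, \code{green_thr}.
#' @export
quantify_movie <- function(movie, det_params = detection_params(),
                           lnk_params = link_params(),
                           div_params = division_params(),
                           ind_params = induction_params()) {
  cfg <- movie$config
  n_frames <- dim(movie$data)[4]
  dets <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    d <- detect_nuclei(movie$data[, , 1L, f], movie$data[, , 2L, f],
                       det_params, cfg$pixel_size)
    if (nrow(d) > 0L) d$frame <- f - 1L
    dets[[f]] <- d
  }
  detections <- do.call(rbind, dets[vapply(dets, nrow, integer(1)) > 0])
  if (is.null(detections) || nrow(detections) == 0L)
    stop("no detections in any frame")
  ts <- link_tracks(detections, lnk_params)
  divisions <- call_divisions(ts, div_params)
  thr <- green_threshold(ts, ind_params)
  inductions <- call_inductions(ts, ind_params, threshold = thr)

  frame_min <- cfg$frame_interval / 60
  duration <- (n_frames - 1L) * frame_min
  det0 <- ts$detections[ts$detections$frame == 0L, ]
  n0_total <- nrow(det0)
  n0_plasma <- sum(det0$green_mean <= thr)
  division_rate <- differentiation_rate <- NULL
  if (n0_plasma > 0) {
    division_rate <- estimate_rate(nrow(divisions), n0_plasma, duration,
                                   lag = (div_params$min_daughter_len - 1) *
                                     frame_min)
    differentiation_rate <- estimate_rate(nrow(inductions), n0_plasma,
                                          duration,
                                          lag = (ind_params$m + 2) * frame_min)
  }
  structure(list(detections = detections, track_set = ts,
                 divisions = divisions, inductions = inductions,
                 n0_total = n0_total, n0_plasma = n0_plasma,
                 division_rate = division_rate,
                 differentiation_rate = differentiation_rate,
                 green_thr = thr),
            class = "movie_quant")
}

#' Score called events against a ground-truth log
#'
#' Greedy one-to-one matching of called to truth events on frame distance.
#' Truth events too late to be observable (within \code{dead_frames} of the
#' movie end) are excluded from the reference set, mirroring the fact that
#' a scorer cannot call an event whose persistence window extends past the
#' last frame.
#'
#' @param called Data frame with a \code{frame} column.
#' @param truth_frames Integer vector of truth event frames.
#' @param window Maximum |frame difference| for a match.
#' @param last_frame Last (0-based) movie frame index.
#' @param dead_frames Truth events with frame > last_frame - dead_frames
#'   are dropped from the reference set.
#' @return List: \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, \code{f1}, \code{n_truth_scored}.
#' @export
score_events <- function(called, truth_frames, window = 5, last_frame = NULL,
                         dead_frames = 0) {
  if (!is.null(last_frame) && dead_frames > 0)
    truth_frames <- truth_frames[truth_frames <= last_frame - dead_frames]
  cf <- sort(called$frame)
  tf <- sort(truth_frames)
  used <- rep(FALSE, length(tf))
  tp <- 0L
  for (f in cf) {
    d <- abs(tf - f)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1L && is.finite(d[j]) && d[j] <= window) {
      used[j] <- TRUE; tp <- tp + 1L
    }
  }
  fp <- length(cf) - tp
  fn <- length(tf) - tp
  precision <- if (length(cf) > 0) tp / length(cf) else NA_real_
  recall <- if (length(tf) > 0) tp / length(tf) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, n_truth_scored = length(tf))
}
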