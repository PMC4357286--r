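#' Imaging configuration for synthetic time-lapse rendering
#'
#' Describes the forward model for the two-channel confocal movies: a
#' nuclear red channel (Gaussian blobs, one per Hml+ nucleus) and a
#' cytoplasmic green channel (soft-edged disks whose amplitude follows the
#' Lz>GFP reporter), over a single projected plane. Default timing matches
#' the live protocol: one frame every 90 s for 3 hr, i.e. 121 frames.
#'
#' @param frame_interval Seconds between frames (default 90).
#' @param duration Movie duration in minutes (default 180);
#'   \code{duration * 60 / frame_interval} must be integral.
#' @param pixel_size Micrometres per pixel.
#' @param field_px Square field side, pixels.
#' @param psf_sigma Gaussian sigma of a rendered nucleus, pixels.
#' @param background Constant background level, intensity units.
#' @param noise_gaussian_sd Additive Gaussian read-noise sigma (0 = none).
#' @param noise_poisson Logical; apply Poisson shot noise to the noise-free
#'   intensities before read noise.
#' @param green_edge Logistic edge width of the cytoplasmic disk, pixels.
#' @param red_scale,green_scale Multiplicative gains applied to the cell
#'   marker intensities.
#' @return An object of class \code{imaging_config}.
#' @export
imaging_config <- function(frame_interval = 90, duration = 180,
                           pixel_size = 1, field_px = 128,
                           psf_sigma = 1.6, background = 10,
                           noise_gaussian_sd = 2, noise_poisson = FALSE,
                           green_edge = 0.4, red_scale = 1, green_scale = 1) {
  n <- duration * 60 / frame_interval
  if (abs(n - round(n)) > 1e-9)
    stop("duration/frame_interval must be integral")
  structure(list(frame_interval = frame_interval, duration = duration,
                 pixel_size = pixel_size, field_px = as.integer(field_px),
                 psf_sigma = psf_sigma, background = background,
                 noise_gaussian_sd = noise_gaussian_sd,
                 noise_poisson = noise_poisson, green_edge = green_edge,
                 red_scale = red_scale, green_scale = green_scale,
                 n_frames = as.integer(round(n)) + 1L,
                 channels = c(RED = "nuclear", GREEN = "cytoplasmic")),
            class = "imaging_config")
}

# Add a radially symmetric profile centred at (cx, cy) (0-based pixel
# coordinates, pixel centres at integers) to `img` in place.
add_blob <- function(img, cx, cy, amplitude, profile, reach) {
  n <- nrow(img)
  x0 <- max(0L, floor(cx - reach)); x1 <- min(n - 1L, ceiling(cx + reach))
  y0 <- max(0L, floor(cy - reach)); y1 <- min(n - 1L, ceiling(cy + reach))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amplitude * profile(d)
  img
}

#' Render one two-channel frame from a cluster snapshot
#'
#' Pure function of (cells, config): the red channel is a sum of Gaussian
#' nuclear blobs with amplitude proportional to \code{hml_red}; the green
#' channel a sum of soft-edged disks of radius \code{sqrt(area/pi)} with
#' amplitude proportional to \code{lz_gfp}. Only sessile, alive cells are
#' rendered (circulating cells have left the imaged plane). Noise is added
#' by [render_movie()], not here, unless \code{noise = TRUE}.
#'
#' @param cells Cell table of a \code{cluster_state} (or the state itself).
#' @param config An [imaging_config()].
#' @param noise Add the configured noise to this single frame.
#' @return Numeric array \code{field_px x field_px x 2}; channel 1 = red,
#'   channel 2 = green. Pixel (1, 1) has 0-based centre (0, 0).
#' @export
render_frame <- function(cells, config = imaging_config(), noise = FALSE) {
  if (inherits(cells, "cluster_state")) cells <- cells$cells
  npx <- config$field_px
  red <- matrix(config$background, npx, npx)
  green <- matrix(config$background, npx, npx)
  sel <- which(cells$alive & cells$compartment == "SESSILE")
  for (i in sel) {
    cx <- cells$x[i] / config$pixel_size
    cy <- cells$y[i] / config$pixel_size
    r_px <- cell_radius(cells$area[i]) / config$pixel_size
    if (cx < 0 || cy < 0 || cx > npx - 1 || cy > npx - 1)
      stop(sprintf("cell %d at (%.1f, %.1f) px lies outside the %d px field",
                   cells$id[i], cx, cy, npx))
    s <- config$psf_sigma
    red <- add_blob(red, cx, cy, config$red_scale * cells$hml_red[i],
                    function(d) exp(-d^2 / (2 * s^2)), reach = 4 * s)
    if (cells$lz_gfp[i] > 0) {
      e <- config$green_edge
      green <- add_blob(green, cx, cy, config$green_scale * cells$lz_gfp[i],
                        function(d) 1 / (1 + exp((d - r_px) / e)),
                        reach = r_px + 6 * e)
    }
  }
  out <- array(c(red, green), dim = c(npx, npx, 2L),
               dimnames = list(NULL, NULL, c("RED", "GREEN")))
  if (noise) out <- add_noise(out, config)
  out
}

add_noise <- function(frame, config) {
  if (config$noise_poisson) frame[] <- stats::rpois(length(frame), pmax(frame, 0))
  if (config$noise_gaussian_sd > 0)
    frame <- frame + stats::rnorm(length(frame), 0, config$noise_gaussian_sd)
  pmax(frame, 0)
}

#' Render a simulated trajectory into a two-channel movie
#'
#' One frame per trajectory snapshot; the ground-truth event log is carried
#' through with event times mapped to 0-based frame indices. Rendering is a
#' pure function of (trajectory, config, seed).
#'
#' @param sim A \code{hemo_sim} (or its \code{trajectory}); the snapshot
#'   interval must equal the frame interval.
#' @param config An [imaging_config()].
#' @param seed Seed for the noise draws (ignored when the config is
#'   noise-free).
#' @return An object of class \code{hemo_movie}: list with \code{data}
#'   (array \code{h x w x 2 x n_frames}), \code{config}, \code{truth}
#'   (event log with \code{frame} column), \code{seed}.
#' @export
render_movie <- function(sim, config = imaging_config(), seed = 1) {
  traj <- if (inherits(sim, "hemo_sim")) sim$trajectory else sim
  truth <- if (inherits(sim, "hemo_sim"))
    truth_log(sim, config$frame_interval / 60) else NULL
  frame_min <- config$frame_interval / 60
  if (abs(traj$snapshot_interval - frame_min) > 1e-9)
    stop(sprintf("trajectory snapshot interval (%.2f min) must equal the frame interval (%.2f min)",
                 traj$snapshot_interval, frame_min))
  n_frames <- length(traj$states)
  npx <- config$field_px
  data <- array(0, dim = c(npx, npx, 2L, n_frames))
  if (!is.null(seed)) set.seed(seed)
  for (f in seq_len(n_frames)) {
    fr <- render_frame(traj$states[[f]], config, noise = FALSE)
    data[, , , f] <- add_noise(fr, config)
  }
  structure(list(data = data, config = config, truth = truth, seed = seed,
                 times = traj$times),
            class = "hemo_movie")
}

#' @export
print.hemo_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hemo_movie: %d frames, %d x %d px, 2 channels (%s)\n",
              d[4], d[1], d[2],
              paste(names(x$config$channels), collapse = "/")))
  invisible(x)
}

#' Extract one channel of one frame
#'
#' @param movie A \code{hemo_movie}.
#' @param frame 0-based frame index.
#' @param channel \code{"RED"} or \code{"GREEN"}.
#' @return A matrix.
#' @export
movie_frame <- function(movie, frame, channel = c("RED", "GREEN")) {
  channel <- match.arg(channel)
  movie$data[, , if (channel == "RED") 1L else 2L, frame + 1L]
}

#' Write a movie as multi-page TIFF plus JSON sidecar
#'
#' Pages are frame-major with the red page preceding the green page of each
#' frame; intensities are stored as 16-bit unsigned. The sidecar records
#' the imaging configuration, seed, page layout, and ground-truth events.
#'
#' @param movie A \code{hemo_movie}.
#' @param path Output TIFF path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$data)
  pages <- vector("list", d[4] * 2L)
  for (f in seq_len(d[4])) {
    pages[[2L * f - 1L]] <- movie$data[, , 1L, f]
    pages[[2L * f]] <- movie$data[, , 2L, f]
  }
  pages <- lapply(pages, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(config = unclass(movie$config), seed = movie$seed,
                  layout = "frame-major; channels RED,GREEN per frame",
                  n_frames = d[4],
                  truth = movie$truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path with its JSON sidecar alongside.
#' @return A \code{hemo_movie}.
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- side$config
  config <- imaging_config(frame_interval = cfg$frame_interval,
                           duration = cfg$duration,
                           pixel_size = cfg$pixel_size,
                           field_px = cfg$field_px, psf_sigma = cfg$psf_sigma,
                           background = cfg$background,
                           noise_gaussian_sd = cfg$noise_gaussian_sd,
                           noise_poisson = cfg$noise_poisson,
                           green_edge = cfg$green_edge,
                           red_scale = cfg$red_scale,
                           green_scale = cfg$green_scale)
  n_frames <- length(pages) / 2L
  npx <- nrow(pages[[1]])
  data <- array(0, dim = c(npx, npx, 2L, n_frames))
  for (f in seq_len(n_frames)) {
    data[, , 1L, f] <- pages[[2L * f - 1L]] * 65535
    data[, , 2L, f] <- pages[[2L * f]] * 65535
  }
  truth <- side$truth
  if (!is.null(truth) && length(truth)) truth <- as.data.frame(truth)
  structure(list(data = data, config = config, truth = truth,
                 seed = side$seed, times = NULL),
            class = "hemo_movie")
}
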