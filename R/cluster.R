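#' Cluster geometry
#'
#' A sessile cluster is modelled as a 2-D disk packing: the 28-um projected
#' Z-stack is collapsed to one plane, cells are disks whose radii derive
#' from their areas, and nuclei never overlap. Positions are in micrometres
#' with the origin at the field's top-left corner.
#'
#' @param field_um Side length of the (square) imaged field, um.
#' @param cluster_radius Radius of the disk within which cells are seeded, um.
#' @param center Cluster centre, um; defaults to the field centre.
#' @param max_tries Rejection-sampling budget per cell; the whole packing is
#'   restarted a few times before being declared infeasible.
#' @return An object of class \code{cluster_geometry}.
#' @export
cluster_geometry <- function(field_um = 128, cluster_radius = 44,
                             center = NULL, max_tries = 2000L) {
  if (is.null(center)) center <- c(field_um / 2, field_um / 2)
  if (cluster_radius <= 0 || field_um <= 0) stop("sizes must be positive")
  structure(list(field_um = field_um, cluster_radius = cluster_radius,
                 center = center, max_tries = as.integer(max_tries)),
            class = "cluster_geometry")
}

cell_cols <- c("id", "cls", "hml_red", "lz_gfp", "area", "area0", "x", "y",
               "compartment", "t_induced", "phago", "notch_eff",
               "serrate_eff", "alive")

empty_cells <- function() {
  data.frame(id = integer(0), cls = character(0), hml_red = numeric(0),
             lz_gfp = numeric(0), area = numeric(0), area0 = numeric(0),
             x = numeric(0), y = numeric(0), compartment = character(0),
             t_induced = numeric(0), phago = numeric(0),
             notch_eff = numeric(0), serrate_eff = numeric(0),
             alive = logical(0), stringsAsFactors = FALSE)
}

cell_radius <- function(area) sqrt(area / pi)

# Rejection-sample positions in the cluster disk so that no two cell disks
# overlap (centre distance >= sum of radii). Cells are placed largest-first,
# which eases packing at the densities used here; a stuck packing is
# restarted from scratch a few times before giving up.
place_cells <- function(radii, geometry, restarts = 5L) {
  n <- length(radii)
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  ord <- order(radii, decreasing = TRUE)
  for (attempt in seq_len(restarts)) {
    xs <- numeric(n); ys <- numeric(n)
    px <- numeric(n); py <- numeric(n); pr <- numeric(n)
    placed <- 0L
    failed <- FALSE
    for (i in ord) {
      ok <- FALSE
      for (try in seq_len(geometry$max_tries)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- geometry$cluster_radius * sqrt(stats::runif(1))
        x <- geometry$center[1] + rad * cos(ang)
        y <- geometry$center[2] + rad * sin(ang)
        if (x - radii[i] < 0 || y - radii[i] < 0 ||
            x + radii[i] > geometry$field_um ||
            y + radii[i] > geometry$field_um)
          next
        if (placed == 0L ||
            all((px[seq_len(placed)] - x)^2 + (py[seq_len(placed)] - y)^2 >=
                (pr[seq_len(placed)] + radii[i])^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) { failed <- TRUE; break }
      placed <- placed + 1L
      px[placed] <- x; py[placed] <- y; pr[placed] <- radii[i]
      xs[i] <- x; ys[i] <- y
    }
    if (!failed) return(cbind(x = xs, y = ys))
  }
  stop(sprintf(paste0("packing infeasible: could not place %d cells ",
                      "(max radius %.2f um) in a cluster of radius %.1f um"),
               n, max(radii), geometry$cluster_radius))
}

#' GFP intensity of a crystal cell as a function of time since induction
#'
#' Saturating-exponential maturation law:
#' \code{gfp(t) = gfp_max * (1 - exp(-t / tau_mat))}.
#'
#' @param t_induced Minutes since induction.
#' @param params A [sim_params()] object.
#' @return GFP intensity, arbitrary units.
#' @export
maturation_gfp <- function(t_induced, params) {
  params$gfp_max * (1 - exp(-t_induced / params$tau_mat))
}

#' Initialize a sessile hemocyte cluster
#'
#' Seeds \code{n_plasma} plasmatocytes (Hml+Lz-) and \code{n_cc} crystal
#' cells (Hml+Lz+, split GFP-low/GFP-high by
#' \code{params$cc_mature_fraction}) at non-overlapping positions inside the
#' cluster disk and builds the initial contact graph. A typical imaged field
#' carries about 50 plasmatocytes and 6 crystal cells.
#'
#' @param n_plasma,n_cc Non-negative cell counts.
#' @param geometry A [cluster_geometry()] object.
#' @param params A [sim_params()] object.
#' @return A \code{cluster_state}: list with elements \code{cells} (one row
#'   per cell), \code{t} (minutes), \code{edges} (two-column matrix of
#'   contacting cell ids), \code{next_id}, \code{geometry}.
#' @export
init_cluster <- function(n_plasma, n_cc, geometry = cluster_geometry(),
                         params = sim_params()) {
  if (n_plasma < 0 || n_cc < 0) stop("cell counts must be >= 0")
  n <- n_plasma + n_cc
  if (n == 0L) {
    state <- structure(list(cells = empty_cells(), t = 0,
                            edges = cbind(id1 = integer(0), id2 = integer(0)),
                            next_id = 1L, geometry = geometry),
                       class = "cluster_state")
    return(state)
  }
  n_mature <- round(n_cc * params$cc_mature_fraction)
  cls <- c(rep("PLASMATOCYTE", n_plasma),
           rep("MATURE_CC", n_mature),
           rep("INDUCED_CC", n_cc - n_mature))
  area0 <- stats::rlnorm(n, meanlog = log(50), sdlog = 0.08)
  # Time since induction for seeded crystal cells: mature cells past the
  # GFP-high crossing, induced cells spread over the pre-crossing range.
  t_cross <- -params$tau_mat *
    log(1 - params$gfp_high_threshold / params$gfp_max)
  t_induced <- rep(NA_real_, n)
  is_mat <- cls == "MATURE_CC"
  is_ind <- cls == "INDUCED_CC"
  t_induced[is_mat] <- stats::runif(sum(is_mat), t_cross * 1.1, t_cross * 4)
  t_induced[is_ind] <- stats::runif(sum(is_ind), 30, t_cross * 0.9)
  lz_gfp <- ifelse(is.na(t_induced), 0, maturation_gfp(t_induced, params))
  area <- area0 * (1 + params$area_gain * lz_gfp / params$gfp_max)
  cells <- data.frame(
    id = seq_len(n), cls = cls,
    hml_red = stats::rlnorm(n, meanlog = log(params$hml_red), sdlog = 0.08),
    lz_gfp = lz_gfp, area = area, area0 = area0,
    x = 0, y = 0, compartment = rep("SESSILE", n),
    t_induced = t_induced, phago = 1 - lz_gfp / params$gfp_max,
    notch_eff = 1, serrate_eff = 1, alive = TRUE,
    stringsAsFactors = FALSE)
  pos <- place_cells(cell_radius(cells$area), geometry)
  cells$x <- pos[, "x"]; cells$y <- pos[, "y"]
  state <- structure(list(cells = cells, t = 0, edges = NULL,
                          next_id = n + 1L, geometry = geometry),
                     class = "cluster_state")
  state$edges <- build_contact_graph(state, params)
  state
}

#' @export
print.cluster_state <- function(x, ...) {
  tab <- table(factor(x$cells$cls,
                      levels = c("PLASMATOCYTE", "INDUCED_CC", "MATURE_CC")))
  cat(sprintf("cluster_state at t = %.1f min: %d cells (%s), %d contacts\n",
              x$t, nrow(x$cells),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Build the contact graph of a cluster
#'
#' An undirected edge joins two cells iff both are sessile and alive and
#' their centre distance is at most
#' \code{contact_radius_factor * (r_i + r_j)}, with radii derived from
#' areas. Circulating cells have degree zero by construction.
#'
#' @param state A \code{cluster_state}.
#' @param params A [sim_params()] object.
#' @return Two-column integer matrix of cell id pairs (id1 < id2).
#' @export
build_contact_graph <- function(state, params = sim_params()) {
  cells <- state$cells
  sess <- which(cells$compartment == "SESSILE" & cells$alive)
  out <- cbind(id1 = integer(0), id2 = integer(0))
  if (length(sess) < 2L) return(out)
  x <- cells$x[sess]; y <- cells$y[sess]
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite cell positions")
  r <- cell_radius(cells$area[sess])
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  lim <- (params$contact_radius_factor * outer(r, r, "+"))^2
  adj <- d2 <= lim
  adj[!upper.tri(adj)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  cbind(id1 = cells$id[sess[idx[, 1]]], id2 = cells$id[sess[idx[, 2]]])
}

#' Per-cell contact counts
#'
#' Scores, for every sessile cell, its total number of contacts and the
#' Serrate-weighted number of plasmatocyte (Lz-) contacts that drive the
#' induction hazard.
#'
#' @param state A \code{cluster_state}.
#' @param params A [sim_params()] object (controls the contact criterion).
#' @return Data frame with columns \code{id}, \code{cls}, \code{area},
#'   \code{compartment}, \code{k_total}, \code{k_plasma}, \code{k_eff}.
#' @export
count_contacts <- function(state, params = sim_params()) {
  cells <- state$cells
  edges <- build_contact_graph(state, params)
  k_total <- k_plasma <- k_eff <- stats::setNames(numeric(nrow(cells)), cells$id)
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      a <- as.character(edges[k, 1]); b <- as.character(edges[k, 2])
      ra <- match(edges[k, 1], cells$id); rb <- match(edges[k, 2], cells$id)
      k_total[a] <- k_total[a] + 1; k_total[b] <- k_total[b] + 1
      if (cells$cls[rb] == "PLASMATOCYTE") {
        k_plasma[a] <- k_plasma[a] + 1
        k_eff[a] <- k_eff[a] + cells$serrate_eff[rb]
      }
      if (cells$cls[ra] == "PLASMATOCYTE") {
        k_plasma[b] <- k_plasma[b] + 1
        k_eff[b] <- k_eff[b] + cells$serrate_eff[ra]
      }
    }
  }
  data.frame(id = cells$id, cls = cells$cls, area = cells$area,
             compartment = cells$compartment,
             k_total = unname(k_total), k_plasma = unname(k_plasma),
             k_eff = unname(k_eff), stringsAsFactors = FALSE)
}
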