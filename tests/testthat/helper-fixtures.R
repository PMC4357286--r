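# Build a cluster_state directly from positions/attributes, bypassing the
# random packing, for geometry- and rendering-level tests.
make_cells <- function(x, y, area = 50, cls = "PLASMATOCYTE", lz_gfp = 0,
                       hml_red = 150, compartment = "SESSILE",
                       serrate_eff = 1, notch_eff = 1) {
  n <- length(x)
  if (n == 0L)
    return(data.frame(id = integer(0), cls = character(0),
                      hml_red = numeric(0), lz_gfp = numeric(0),
                      area = numeric(0), area0 = numeric(0), x = numeric(0),
                      y = numeric(0), compartment = character(0),
                      t_induced = numeric(0), phago = numeric(0),
                      notch_eff = numeric(0), serrate_eff = numeric(0),
                      alive = logical(0), stringsAsFactors = FALSE))
  rep_n <- function(v) rep_len(v, n)
  data.frame(id = seq_len(n), cls = rep_n(cls), hml_red = rep_n(hml_red),
             lz_gfp = rep_n(lz_gfp), area = rep_n(area),
             area0 = rep_n(area), x = x, y = y,
             compartment = rep_n(compartment),
             t_induced = ifelse(rep_n(cls) == "PLASMATOCYTE", NA_real_, 100),
             phago = 1 - rep_n(lz_gfp) / 200,
             notch_eff = rep_n(notch_eff), serrate_eff = rep_n(serrate_eff),
             alive = TRUE, stringsAsFactors = FALSE)
}

make_state <- function(cells, t = 0, geometry = cluster_geometry(),
                       params = sim_params()) {
  st <- structure(list(cells = cells, t = t, edges = NULL,
                       next_id = max(cells$id, 0L) + 1L,
                       geometry = geometry),
                  class = "cluster_state")
  st$edges <- build_contact_graph(st, params)
  st
}

# One-snapshot trajectory wrapper so render_movie can be fed hand-built
# frames.
make_trajectory <- function(states, interval = 1.5, params = sim_params()) {
  structure(list(times = (seq_along(states) - 1L) * interval,
                 states = states, snapshot_interval = interval,
                 params = params, geometry = cluster_geometry()),
            class = "trajectory")
}

alive_count <- function(cells) sum(cells$alive)
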