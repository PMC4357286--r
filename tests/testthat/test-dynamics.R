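test_that("per-window proportions convert to per-step probabilities", {
  # direct evaluation of 1 - 0.93^(1/120)
  expect_equal(per_step_probability(0.07, 1.5), 1 - 0.93^(1 / 120),
               tolerance = 1e-12)
  expect_lt(abs(per_step_probability(0.07, 1.5) - 6.046e-4), 1e-7)
  expect_identical(per_step_probability(0, 7.5), 0)
  expect_equal(per_step_probability(0.035, 180), 0.035)
  # round trip with the window rescaling
  p_step <- per_step_probability(0.07, 1.5)
  expect_equal(rescale_proportion(p_step, 1.5, 180), 0.07, tolerance = 1e-12)
  expect_error(per_step_probability(1.2, 1.5), "0, 1")
  expect_error(per_step_probability(0.1, 7), "divide 180")
})

test_that("induction probability is contact-linear, Notch-gated, and refuses crystal cells", {
  p <- sim_params(beta_contact = 0.01)
  plasma <- list(cls = "PLASMATOCYTE", notch_eff = 1)
  expect_identical(induction_probability(plasma, 0, p), 0)
  knocked <- list(cls = "PLASMATOCYTE", notch_eff = 0)
  expect_identical(induction_probability(knocked, 5, p), 0)
  # identity window: linear form is exact
  expect_equal(induction_probability(plasma, 4, p, dt = 180), 0.04)
  # strictly increasing below saturation
  p_k <- vapply(1:6, function(k) induction_probability(plasma, k, p),
                numeric(1))
  expect_true(all(diff(p_k) > 0))
  cc <- list(cls = "MATURE_CC", notch_eff = 1)
  expect_error(induction_probability(cc, 2, p), "plasmatocytes only")
})

test_that("cluster initialization honours counts, marker states, and seed determinism", {
  p <- sim_params()
  set.seed(11)
  st <- init_cluster(50, 6, cluster_geometry(), p)
  expect_equal(nrow(st$cells), 56)
  expect_equal(sum(st$cells$lz_gfp == 0), 50)
  expect_equal(sum(st$cells$cls == "PLASMATOCYTE"), 50)
  # marker invariant both ways
  expect_true(all((st$cells$cls == "PLASMATOCYTE") == (st$cells$lz_gfp == 0)))
  expect_true(all(st$cells$area > 0))
  # empty case
  set.seed(11)
  st0 <- init_cluster(0, 0, cluster_geometry(), p)
  expect_equal(nrow(st0$cells), 0)
  expect_equal(nrow(st0$edges), 0)
  # determinism under a fixed seed
  set.seed(42); a <- init_cluster(30, 4, cluster_geometry(), p)
  set.seed(42); b <- init_cluster(30, 4, cluster_geometry(), p)
  expect_identical(a$cells, b$cells)
  # infeasible packing fails loudly
  expect_error({
    set.seed(1)
    init_cluster(500, 0, cluster_geometry(cluster_radius = 20,
                                          max_tries = 50), p)
  }, "packing infeasible")
})

test_that("contact graph joins sessile cells within the radius criterion only", {
  p <- sim_params(contact_radius_factor = 1)
  r <- cell_radius(50)
  # distance 0.9 x (r_i + r_j) with factor 1 -> one edge
  st <- make_state(make_cells(x = c(30, 30 + 1.8 * r), y = c(30, 30)),
                   params = p)
  expect_equal(nrow(st$edges), 1)
  # distance 2 x (r_i + r_j) -> none
  st2 <- make_state(make_cells(x = c(30, 30 + 4 * r), y = c(30, 30)),
                    params = p)
  expect_equal(nrow(st2$edges), 0)
  # circulating cells have degree zero
  st3 <- make_state(make_cells(x = c(30, 30 + 1.8 * r), y = c(30, 30),
                               compartment = c("SESSILE", "CIRCULATION")),
                    params = p)
  expect_equal(nrow(st3$edges), 0)
  k <- count_contacts(st3, p)
  expect_equal(k$k_total, c(0, 0))
})

test_that("frozen dynamics leave everything but maturation unchanged", {
  p <- sim_params(p_div_3h = 0, beta_contact = 0, k_detach = 0, k_attach = 0)
  set.seed(5)
  st <- init_cluster(20, 4, cluster_geometry(), p)
  res <- step_cluster(st, p)
  expect_equal(nrow(res$state$cells), nrow(st$cells))
  expect_identical(res$state$cells$id, st$cells$id)
  expect_identical(res$state$cells$cls, st$cells$cls)
  expect_identical(res$state$cells$x, st$cells$x)
  expect_equal(nrow(res$events), 0)
  cc <- st$cells$cls != "PLASMATOCYTE"
  expect_true(all(res$state$cells$lz_gfp[cc] > st$cells$lz_gfp[cc]))
  expect_identical(res$state$cells$lz_gfp[!cc], st$cells$lz_gfp[!cc])
})

test_that("crystal cells never divide and cell counts balance the event log", {
  p <- sim_params(p_death_3h = 0.02)   # exercise deaths too
  sim <- simulate_cluster(p, 360, seed = 61, snapshot_interval = 360)
  log <- sim$log
  # replay: the set of Lz+ cells grows by INDUCTION; no DIVISION parent may
  # ever be in it
  cc_ids <- sim$trajectory$states[[1]]$id[
    sim$trajectory$states[[1]]$cls != "PLASMATOCYTE"]
  for (i in seq_len(nrow(log))) {
    if (log$kind[i] == "INDUCTION") cc_ids <- c(cc_ids, log$cell_id[i])
    if (log$kind[i] == "DIVISION")
      expect_false(log$cell_id[i] %in% cc_ids)
  }
  n0 <- alive_count(sim$trajectory$states[[1]])
  n1 <- alive_count(sim$final_state$cells)
  expect_equal(n1 - n0,
               sum(log$kind == "DIVISION") - sum(log$kind == "DEATH"))
  # compartments partition the population
  expect_true(all(sim$final_state$cells$compartment %in%
                    c("SESSILE", "CIRCULATION")))
})

test_that("maturation is monotone: GFP never falls, phagocytosis never rises", {
  sim <- simulate_cluster(sim_params(), 300, seed = 77)
  tr <- sim$trajectory
  ids <- unique(unlist(lapply(tr$states, function(s) s$id)))
  for (id in ids) {
    gfp <- vapply(tr$states, function(s) {
      i <- match(id, s$id); if (is.na(i)) NA_real_ else s$lz_gfp[i]
    }, numeric(1))
    ph <- vapply(tr$states, function(s) {
      i <- match(id, s$id); if (is.na(i)) NA_real_ else s$phago[i]
    }, numeric(1))
    gfp <- gfp[!is.na(gfp)]; ph <- ph[!is.na(ph)]
    expect_true(all(diff(gfp) >= -1e-9))
    expect_true(all(diff(ph) <= 1e-9))
  }
})

test_that("3-hr division proportions agree across step sizes", {
  frac_at_dt <- function(dt, seeds) {
    p <- sim_params(dt = dt, beta_contact = 0)
    mean(vapply(seeds, function(s) {
      sim <- simulate_cluster(p, 180, n_cc = 0, snapshot_interval = 180,
                              seed = s)
      sum(sim$log$kind == "DIVISION" & sim$log$cell_id <= 50) / 50
    }, numeric(1)))
  }
  f_fine <- frac_at_dt(1.5, 301:340)
  f_coarse <- frac_at_dt(7.5, 401:440)
  se_diff <- sqrt(2 * 0.07 * 0.93 / (40 * 50))
  expect_lt(abs(f_fine - f_coarse), 3 * se_diff)
  expect_lt(abs(f_fine - 0.07), 3 * se_diff)
})

test_that("Notch and pan-hemocyte Serrate knockdowns abolish induction", {
  p <- sim_params()
  for (kind in c("NOTCH_RNAI", "SERRATE_RNAI_ALL")) {
    sim <- simulate_cluster(p, 1440, perturbations = perturbation(kind, 1),
                            snapshot_interval = 1440, seed = 13)
    expect_equal(sum(sim$log$kind == "INDUCTION"), 0)
  }
  # Lz-restricted Serrate knockdown leaves lateral induction intact
  sim_lz <- simulate_cluster(p, 1440,
                             perturbations = perturbation("SERRATE_RNAI_LZ_ONLY", 1),
                             snapshot_interval = 1440, seed = 13)
  expect_gt(sum(sim_lz$log$kind == "INDUCTION"), 0)
})

test_that("disruption empties the sessile compartment and clusters re-form in 90 min", {
  p <- sim_params()
  set.seed(9)
  st <- init_cluster(40, 5, cluster_geometry(), p)
  d <- apply_disruption(st)
  expect_equal(sum(d$cells$compartment == "SESSILE"), 0)
  expect_equal(nrow(d$cells), nrow(st$cells))
  expect_equal(nrow(d$edges), 0)
  # expected reattachment: ~90% sessile again 90 min after a disruption
  sess_frac <- vapply(1:12, function(r) {
    sim <- simulate_cluster(p, 91.5,
                            perturbations = perturbation("DISRUPTION",
                                                         schedule = 1.5),
                            snapshot_interval = 91.5, seed = 800 + r)
    cells <- sim$final_state$cells
    mean(cells$compartment[cells$alive] == "SESSILE")
  }, numeric(1))
  expect_gt(mean(sess_frac), 0.86)
  expect_lt(mean(sess_frac), 0.95)
})

test_that("beta calibration brackets, converges, and responds to contact density", {
  p <- sim_params()
  expect_identical(as.numeric(calibrate_beta(p, 0)), 0)
  expect_error(calibrate_beta(p, 0.5, n_reps = 2, upper = 1e-5, seed = 3),
               "non-bracketing")
  b <- calibrate_beta(p, 0.035, n_reps = 8, tol = 0.15, seed = 51)
  expect_gt(as.numeric(b), 0)
  expect_lt(abs(attr(b, "achieved") - 0.035), 0.15 * 0.035 + 1e-9)
  # denser clusters induce more at fixed beta
  frac_for <- function(radius) {
    mean(vapply(1:16, function(r) {
      sim <- simulate_cluster(p, 180, geometry = cluster_geometry(cluster_radius = radius),
                              snapshot_interval = 180, seed = 900 + r)
      sum(sim$log$kind == "INDUCTION" & sim$log$cell_id <= 50) / 50
    }, numeric(1)))
  }
  expect_gt(frac_for(44), frac_for(62))
})
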