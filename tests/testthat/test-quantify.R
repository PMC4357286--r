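test_that("nucleus detection finds rendered blobs with sub-pixel accuracy", {
  cfg <- imaging_config(noise_gaussian_sd = 0)
  blank <- matrix(10, 128, 128)
  expect_equal(nrow(detect_nuclei(blank)), 0)
  fr <- render_frame(make_cells(32, 48), cfg)
  d <- detect_nuclei(fr[, , "RED"], fr[, , "GREEN"])
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 32), 1)
  expect_lt(abs(d$y - 48), 1)
  fr2 <- render_frame(make_cells(c(40, 60), c(40, 40)), cfg)
  expect_equal(nrow(detect_nuclei(fr2[, , "RED"])), 2)
  # green mean grey distinguishes marker states
  frg <- render_frame(make_cells(c(40, 80), c(40, 40),
                                 cls = c("PLASMATOCYTE", "MATURE_CC"),
                                 lz_gfp = c(0, 150)), cfg)
  dg <- detect_nuclei(frg[, , "RED"], frg[, , "GREEN"])
  dg <- dg[order(dg$x), ]
  expect_lt(dg$green_mean[1], 13)
  expect_gt(dg$green_mean[2], 100)
})

test_that("greedy linking keeps identities, starts tracks, and bridges gaps", {
  det1 <- data.frame(frame = rep(0:9, each = 1), x = 20, y = 20)
  ts1 <- link_tracks(det1)
  expect_equal(nrow(ts1$tracks), 1)
  expect_equal(ts1$tracks$n, 10)
  # two far-apart cells never swap
  det2 <- data.frame(frame = rep(0:19, 2),
                     x = c(rep(20, 20), rep(80, 20)),
                     y = 20)
  ts2 <- link_tracks(det2)
  expect_equal(nrow(ts2$tracks), 2)
  by_tr <- split(ts2$detections$x, ts2$detections$track_id)
  expect_true(all(vapply(by_tr, function(v) length(unique(v)) == 1,
                         logical(1))))
  # a missing middle frame is bridged within the gap allowance
  det3 <- data.frame(frame = c(0:4, 6:10), x = 50, y = 50)
  ts3 <- link_tracks(det3, link_params(max_gap = 2))
  expect_equal(nrow(ts3$tracks), 1)
  ts3b <- link_tracks(det3, link_params(max_gap = 0))
  expect_equal(nrow(ts3b$tracks), 2)
})

test_that("division calling needs a daughter track appearing beside a parent", {
  static <- link_tracks(data.frame(frame = 0:30, x = 20, y = 20))
  expect_equal(nrow(call_divisions(static)), 0)
  # scripted split at frame 60
  det <- rbind(data.frame(frame = 0:120, x = 20, y = 20),
               data.frame(frame = 60:120, x = 25.6, y = 20))
  ts <- link_tracks(det)
  ev <- call_divisions(ts)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$frame - 60), 1)
  expect_equal(ev$parent_track, 1)
  # a movie of only mature crystal cells renders no splits
  cells <- make_cells(c(40, 64, 88), c(64, 64, 64), cls = "MATURE_CC",
                      lz_gfp = 180, area = 90)
  states <- replicate(31, cells, simplify = FALSE)
  mv <- render_movie(make_trajectory(states),
                     imaging_config(duration = 45, noise_gaussian_sd = 0),
                     seed = 1)
  q <- quantify_movie(mv)
  expect_equal(nrow(q$divisions), 0)
  expect_equal(nrow(q$inductions), 0)   # green-high from frame 0
})

test_that("induction calling requires onset plus persistence", {
  base <- data.frame(frame = 0:100, x = 50, y = 50, green_bg = 10)
  flat <- base; flat$green_mean <- 10
  expect_equal(nrow(call_inductions(link_tracks(flat),
                                    induction_params(m = 5))), 0)
  ramp <- base
  ramp$green_mean <- ifelse(ramp$frame >= 60, 10 + 2 * (ramp$frame - 59), 10)
  ev <- call_inductions(link_tracks(ramp), induction_params(m = 5))
  expect_equal(nrow(ev), 1)
  expect_true(ev$frame >= 60 && ev$frame <= 65)
  spike <- base; spike$green_mean <- ifelse(spike$frame == 60, 100, 10)
  expect_equal(nrow(call_inductions(link_tracks(spike),
                                    induction_params(m = 5))), 0)
  # a track green-positive from the start is never called
  high <- base; high$green_mean <- 100
  expect_equal(nrow(call_inductions(link_tracks(high),
                                    induction_params(m = 5))), 0)
})

test_that("rate estimation rescales geometrically and pools by events", {
  expect_equal(estimate_rate(0, 100, 180)$proportion, 0)
  r <- estimate_rate(46, 650, 180)
  expect_equal(r$proportion, 46 / 650)
  expect_equal(round(r$proportion, 4), 0.0708)
  expect_equal(r$se, sqrt((46 / 650) * (1 - 46 / 650) / 650))
  expect_error(estimate_rate(3, 0, 180), "denominator")
  # pooling equals the denominator-weighted mean of per-field estimates
  ev <- c(2, 5, 1); n0 <- c(50, 48, 52)
  pooled <- pool_rates(ev, n0, 180)$proportion
  per_field <- ev / n0
  expect_equal(pooled, sum(n0 * per_field) / sum(n0))
  # 90-min observations scale geometrically, not linearly
  r90 <- estimate_rate(10, 100, 90)
  expect_equal(r90$proportion, 1 - (1 - 0.1)^2)
})

test_that("Lz+ versus contact-count curve behaves at the edges and under induction", {
  # isolated cells, no induction: flat zero
  counts0 <- data.frame(cls = rep("PLASMATOCYTE", 30), area = 50,
                        compartment = "SESSILE", k_plasma = 0)
  cv0 <- lz_vs_contacts(counts0, size_gate = 60)
  expect_true(all(cv0$bins$fraction == 0))
  # simulated induction gives a positive slope
  sc <- run_scenario("contacts", seed = 19, replicates = 12,
                     params = sim_params())
  expect_gt(sc$summary$slope, 0)
  expect_gt(sc$summary$slope_origin, 0)
  expect_error(lz_vs_contacts(counts0[0, ]), "size gate|empty")
})

test_that("flow gating removes debris and doublets before the PI and Lz calls", {
  p <- sim_params()
  set.seed(47)
  st <- init_cluster(30, 8, cluster_geometry(), p)
  ev <- synth_flow_events(st, n_events = 8000, dead_fraction = 0,
                          doublet_fraction = 0.05, debris_fraction = 0.08,
                          seed = 5)
  gt <- gate_flow_events(ev)
  expect_equal(gt$summary$viable_fraction, 1.0)
  # debris truth rows all fall outside the scatter gate
  g <- flow_gates()
  deb <- ev[ev$truth_debris, ]
  expect_true(all(deb$FSC < g$fsc_range[1] | deb$SSC < g$ssc_range[1]))
  expect_true(all(!gt$gated$truth_debris))
  # doublets are excluded by pulse width
  expect_lt(mean(gt$gated$truth_doublet), 0.005)
  expect_error(gate_flow_events(ev[, c("FSC", "SSC")]), "missing columns")
})

test_that("hemocytometer conversion follows the x 10^5 rule", {
  expect_equal(hemocytometer_concentration(0), 0)
  expect_equal(hemocytometer_concentration(25), 2.5e6)
  expect_equal(hemocytometer_concentration(13), 1.3e6)
  expect_error(hemocytometer_concentration(-1), ">= 0")
})
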