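test_that("normality-gated comparison picks the documented paths", {
  set.seed(1)
  x <- rnorm(100)
  # identical samples: parametric path, no difference
  same <- compare_groups(c(x, x), rep(c("a", "b"), each = 100))
  expect_equal(same$path, "parametric")
  expect_gt(same$p.value, 0.99)
  expect_equal(same$stars, "n.s.")
  # unit effect at n = 100: detected at the 0.001 level
  set.seed(2)
  strong <- compare_groups(c(rnorm(100, 0), rnorm(100, 1)),
                           rep(c("a", "b"), each = 100))
  expect_lt(strong$p.value, 0.001)
  expect_equal(strong$stars, "***")
  expect_equal(strong$test, "Student's t-test")
  # heavy tails flip to the rank-based path
  set.seed(3)
  heavy <- compare_groups(c(rcauchy(60), rcauchy(60)),
                          rep(c("a", "b"), each = 60))
  expect_equal(heavy$path, "nonparametric")
  expect_equal(heavy$test, "Wilcoxon rank-sum")
  expect_error(compare_groups(1:4, c("a", "a", "b", "b")), "n >= 3")
})

test_that("many-group comparisons report Dunnett or Dunn against the control", {
  set.seed(4)
  vals <- c(rnorm(30, 0), rnorm(30, 0.1), rnorm(30, 2))
  grp <- rep(c("ctrl", "g1", "g2"), each = 30)
  par <- compare_groups(vals, grp, control = "ctrl")
  expect_equal(par$test, "one-way ANOVA + Dunnett")
  expect_equal(nrow(par$pairwise), 2)
  pw <- par$pairwise
  expect_gt(pw$p_adjusted[grepl("g1", pw$comparison)], 0.05)
  expect_lt(pw$p_adjusted[grepl("g2", pw$comparison)], 0.001)
  # rank path with skewed data
  set.seed(5)
  vals2 <- c(rexp(30), rexp(30), rexp(30) + 3)
  np <- compare_groups(vals2, grp, control = "ctrl")
  expect_equal(np$test, "Kruskal-Wallis + Dunn")
  expect_lt(np$pairwise$p_adjusted[grepl("g2", np$pairwise$comparison)],
            0.01)
  # omnibus p is invariant to group-label permutation
  perm <- sample(seq_along(vals))
  par_p <- compare_groups(vals[perm], grp[perm], control = "ctrl")
  expect_equal(par$p.value, par_p$p.value, tolerance = 1e-12)
})

test_that("Dunn z statistics match a hand computation with ties", {
  vals <- c(1, 2, 2, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("c", "a", "b"), each = 3)
  got <- dunn_test(vals, grp, control = "c")
  # hand oracle
  r <- rank(vals); N <- length(vals)
  ties <- table(vals); corr <- sum(ties^3 - ties) / (12 * (N - 1))
  z_hand <- function(g) {
    (mean(r[grp == g]) - mean(r[grp == "c"])) /
      sqrt((N * (N + 1) / 12 - corr) * (2 / 3))
  }
  expect_equal(got$z[got$comparison == "a - c"], z_hand("a"),
               tolerance = 1e-12)
  expect_equal(got$z[got$comparison == "b - c"], z_hand("b"),
               tolerance = 1e-12)
})

test_that("the gated two-group procedure holds its type-I error", {
  set.seed(6)
  rej <- mean(vapply(1:2000, function(i) {
    v <- rnorm(30)
    compare_groups(v, rep(c("a", "b"), each = 15))$p.value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("SEM matches the direct loop computation", {
  set.seed(7)
  x <- rnorm(37)
  m <- sum(x) / length(x)
  s2 <- 0
  for (xi in x) s2 <- s2 + (xi - m)^2
  expect_equal(sem(x), sqrt(s2 / (length(x) - 1)) / sqrt(length(x)),
               tolerance = 1e-12)
})

test_that("size densities put the plasmatocyte mode below the crystal-cell mode", {
  p <- sim_params()
  set.seed(8)
  cells <- do.call(rbind, lapply(1:5, function(i)
    init_cluster(50, 6, cluster_geometry(), p)$cells))
  cls <- ifelse(cells$cls == "PLASMATOCYTE", "plasmatocyte", "crystal")
  sd_ <- size_density(cells$area, cls)
  expect_lt(sd_$modes["plasmatocyte"], sd_$modes["crystal"])
  expect_equal(sd_$ordering[1], "plasmatocyte")
  # densities integrate to one on the grid
  dx <- diff(sd_$grid[1:2])
  for (cl in colnames(sd_$density))
    expect_lt(abs(sum(sd_$density[, cl]) * dx - 1), 1e-3)
  # degenerate class flagged, mode at the common value
  sd2 <- size_density(c(rep(50, 6), rnorm(10, 80, 5)),
                      rep(c("flat", "var"), c(6, 10)))
  expect_true(sd2$degenerate["flat"])
  expect_equal(unname(sd2$modes["flat"]), 50)
  expect_error(size_density(1:8, rep(c("a", "b"), c(4, 4))), ">= 5")
})

test_that("area-GFP correlation is strong in a maturation cohort and guarded otherwise", {
  p <- sim_params()
  cells <- do.call(rbind, lapply(1:8, function(r) {
    sim <- simulate_cluster(p, 480, n_cc = 0, snapshot_interval = 480,
                            seed = 600 + r)
    sim$final_state$cells
  }))
  lz <- cells[cells$cls != "PLASMATOCYTE" & cells$alive, ]
  expect_gte(nrow(lz), 10)
  ct <- intensity_area_correlation(lz$area, lz$lz_gfp)
  expect_gt(ct$r, 0.8)
  expect_gt(ct$slope, 0)
  expect_error(intensity_area_correlation(lz$area, rep(5, nrow(lz))),
               "zero variance")
  # destroying the pairing destroys the correlation
  set.seed(9)
  shuf <- vapply(1:20, function(i)
    intensity_area_correlation(lz$area, sample(lz$lz_gfp))$r, numeric(1))
  expect_lt(mean(abs(shuf)), 0.25)
})

test_that("phagocytic capacity declines with size and GFP in maturing cells", {
  p <- sim_params()
  cells <- do.call(rbind, lapply(1:6, function(r) {
    sim <- simulate_cluster(p, 480, n_cc = 0, snapshot_interval = 480,
                            seed = 700 + r)
    sim$final_state$cells
  }))
  lz <- cells[cells$cls != "PLASMATOCYTE" & cells$alive, ]
  tr <- phagocytosis_trend(lz$phago, lz$area, lz$lz_gfp)
  expect_true(tr$non_increasing_area)
  expect_true(tr$non_increasing_green)
  # SEM oracle on an unambiguous 3-bin fixture
  ph <- c(0.9, 1.0, 0.8, 0.6, 0.5, 0.7, 0.2, 0.1, 0.3)
  tr3 <- phagocytosis_trend(ph, area = 1:9, green = 1:9, n_bins = 3)
  sem_loop <- function(v) {
    m <- sum(v) / length(v); s <- 0
    for (x in v) s <- s + (x - m)^2
    sqrt(s / (length(v) - 1)) / sqrt(length(v))
  }
  expect_equal(tr3$by_green$mean, c(0.9, 0.6, 0.2))
  expect_equal(tr3$by_green$sem,
               c(sem_loop(ph[1:3]), sem_loop(ph[4:6]), sem_loop(ph[7:9])))
  # uniform capacity gives a flat trend
  flat <- phagocytosis_trend(rep(1, nrow(lz)), lz$area, lz$lz_gfp)
  expect_true(flat$non_increasing_area)
  expect_true(all(flat$by_area$mean == 1))
  # reversed maturation law (diagnostic): verdict must fail
  rev_ <- phagocytosis_trend(lz$lz_gfp / 200, lz$area, lz$lz_gfp)
  expect_false(rev_$non_increasing_green)
})
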