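#' Significance stars
#'
#' Convention: \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05,
#' otherwise \code{n.s.}.
#'
#' @param p P-value(s).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "n.s.")))
}

#' Standard error of the mean
#'
#' @param x Numeric vector.
#' @return \code{sd(x)/sqrt(length(x))}.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))

shapiro_p <- function(x) {
  if (length(unique(x)) < 3L) return(0)   # degenerate: treat as non-normal
  if (length(x) > 5000L) x <- sample(x, 5000L)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

#' Dunn's multiple-comparison test against a control group
#'
#' Rank-based many-to-one comparisons following a Kruskal-Wallis test:
#' z statistics on mean ranks with the tie correction, two-sided p-values
#' adjusted by Bonferroni over the comparisons.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coercible to factor).
#' @param control Control group label (default: first factor level).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Data frame: \code{comparison}, \code{z}, \code{p},
#'   \code{p_adjusted}, \code{stars}.
#' @export
dunn_test <- function(values, groups, control = NULL,
                      p_adjust = "bonferroni") {
  groups <- factor(groups)
  if (is.null(control)) control <- levels(groups)[1]
  if (!control %in% levels(groups)) stop("unknown control group")
  N <- length(values)
  r <- rank(values)                       # mid-ranks for ties
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n <- table(groups)
  others <- setdiff(levels(groups), control)
  z <- vapply(others, function(g) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / n[[control]] + 1 / n[[g]]))
    (mean_rank[[g]] - mean_rank[[control]]) / se
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = p_adjust)
  data.frame(comparison = paste(others, "-", control), z = unname(z),
             p = unname(p), p_adjusted = unname(p_adj),
             stars = significance_stars(unname(p_adj)),
             stringsAsFactors = FALSE)
}

#' Normality-gated group comparison
#'
#' Each group is tested for normality (Shapiro-Wilk at \code{alpha}); if
#' every group passes, the parametric path is taken (Student's t-test for
#' two groups; one-way ANOVA with Dunnett's many-to-one comparisons for
#' more), otherwise the rank-based path (Wilcoxon rank-sum for two groups;
#' Kruskal-Wallis with Dunn's comparisons for more). The two-group
#' non-normal fallback is the rank-sum test, a documented convention.
#'
#' @param values Numeric observations.
#' @param groups Group labels; the control is the first factor level unless
#'   \code{control} is given.
#' @param alpha Level for both the normality gate and the stars.
#' @param control Control group label for many-to-one comparisons.
#' @return Object of class \code{group_comparison}: \code{path}
#'   (\code{"parametric"}/\code{"nonparametric"}), \code{test} (name),
#'   \code{statistic}, \code{p.value} (omnibus), \code{pairwise} (data
#'   frame with adjusted p-values and stars; \code{NULL} for two groups),
#'   \code{normality} (per-group Shapiro p), \code{stars}.
#' @export
compare_groups <- function(values, groups, alpha = 0.05, control = NULL) {
  groups <- factor(groups)
  if (!is.null(control)) groups <- stats::relevel(groups, ref = control)
  ns <- table(groups)
  if (any(ns < 3L))
    stop("each group needs n >= 3 (got: ",
         paste(sprintf("%s=%d", names(ns), ns), collapse = ", "), ")")
  if (any(!is.finite(values))) stop("observations must be finite")
  sw <- vapply(split(values, groups), shapiro_p, numeric(1))
  normal <- all(sw >= alpha)
  k <- nlevels(groups)
  pairwise <- NULL
  if (normal) {
    if (k == 2L) {
      tt <- stats::t.test(values ~ groups, var.equal = TRUE)
      test <- "Student's t-test"; statistic <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      fit <- stats::aov(values ~ groups)
      an <- summary(fit)[[1]]
      test <- "one-way ANOVA + Dunnett"; statistic <- an$`F value`[1]
      p <- an$`Pr(>F)`[1]
      glht <- multcomp::glht(fit, linfct = multcomp::mcp(groups = "Dunnett"))
      sm <- summary(glht)
      pairwise <- data.frame(
        comparison = names(sm$test$coefficients),
        estimate = unname(sm$test$coefficients),
        p_adjusted = unname(as.numeric(sm$test$pvalues)),
        stringsAsFactors = FALSE)
      pairwise$stars <- significance_stars(pairwise$p_adjusted)
    }
  } else {
    if (k == 2L) {
      wt <- stats::wilcox.test(values ~ groups, exact = FALSE)
      test <- "Wilcoxon rank-sum"; statistic <- unname(wt$statistic)
      p <- wt$p.value
    } else {
      kw <- stats::kruskal.test(values, groups)
      test <- "Kruskal-Wallis + Dunn"; statistic <- unname(kw$statistic)
      p <- kw$p.value
      pairwise <- dunn_test(values, groups, control = levels(groups)[1])
    }
  }
  structure(list(path = if (normal) "parametric" else "nonparametric",
                 test = test, statistic = statistic, p.value = p,
                 pairwise = pairwise, normality = sw,
                 stars = significance_stars(p), alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s path): statistic %.3f, p = %.3g %s\n",
              x$test, x$path, x$statistic, x$p.value, x$stars))
  if (!is.null(x$pairwise)) {
    cat("pairwise vs control:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Kernel-density summaries of cell sizes by class
#'
#' Per-class kernel densities on a shared grid, with the mode location of
#' each class and their ordering (plasmatocytes are expected to peak at
#' smaller areas than crystal cells).
#'
#' @param areas Numeric areas (um^2).
#' @param classes Class labels, one per area.
#' @param n_grid Grid size.
#' @return List of class \code{size_density}: \code{grid}, \code{density}
#'   (matrix, one column per class), \code{modes} (named vector),
#'   \code{degenerate} (named logical: classes with zero variance),
#'   \code{ordering} (class names sorted by mode).
#' @export
size_density <- function(areas, classes, n_grid = 512) {
  classes <- factor(classes)
  ns <- table(classes)
  if (any(ns < 5L)) stop("each class needs >= 5 observations")
  rng <- range(areas)
  pad <- diff(rng) * 0.2 + 1
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = n_grid)
  dens <- matrix(0, n_grid, nlevels(classes),
                 dimnames = list(NULL, levels(classes)))
  modes <- stats::setNames(numeric(nlevels(classes)), levels(classes))
  degenerate <- stats::setNames(logical(nlevels(classes)), levels(classes))
  for (cl in levels(classes)) {
    x <- areas[classes == cl]
    if (stats::sd(x) == 0) {
      degenerate[cl] <- TRUE
      modes[cl] <- x[1]
      d <- stats::density(x, bw = max(abs(x[1]), 1) * 0.01,
                          from = grid[1], to = grid[n_grid], n = n_grid)
    } else {
      d <- stats::density(x, from = grid[1], to = grid[n_grid], n = n_grid)
      modes[cl] <- d$x[which.max(d$y)]
    }
    dens[, cl] <- d$y
  }
  structure(list(grid = grid, density = dens, modes = modes,
                 degenerate = degenerate,
                 ordering = names(sort(modes))),
            class = "size_density")
}

#' Correlation between cell area and GFP intensity
#'
#' Pearson correlation with a least-squares line, for Lz+ cells; GFP
#' intensity rises with cell size during crystal-cell maturation.
#'
#' @param area Cell areas.
#' @param green Green mean grey values, same length.
#' @return List: \code{r}, \code{p}, \code{slope}, \code{intercept},
#'   \code{n}.
#' @export
intensity_area_correlation <- function(area, green) {
  if (length(area) < 10L) stop("need >= 10 cells")
  if (stats::sd(area) == 0 || stats::sd(green) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(area, green)
  fit <- stats::lm(green ~ area)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(area))
}

#' Phagocytic capacity binned by size and by GFP
#'
#' Bin means with SEM and a monotonicity verdict: phagocytic capacity in
#' Lz+ cells declines with both cell size and GFP intensity as cells
#' mature.
#'
#' @param phago Phagocytic capacities in \[0, 1\].
#' @param area,green Binning covariates, same length.
#' @param n_bins Number of quantile bins per covariate.
#' @param tol Slack allowed on increases before the non-increasing verdict
#'   fails (absorbs bin-level sampling noise).
#' @param empty How to treat empty bins: \code{"drop"} or \code{"merge"}
#'   (merge into the previous bin).
#' @return List of class \code{phago_trend}: \code{by_area},
#'   \code{by_green} (data frames: bin, mid, n, mean, sem),
#'   \code{non_increasing_area}, \code{non_increasing_green}.
#' @export
phagocytosis_trend <- function(phago, area, green, n_bins = 5, tol = 0.02,
                               empty = c("drop", "merge")) {
  empty <- match.arg(empty)
  bin_means <- function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3L) br <- range(x) + c(-1e-9, 1e-9)
    cut_idx <- cut(x, br, include.lowest = TRUE)
    if (empty == "merge") {
      lv <- levels(cut_idx)[table(cut_idx) > 0]
      cut_idx <- factor(as.character(cut_idx), levels = lv)
    } else {
      cut_idx <- droplevels(cut_idx)
    }
    agg <- data.frame(
      bin = levels(cut_idx),
      mid = as.numeric(tapply(x, cut_idx, stats::median)),
      n = as.integer(table(cut_idx)),
      mean = as.numeric(tapply(phago, cut_idx, mean)),
      sem = as.numeric(tapply(phago, cut_idx, sem)),
      stringsAsFactors = FALSE)
    agg[order(agg$mid), ]
  }
  by_area <- bin_means(area)
  by_green <- bin_means(green)
  if (sum(by_area$n > 0) < 3L || sum(by_green$n > 0) < 3L)
    stop("need >= 3 non-empty bins")
  structure(list(by_area = by_area, by_green = by_green,
                 non_increasing_area = all(diff(by_area$mean) <= tol),
                 non_increasing_green = all(diff(by_green$mean) <= tol)),
            class = "phago_trend")
}
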