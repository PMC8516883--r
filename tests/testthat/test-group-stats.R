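test_that("Mann-Whitney U reproduces exact small-sample results", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_match(r$method, "exact")

  r2 <- mann_whitney_u(c(1, 2), c(3, 4), convention = "second")
  expect_equal(r2$statistic, 4)

  # identical samples: p ~= 1 under the tie-corrected approximation
  x <- c(1.2, 3.4, 5.6, 7.8)
  expect_gt(mann_whitney_u(x, x)$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact p equals the exhaustive permutation p for small samples", {
  set.seed(10)
  for (i in 1:30) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_perm_mw(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the vectorized test engine agrees with the scalar operation", {
  set.seed(11)
  X <- matrix(rnorm(18 * 7), 18)
  Y <- matrix(rnorm(35 * 7), 35)
  many <- eegspect:::mw_many(X, Y)
  for (j in 1:7) {
    one <- mann_whitney_u(X[, j], Y[, j])
    expect_equal(many$statistic[j], one$statistic)
    expect_equal(many$p_value[j], one$p_value, tolerance = 1e-12)
  }
  # with ties
  Xt <- matrix(sample(1:5, 18 * 3, replace = TRUE), 18)
  Yt <- matrix(sample(1:5, 35 * 3, replace = TRUE), 35)
  many_t <- eegspect:::mw_many(Xt, Yt)
  for (j in 1:3) {
    wt <- suppressWarnings(wilcox.test(Xt[, j], Yt[, j], correct = TRUE))
    expect_equal(many_t$p_value[j], wt$p.value, tolerance = 1e-12)
  }
})

test_that("Benjamini-Hochberg implements the step-up rule", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(bh$flags))
  expect_equal(bh$adjusted, rep(0.04, 4))

  expect_false(any(benjamini_hochberg(rep(0.9, 10))$flags))
  expect_true(benjamini_hochberg(0.04, q = 0.05)$flags)
  expect_false(benjamini_hochberg(0.06, q = 0.05)$flags)

  set.seed(12)
  for (i in 1:20) {
    p <- runif(25)^2
    bh <- benjamini_hochberg(p, q = 0.05)
    expect_true(all(bh$adjusted >= p - 1e-15))
    expect_false(any(bh$flags & p > 0.05))  # never rejects raw p > q
    expect_equal(bh$flags, bh$adjusted <= 0.05)
    expect_equal(bh$adjusted, p.adjust(p, "BH"))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the demographic chi-square tables reproduce the printed statistics", {
  sex <- pearson_chi2(matrix(c(8, 5, 4, 7), 2))
  expect_equal(round(sex$statistic, 2), 1.51)
  expect_equal(round(sex$p_value, 3), 0.219)
  expect_equal(sex$df, 1)

  sev <- pearson_chi2(matrix(c(6, 17, 8, 8, 4, 10), 2))
  expect_equal(round(sev$statistic, 2), 2.65)
  expect_equal(round(sev$p_value, 3), 0.265)
  expect_equal(sev$df, 2)

  prop <- pearson_chi2(matrix(c(10, 20, 5, 10), 2))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("distribution checks are calibrated on known distributions", {
  normal_p <- vapply(1:30, function(s) {
    set.seed(s)
    d <- data.frame(v = rnorm(400), g = "a")
    distribution_checks(d, "v", "g")$p_value[1]
  }, numeric(1))
  expect_gte(mean(normal_p > 0.05), 0.9)

  heavy_p <- vapply(1:30, function(s) {
    set.seed(100 + s)
    d <- data.frame(v = rt(200, df = 1), g = "a")
    distribution_checks(d, "v", "g")$p_value[1]
  }, numeric(1))
  expect_gte(mean(heavy_p < 0.05), 0.9)

  lev_p <- vapply(1:40, function(s) {
    set.seed(200 + s)
    d <- data.frame(v = rnorm(60), g = rep(c("a", "b"), each = 30))
    r <- distribution_checks(d, "v", "g")
    r$p_value[r$test == "levene"]
  }, numeric(1))
  expect_gt(mean(lev_p), 0.35)
  expect_lt(mean(lev_p), 0.65)
  expect_error(distribution_checks(data.frame(v = 1:2, g = "a"), "v", "g"),
               "3 values")
})

make_rp_tables <- function(n1 = 6, n2 = 6, n_rois = 8, shift_beta = 0) {
  ids <- sprintf("S%02d", seq_len(n1 + n2))
  md <- tibble::tibble(subject_id = ids,
                       group = rep(c("risk", "protective"), c(n1, n2)))
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  rp <- expand.grid(subject_id = ids, roi = paste0("r", seq_len(n_rois)),
                    band = bands, stringsAsFactors = FALSE)
  rp$rp <- runif(nrow(rp))
  sel <- rp$band == "beta" & rp$subject_id %in% ids[seq_len(n1)]
  rp$rp[sel] <- rp$rp[sel] + shift_beta
  se <- expand.grid(subject_id = ids, band = bands, stringsAsFactors = FALSE)
  se$se <- runif(nrow(se))
  list(rp = tibble::as_tibble(rp), se = tibble::as_tibble(se), md = md)
}

test_that("compare_groups assembles consistent tidy output", {
  set.seed(20)
  d <- make_rp_tables(shift_beta = 2)
  cmp <- compare_groups(d$rp, d$se, d$md)
  expect_s3_class(cmp, "eeg_group_comparison")
  expect_equal(sort(unique(cmp$scope)), c("rp_global", "rp_roi", "se"))
  roi <- cmp[cmp$scope == "rp_roi", ]
  expect_equal(nrow(roi), 8 * 5)
  expect_true(all(roi$p_adjusted >= roi$p_value - 1e-15))
  expect_equal(roi$significant, roi$p_adjusted <= 0.05)
  # the planted beta effect is found globally and in every ROI
  expect_true(cmp$significant[cmp$scope == "rp_global" & cmp$band == "beta"])
  expect_true(all(roi$significant[roi$band == "beta"]))

  expect_error(compare_groups(d$rp[-1, ], d$se, d$md), "complete")
  bad_md <- d$md
  bad_md$group <- "one"
  expect_error(compare_groups(d$rp, d$se, bad_md), "two values")
})

test_that("identical groups yield no discoveries", {
  set.seed(21)
  d <- make_rp_tables(n1 = 6, n2 = 6)
  # protective half duplicates the risk half exactly
  ids <- unique(d$rp$subject_id)
  for (i in 1:6) {
    d$rp$rp[d$rp$subject_id == ids[i + 6]] <-
      d$rp$rp[d$rp$subject_id == ids[i]]
  }
  cmp <- compare_groups(d$rp, NULL, d$md)
  expect_false(any(cmp$significant))
})

test_that("shuffled group labels reject at the nominal rate", {
  set.seed(22)
  hits <- 0
  trials <- 400
  for (i in seq_len(trials)) {
    glob <- rnorm(12)
    p <- eegspect:::mw_many(matrix(glob[1:6]), matrix(glob[7:12]))$p_value
    hits <- hits + (p <= 0.05)
  }
  expect_gt(hits / trials, 0.02)
  expect_lt(hits / trials, 0.09)
})
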