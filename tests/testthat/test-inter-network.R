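test_that("detrending removes exactly linear signals and is idempotent", {
  t <- 1:100
  expect_lt(max(abs(detrend_timecourse(2 * t + 5))), 1e-9)
  x <- rnorm(100)
  d1 <- detrend_timecourse(x)
  expect_lt(max(abs(detrend_timecourse(d1) - d1)), 1e-9)
  # sine on a ramp: the sine survives with < 1% amplitude error
  s <- sin(2 * pi * (1:200) / 25)
  d <- detrend_timecourse(s + 0.05 * (1:200))
  amp <- coef(lm(d ~ sin(2 * pi * (1:200) / 25) - 1))[1]
  expect_lt(abs(amp - 1), 0.01)
  expect_warning(out <- detrend_timecourse(rep(3, 10)), "constant")
  expect_equal(out, numeric(10))
})

test_that("circular lagged correlation matches its definition and symmetry", {
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  expect_identical(circular_lagged_r(x, y, 0L), cor(x, y))
  y3 <- x[((seq_len(50) - 1 + 3) %% 50) + 1]   # y3[t] = x[t+3]
  # aligning x with y3 shifted back recovers r = 1
  expect_equal(circular_lagged_r(y3, x, 3L), 1, tolerance = 1e-12)
  for (k in -12:12)
    expect_equal(circular_lagged_r(x, y, k), circular_lagged_r(y, x, -k),
                 tolerance = 1e-12)
  expect_error(circular_lagged_r(rep(1, 10), rnorm(10)), "constant")
})

test_that("maximal lagged correlation agrees with a brute-force scan", {
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(216); y <- rnorm(216)
    got <- max_lagged_correlation(x, y)
    want <- brute_max_lag(x, y)
    expect_identical(got$optimal_lag, want$optimal_lag)
    expect_lt(abs(got$r - want$r), 1e-12)
  }
})

test_that("maximal lagged correlation finds constructed optima and applies tie rules", {
  set.seed(3)
  x <- rnorm(216)
  y <- circular_shift(x, 5)          # y[t] = x[t+5]; x[t] pairs with y[t-5]
  res <- max_lagged_correlation(x, y)
  expect_equal(abs(res$r), 1, tolerance = 1e-12)
  expect_equal(res$optimal_lag, -5L)
  # periodic series: |r| = 1 at lags 0, +-8; smaller |lag| wins
  p <- sin(2 * pi * (0:215) / 8)
  res0 <- max_lagged_correlation(p, p)
  expect_equal(res0$optimal_lag, 0L)
  # |r| = 1 at both +2 (r = +1) and -2 (half-period, r = -1):
  # equal |lag|, so the negative lag wins
  q <- circular_shift(p, -2)
  res2 <- max_lagged_correlation(p, q)
  expect_equal(res2$optimal_lag, -2L)
  expect_error(max_lagged_correlation(rnorm(20), rnorm(20), max_lag = 12),
               "max_lag")
})

test_that("the scanned lag window is constrained and the maximum dominates lag zero", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(100); y <- rnorm(100)
    res <- max_lagged_correlation(x, y, max_lag = 12)
    expect_gte(abs(res$r), abs(circular_lagged_r(x, y, 0L)))
    expect_lte(abs(res$optimal_lag), 12L)
  }
})

test_that("the lag-correlation multiset is invariant to a common circular shift", {
  set.seed(11)
  x <- rnorm(60); y <- rnorm(60)
  r1 <- vapply(-12:12, function(l) circular_lagged_r(x, y, l), numeric(1))
  xs <- circular_shift(x, 17); ys <- circular_shift(y, 17)
  r2 <- vapply(-12:12, function(l) circular_lagged_r(xs, ys, l), numeric(1))
  expect_equal(sort(r1), sort(r2), tolerance = 1e-12)
})

test_that("Fisher z matches its closed form", {
  expect_identical(fisher_z(0), 0)
  # value for the control-group DMN/ExN coupling strength reported in the
  # source cohort: atanh(-0.451)
  expect_equal(fisher_z(-0.451), -0.4859549, tolerance = 1e-6)
  expect_equal(fisher_z(-0.451), 0.5 * log((1 - 0.451) / (1 + 0.451)),
               tolerance = 1e-14)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-14)
  expect_error(fisher_z(1), "< 1")
})

test_that("Fisher z of a fixed-lag null correlation has SD near 1/sqrt(T-3)", {
  set.seed(5)
  T <- 216
  zs <- replicate(400, fisher_z(circular_lagged_r(rnorm(T), rnorm(T), 0L)))
  expect_lt(abs(sd(zs) - 1 / sqrt(T - 3)), 0.012)
})

test_that("rotation-calibrated p is valid and the naive p anti-conservative under the max", {
  set.seed(8)
  ps <- replicate(60, {
    x <- rnorm(120); y <- rnorm(120)
    max_lagged_correlation(x, y, n_rotations = 99, seed = 1)$p_rotation
  })
  # roughly uniform: mean near 0.5, not concentrated near 0
  expect_gt(mean(ps), 0.3)
  expect_gt(min(ps), 0)
})

test_that("group ANCOVA on z reduces to t^2 with two groups and no nuisance", {
  set.seed(2)
  phen <- fake_phen(n_hc = 12, n_het = 9, n_hom = 2)
  keep <- phen$group != "HOM"
  z <- rnorm(sum(keep))
  av <- group_anova_z(z, phen[keep, ], nuisance = character(0))
  tt <- t.test(z ~ phen$group[keep], var.equal = TRUE)
  expect_equal(av$F, unname(tt$statistic^2), tolerance = 1e-8)
  expect_equal(av$df1, 1L)
})

test_that("group ANCOVA F matches the textbook nested-model comparison", {
  set.seed(4)
  phen <- fake_phen()
  z <- rnorm(nrow(phen)) + 0.3 * (phen$group == "HOM")
  av <- group_anova_z(z, phen, n_pairs = 10)
  full <- lm(z ~ education + gm_volume + factor(group), data = phen)
  red <- lm(z ~ education + gm_volume, data = phen)
  ref <- anova(red, full)
  expect_equal(av$F, ref$F[2], tolerance = 1e-10)
  expect_equal(av$p, ref$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(av$p_bonferroni, min(1, av$p * 10))
})

test_that("pairwise contrasts match the full-model coefficient tests", {
  set.seed(6)
  phen <- fake_phen()
  z <- rnorm(nrow(phen)) + 0.5 * (phen$group == "HOM")
  ct <- pairwise_contrasts(z, phen)
  fit <- lm(z ~ I(education - mean(education)) +
              I(gm_volume - mean(gm_volume)) + factor(group), data = phen)
  sm <- summary(fit)$coefficients
  expect_equal(ct$t[ct$contrast == "HET-HC"],
               unname(sm["factor(group)HET", "t value"]), tolerance = 1e-8)
  expect_equal(ct$t[ct$contrast == "HOM-HC"],
               unname(sm["factor(group)HOM", "t value"]), tolerance = 1e-8)
  expect_setequal(ct$contrast, c("HET-HC", "HOM-HC", "HOM-HET"))
})

test_that("partial correlation equals the closed-form partial r and plain r when nuisance is orthogonal", {
  set.seed(7)
  n <- 60
  z <- rnorm(n); score <- 0.5 * z + rnorm(n); nui <- rnorm(n)
  got <- behavior_partial_correlation(z, score, nui)
  r_xy <- cor(z, score); r_xz <- cor(z, nui); r_yz <- cor(score, nui)
  want <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(got$r, want, tolerance = 1e-10)
  expect_equal(got$df, n - 3L)
  # orthogonalized nuisance leaves r untouched
  nui_orth <- qr.resid(qr(cbind(1, z, score)), rnorm(n))
  got2 <- behavior_partial_correlation(z, score, nui_orth)
  expect_equal(got2$r, cor(z, score), tolerance = 1e-8)
})

test_that("behavioural recovery: a score built from z is detected with the right sign", {
  set.seed(10)
  hits <- replicate(40, {
    z <- rnorm(20); nui <- rnorm(20)
    score <- 0.8 * z + rnorm(20, sd = 0.6)
    behavior_partial_correlation(z, score, nui)$r > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("LEDD sensitivity check handles affine, constant and small-n inputs", {
  fc <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  ledd <- 3 * fc[, 2] + 7
  out <- ledd_fc_check(fc, ledd)
  expect_equal(abs(out$r[out$network == "b"]), 1, tolerance = 1e-12)
  expect_error(ledd_fc_check(fc, rep(5, 10)), "constant")
  expect_warning(out2 <- ledd_fc_check(fc[1:3, ], ledd[1:3]), "fewer than 4")
  expect_null(out2)
})

test_that("the per-subject lagged correlation table covers all pairs with consistent z", {
  set.seed(12)
  tcs <- lapply(1:4, function(i)
    matrix(rnorm(60 * 5), 60, 5,
           dimnames = list(NULL, c("DMN", "SN", "ExN", "rFP", "lFP"))))
  names(tcs) <- paste0("s", 1:4)
  tab <- lagged_correlation_table(tcs, max_lag = 6)
  expect_equal(nrow(tab), 4 * 10)
  expect_equal(length(unique(tab$pair)), 10L)
  expect_equal(tab$z, atanh(tab$r), tolerance = 1e-12)
  expect_true(all(abs(tab$optimal_lag) <= 6))
})
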