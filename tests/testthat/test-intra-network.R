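test_that("the voxelwise OLS t equals the classical pooled two-sample t", {
  set.seed(1)
  n1 <- 12; n2 <- 9
  maps <- matrix(rnorm((n1 + n2) * 40), n1 + n2, 40)
  phen <- data.frame(group = rep(c("HC", "HOM"), c(n1, n2)))
  design <- build_design(phen, interest = "group", nuisance = character(0))
  fit <- fit_voxelwise_glm(maps, design)
  tmap <- contrast_tmap(fit, c(0, 1))
  for (v in c(1, 17, 40)) {
    tt <- t.test(maps[phen$group == "HOM", v], maps[phen$group == "HC", v],
                 var.equal = TRUE)
    expect_equal(tmap[v], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("the voxelwise F equals the textbook ANCOVA on random voxels", {
  set.seed(2)
  phen <- fake_phen()
  maps <- matrix(rnorm(nrow(phen) * 30), nrow(phen), 30)
  design <- build_design(phen)
  fit <- fit_voxelwise_glm(maps, design)
  fmap <- contrast_fmap(fit, netlag:::interest_contrast(design))
  for (v in sample(30, 20)) {
    y <- maps[, v]
    full <- lm(y ~ gm_volume + education + factor(group), data = phen)
    red <- lm(y ~ gm_volume + education, data = phen)
    expect_equal(fmap[v], anova(red, full)$F[2], tolerance = 1e-8)
  }
})

test_that("a covariate orthogonal to the contrast leaves the estimate unchanged", {
  set.seed(3)
  phen <- fake_phen()
  n <- nrow(phen)
  maps <- matrix(rnorm(n * 10), n, 10)
  d0 <- build_design(phen, interest = "group", nuisance = character(0))
  cov_orth <- qr.resid(qr(cbind(d0$X, maps)), rnorm(n))
  phen$orth <- cov_orth
  d1 <- build_design(phen, interest = "group", nuisance = "orth")
  f0 <- fit_voxelwise_glm(maps, d0)
  f1 <- fit_voxelwise_glm(maps, d1)
  c0 <- numeric(ncol(d0$X)); c0[d0$interest_cols[1]] <- 1
  c1 <- numeric(ncol(d1$X)); c1[d1$interest_cols[1]] <- 1
  expect_equal(drop(crossprod(c0, f0$beta)), drop(crossprod(c1, f1$beta)),
               tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  phen <- fake_phen()
  phen$edu2 <- phen$education
  expect_error(build_design(phen, nuisance = c("education", "edu2")),
               "collinear")
})

test_that("cluster labelling partitions the supra-threshold set with 26-connectivity", {
  set.seed(4)
  dims <- c(10, 10, 8)
  supra <- array(runif(prod(dims)) < 0.15, dims)
  cl <- netlag:::label_clusters(supra, dims)
  expect_equal(sum(cl$sizes), sum(supra))
  expect_equal(length(cl$labels), sum(supra))
  expect_true(all(cl$labels >= 1))
  # two diagonal neighbours belong to one cluster under 26-connectivity
  supra2 <- array(FALSE, dims); supra2[3, 3, 3] <- TRUE; supra2[4, 4, 4] <- TRUE
  cl2 <- netlag:::label_clusters(supra2, dims)
  expect_equal(length(cl2$sizes), 1L)
  expect_equal(cl2$sizes, 2L)
})

test_that("cluster inference returns an empty table on flat data", {
  set.seed(5)
  phen <- fake_phen()
  n <- nrow(phen)
  maps <- matrix(rep(rnorm(50), each = n), n, 50)   # identical subjects
  design <- build_design(phen)
  cl <- cluster_inference(maps, design, dims = c(10, 5, 1), n_perm = 100,
                          seed = 1)
  expect_equal(nrow(cl), 0L)
})

test_that("an injected group deficit is localized to the right region", {
  set.seed(6)
  dims <- c(12, 12, 10); V <- prod(dims)
  n1 <- 22; n2 <- 8
  phen <- data.frame(group = rep(c("HC", "HOM"), c(n1, n2)))
  blob <- array(0, dims); blob[4:6, 4:6, 4:6] <- 1
  g <- voxel_grid(dims)
  mk <- function() as.vector(smooth_run(
    bold_run(array(rnorm(V * 2), c(dims, 2)), 1, g), 6)$data[, , , 1])
  maps <- t(vapply(seq_len(n1 + n2), function(i) mk(), numeric(V)))
  maps[phen$group == "HOM", ] <- sweep(maps[phen$group == "HOM", ], 2,
                                       1.5 * as.vector(blob), "-")
  design <- build_design(phen, interest = "group", nuisance = character(0))
  fit <- fit_voxelwise_glm(maps, design)
  tmap <- contrast_tmap(fit, c(0, -1))          # HC > HOM
  peak <- arrayInd(which.max(tmap), dims)
  expect_true(blob[peak[1], peak[2], peak[3]] == 1)
  cl <- cluster_inference(maps, design, contrast = c(0, -1), dims = dims,
                          n_perm = 199, seed = 2)
  expect_gt(nrow(cl), 0)
  expect_lt(cl$corrected_p[1], 0.05)
})

test_that("a strong compact effect is detected at corrected p < 0.05 in most seeds", {
  dims <- c(10, 10, 8); V <- prod(dims)
  n1 <- 22; n2 <- 8
  phen <- data.frame(group = rep(c("HC", "HOM"), c(n1, n2)))
  design <- build_design(phen, interest = "group", nuisance = character(0))
  blob <- array(0, dims); blob[3:7, 3:7, 3:4] <- 1   # 50 voxels
  hits <- 0
  for (s in 1:15) {
    set.seed(s)
    maps <- matrix(rnorm((n1 + n2) * V), n1 + n2, V)
    maps[phen$group == "HOM", ] <- sweep(maps[phen$group == "HOM", ], 2,
                                         1.5 * as.vector(blob), "-")
    cl <- cluster_inference(maps, design, contrast = c(0, -1), dims = dims,
                            n_perm = 199, seed = s)
    if (nrow(cl) > 0 && any(cl$corrected_p < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 14)
})

test_that("the Corsi covariate analysis recovers an amplitude-linked region", {
  set.seed(7)
  dims <- c(10, 10, 8); V <- prod(dims)
  phen <- fake_phen(n_hc = 4, n_het = 10, n_hom = 12)
  blob <- array(0, dims); blob[6:8, 6:8, 4:6] <- 1
  amp <- rnorm(nrow(phen), 1, 0.4)
  maps <- matrix(rnorm(nrow(phen) * V, sd = 0.5), nrow(phen), V) +
    outer(amp, as.vector(blob))
  phen$corsi <- ifelse(phen$group == "HOM", 4 + amp, phen$corsi)
  res <- corsi_correlation_analysis(maps, phen, dims, n_perm = 199, seed = 3)
  expect_true("HOM" %in% names(res))
  hom <- res$HOM
  expect_gt(nrow(hom), 0)
  pk <- unlist(hom[1, c("peak_x", "peak_y", "peak_z")])
  expect_equal(blob[pk[1], pk[2], pk[3]], 1)
})

test_that("missing Corsi scores are excluded with a message and tiny groups skipped", {
  set.seed(8)
  dims <- c(8, 8, 8); V <- prod(dims)
  phen <- fake_phen(n_hc = 2, n_het = 6, n_hom = 3)
  phen$corsi[phen$group == "HET"][1] <- NA
  phen$corsi[phen$group == "HOM"] <- c(4, NA, 5)
  maps <- matrix(rnorm(nrow(phen) * V), nrow(phen), V)
  expect_message(
    expect_warning(res <- corsi_correlation_analysis(maps, phen, dims,
                                                     n_perm = 100, seed = 1),
                   "slope skipped"),
    "excluding")
  expect_false("HOM" %in% names(res))
})
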