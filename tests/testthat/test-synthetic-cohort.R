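test_that("network maps are peak-normalized, distinct and deterministic", {
  g <- voxel_grid()
  m1 <- make_network_maps(g, seed = 5)
  m2 <- make_network_maps(g, seed = 5)
  expect_identical(m1, m2)
  expect_equal(length(m1), 5L)
  expect_named(m1, c("DMN", "SN", "ExN", "rFP", "lFP"))
  for (m in m1) expect_equal(max(m), 1)
  pairs <- combn(5, 2)
  overlaps <- apply(pairs, 2, function(ij)
    abs(cor(as.vector(m1[[ij[1]]]), as.vector(m1[[ij[2]]]))))
  expect_true(all(overlaps < 0.3))
})

test_that("a single blob peaks at 1 at its centre voxel", {
  m <- make_network_maps(voxel_grid(), n_networks = 1, blobs_per_network = 1,
                         seed = 2)
  expect_equal(max(m[[1]]), 1)
  ctr <- round(unlist(attr(m[[1]], "centres")))
  expect_equal(which.max(m[[1]]),
               ctr[1] + 16 * (ctr[2] - 1) + 16 * 20 * (ctr[3] - 1))
})

test_that("map generation fails loudly when the grid cannot host the blobs", {
  g <- voxel_grid(c(8, 8, 8))
  expect_error(make_network_maps(g, n_networks = 5, sigma_vox = 3,
                                 max_tries = 5),
               "too small")
})

test_that("uncoupled time courses are uncorrelated on average", {
  nets <- c("A", "B")
  C <- matrix(0, 2, 2, dimnames = list(nets, nets))
  L <- matrix(0L, 2, 2, dimnames = list(nets, nets))
  rs <- vapply(1:100, function(s) {
    tc <- simulate_network_timecourses(216, 2.08, C, L, seed = s)
    circular_lagged_r(tc[, 1], tc[, 2], 0L)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("an injected coupling is recovered at the right lag with the right value", {
  cl <- pair_coupling(0.9, 3L, k = 2L, nets = c("A", "B"))
  hits <- 0
  for (s in 1:100) {
    tc <- simulate_network_timecourses(216, 2.08, cl$coupling, cl$lags,
                                       seed = s)
    res <- max_lagged_correlation(tc[, 1], tc[, 2])
    if (res$optimal_lag == 3L) hits <- hits + 1
  }
  expect_gte(hits, 95)
  # realized coupling close to target in expectation
  rs <- vapply(1:50, function(s) {
    tc <- simulate_network_timecourses(216, 2.08, cl$coupling, cl$lags,
                                       seed = s)
    circular_lagged_r(tc[, 1], tc[, 2], 3L)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.1)
})

test_that("time courses are band-limited and unit variance", {
  cl <- pair_coupling(0.5, 2L)
  tc <- simulate_network_timecourses(216, 2.08, cl$coupling, cl$lags, seed = 4)
  expect_equal(apply(tc, 2, sd), rep(1, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (j in 1:5) {
    sp <- Mod(fft(tc[, j]))^2
    f <- (0:215) / (216 * 2.08)
    f <- pmin(f, 1 / 2.08 - f)
    out_band <- sum(sp[f < 0.01 | f > 0.08]) / sum(sp)
    expect_lt(out_band, 0.05)
  }
})

test_that("invalid couplings and lags are rejected", {
  nets <- c("A", "B")
  C <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(nets, nets))
  L <- matrix(0L, 2, 2, dimnames = list(nets, nets))
  expect_error(simulate_network_timecourses(100, 2, C, L), "< 1")
  C[1, 2] <- C[2, 1] <- 0.5
  L[1, 2] <- 60L; L[2, 1] <- -60L
  expect_error(simulate_network_timecourses(100, 2, C, L), "max|lag|",
               fixed = TRUE)
})

noise_free_truth <- function(maps) {
  ground_truth(maps, noise = list(rho = 0, sd = 0, drift_sd = 0, baseline = 0))
}

test_that("in the noise-free limit the voxel at a network peak carries its time course", {
  g <- voxel_grid()
  maps <- make_network_maps(g, n_networks = 1, blobs_per_network = 1, seed = 3)
  truth <- noise_free_truth(maps)
  phen <- list(participant_id = "sub-HC01", group = "HC")
  run <- simulate_subject(phen, truth, g, T = 50, tr_s = 2.08, seed = 9)
  pk <- arrayInd(which.max(maps[[1]]), g$dims)
  expect_equal(run$data[pk[1], pk[2], pk[3], ],
               as.vector(attr(run, "timecourses")[, 1]), tolerance = 1e-10)
})

test_that("a group amplitude multiplier scales the regression weight proportionally", {
  g <- voxel_grid()
  maps <- make_network_maps(g, n_networks = 1, blobs_per_network = 1, seed = 3)
  truth <- noise_free_truth(maps)
  truth$group_amplitude$HOM[1, 1] <- 0.5
  hc <- simulate_subject(list(participant_id = "s1", group = "HC"),
                         truth, g, T = 50, tr_s = 2.08, seed = 9)
  hom <- simulate_subject(list(participant_id = "s1", group = "HOM"),
                          truth, g, T = 50, tr_s = 2.08, seed = 9)
  tc <- attr(hc, "timecourses")[, 1]
  pk <- arrayInd(which.max(maps[[1]]), g$dims)
  b_hc <- coef(lm(hc$data[pk[1], pk[2], pk[3], ] ~ tc))[2]
  tc2 <- attr(hom, "timecourses")[, 1]
  b_hom <- coef(lm(hom$data[pk[1], pk[2], pk[3], ] ~ tc2))[2]
  expect_equal(unname(b_hom / b_hc), 0.5, tolerance = 1e-8)
})

test_that("different subject ids give different noise realizations under one master seed", {
  g <- voxel_grid()
  maps <- make_network_maps(g, n_networks = 2, seed = 3)
  truth <- ground_truth(maps)
  r1 <- simulate_subject(list(participant_id = "sub-A", group = "HC"),
                         truth, g, T = 20, tr_s = 2.08, seed = 7)
  r2 <- simulate_subject(list(participant_id = "sub-B", group = "HC"),
                         truth, g, T = 20, tr_s = 2.08, seed = 7)
  expect_false(identical(r1$data, r2$data))
  r1b <- simulate_subject(list(participant_id = "sub-A", group = "HC"),
                          truth, g, T = 20, tr_s = 2.08, seed = 7)
  expect_identical(r1$data, r1b$data)
})

test_that("the default cohort has the study group sizes and matched covariates", {
  cfg <- cohort_config(seed = 77)
  part <- netlag:::simulate_participants(cfg)
  expect_equal(nrow(part), 42L)
  expect_equal(as.vector(table(factor(part$group,
                                      c("HC", "HET", "HOM")))),
               c(22L, 12L, 8L))
  cal <- list(HC = c(47.0, 12.2, 14.7, 3.2), HET = c(41.9, 14.8, 12.3, 2.1),
              HOM = c(51.4, 8.1, 11.4, 2.3))
  for (gname in names(cal)) {
    sub <- part[part$group == gname, ]
    expect_lt(abs(mean(sub$age) - cal[[gname]][1]), cal[[gname]][2])
    expect_lt(abs(mean(sub$education) - cal[[gname]][3]), cal[[gname]][4])
  }
  # gene and treatment structure: mutated gene only in carriers, LEDD only HOM
  expect_true(all(part$gene[part$group == "HC"] == "none"))
  expect_true(all(part$gene[part$group != "HC"] %in% c("PINK1", "Park2")))
  expect_true(all(is.na(part$ledd[part$group != "HOM"])))
  expect_true(all(!is.na(part$ledd[part$group == "HOM"])))
  expect_true(all(is.na(part$corsi[part$group == "HC"])))
})

test_that("cohort generation is deterministic and respects size limits", {
  cfg <- cohort_config(group_sizes = c(HC = 3L, HET = 3L, HOM = 3L),
                       grid = voxel_grid(c(12, 14, 12)), T = 40L,
                       n_nuisance = 2L, max_overlap_r = 0.3, seed = 5)
  t0 <- proc.time()
  c1 <- simulate_cohort(cfg)
  expect_lt((proc.time() - t0)[3], 10)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$runs[[1]]$data, c2$runs[[1]]$data)
  expect_equal(length(c1$runs), 9L)
  expect_error(cohort_config(group_sizes = c(HC = 1L, HET = 3L, HOM = 3L)),
               "GLM")
})

test_that("injected lags are recovered from the generator's own time courses", {
  cl <- pair_coupling(0.6, 0L)
  for (k0 in c(-5L, 7L)) {
    cl$lags[1, 2] <- k0; cl$lags[2, 1] <- -k0
    rec <- vapply(1:20, function(s) {
      tc <- simulate_network_timecourses(216, 2.08, cl$coupling, cl$lags,
                                         seed = 100 + s)
      max_lagged_correlation(tc[, "DMN"], tc[, "SN"])$optimal_lag
    }, integer(1))
    expect_equal(as.integer(names(which.max(table(rec)))), k0)
  }
})
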