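# Shared fixtures, built in code. The small decomposition is computed once
# per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# 5x5 coupling/lag matrices for two networks coupled at (r, lag), rest zero.
pair_coupling <- function(r, lag, k = 5L,
                          nets = c("DMN", "SN", "ExN", "rFP", "lFP")[seq_len(k)]) {
  C <- matrix(0, k, k, dimnames = list(nets, nets))
  L <- matrix(0L, k, k, dimnames = list(nets, nets))
  C[1, 2] <- C[2, 1] <- r
  L[1, 2] <- lag; L[2, 1] <- -lag
  list(coupling = C, lags = L)
}

# A small, fast cohort + preprocessing + group ICA used by several tests.
small_ica_fixture <- function() {
  if (!is.null(.fixture_env$small_ica)) return(.fixture_env$small_ica)
  cfg <- cohort_config(group_sizes = c(HC = 4L, HET = 3L, HOM = 3L),
                       grid = voxel_grid(c(12L, 14L, 12L)), T = 100L,
                       n_nuisance = 4L, max_overlap_r = 0.3, seed = 2024L)
  cohort <- simulate_cohort(cfg)
  reds <- lapply(cohort$runs, function(r)
    subject_reduce(preprocess_run(r), 20L))
  dec <- zscore_maps(group_decompose(reds, 10L,
                                     seed = derive_seed(cfg$seed, "ica")))
  out <- list(cfg = cfg, cohort = cohort, reductions = reds, dec = dec)
  .fixture_env$small_ica <- out
  out
}

# Independent brute-force scan for the constrained maximal lagged
# correlation: explicit-sum Pearson correlation at every lag, argmax by the
# stated tie rule. Kept free of package internals.
brute_max_lag <- function(x, y, max_lag = 12L) {
  T <- length(x)
  pearson <- function(a, b) {
    am <- sum(a) / T; bm <- sum(b) / T
    da <- a - am; db <- b - bm
    sum(da * db) / sqrt(sum(da^2) * sum(db^2))
  }
  lags <- (-max_lag):max_lag
  rs <- numeric(length(lags))
  for (i in seq_along(lags)) {
    idx <- ((seq_len(T) - 1 + lags[i]) %% T) + 1
    rs[i] <- pearson(x, y[idx])
  }
  ord <- order(-abs(rs), abs(lags), lags)
  list(optimal_lag = lags[ord[1]], r = rs[ord[1]], all_r = rs)
}

# Phenotype table without imaging, for statistical unit tests.
fake_phen <- function(n_hc = 10, n_het = 6, n_hom = 5, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    n <- n_hc + n_het + n_hom
    data.frame(
      participant_id = sprintf("s%02d", seq_len(n)),
      group = rep(c("HC", "HET", "HOM"), c(n_hc, n_het, n_hom)),
      gene = c(rep("none", n_hc),
               sample(c("PINK1", "Park2"), n_het + n_hom, replace = TRUE)),
      age = rnorm(n, 47, 10),
      sex = sample(c("M", "F"), n, replace = TRUE),
      education = rnorm(n, 13, 3),
      gm_volume = rnorm(n, 600, 50),
      corsi = rnorm(n, 4.5, 0.6),
      moca = rnorm(n, 24, 2),
      ledd = ifelse(rep(c(FALSE, FALSE, TRUE), c(n_hc, n_het, n_hom)),
                    abs(rnorm(n, 600, 300)), NA),
      stringsAsFactors = FALSE)
  })
}
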