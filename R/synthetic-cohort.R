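#' Generate named synthetic network maps
#'
#' Each network map is a sum of truncated 3-D Gaussian blobs placed at random
#' centres inside the grid, peak-normalized to 1. Maps are redrawn until every
#' pair of networks has spatial correlation below `max_overlap_r`, so the
#' synthetic "networks" are spatially distinct the way canonical resting-state
#' networks are.
#'
#' @param grid A [voxel_grid()].
#' @param n_networks Number of networks (maps) to generate.
#' @param blobs_per_network Gaussian blobs per network.
#' @param seed Integer seed; the same seed reproduces the maps bit-exactly.
#' @param sigma_vox Blob standard deviation in voxels.
#' @param max_overlap_r Upper bound on pairwise spatial correlation.
#' @param names Network names (default DMN, SN, ExN, rFP, lFP, then N6, ...).
#' @param max_tries Redraws allowed before failing.
#' @return Named list of 3-D arrays; each carries a `blobs` attribute with the
#'   individual blob fields (used for per-region amplitude effects).
#' @export
make_network_maps <- function(grid, n_networks = 5L, blobs_per_network = 3L,
                              seed = 1L, sigma_vox = 1.4, max_overlap_r = 0.1,
                              names = NULL, max_tries = 200L) {
  stopifnot(n_networks >= 1L, blobs_per_network >= 1L)
  if (is.null(names)) {
    base <- c("DMN", "SN", "ExN", "rFP", "lFP")
    names <- if (n_networks <= 5L) base[seq_len(n_networks)]
             else c(base, paste0("N", 6:n_networks))
  }
  stopifnot(length(names) == n_networks)
  d <- grid$dims
  margin <- max(2L, ceiling(1.5 * sigma_vox))
  if (any(d - 2 * margin < 1))
    stop_named(paste("make_network_maps: grid %s too small to place blobs of",
                     "sigma %.2f voxels with a %d-voxel margin"),
               paste(d, collapse = "x"), sigma_vox, margin)
  ax <- lapply(1:3, function(k) seq_len(d[k]))
  blob_field <- function(centre) {
    dx2 <- outer(ax[[1]], centre[1], "-")^2
    dy2 <- outer(ax[[2]], centre[2], "-")^2
    dz2 <- outer(ax[[3]], centre[3], "-")^2
    r2 <- outer(outer(drop(dx2), drop(dy2), "+"), drop(dz2), "+")
    f <- exp(-r2 / (2 * sigma_vox^2))
    f[r2 > (4 * sigma_vox)^2] <- 0  # compact support at 4 sigma
    f
  }
  with_seed(seed, {
    maps <- vector("list", n_networks)
    for (i in seq_len(n_networks)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        centres <- lapply(seq_len(blobs_per_network), function(j)
          vapply(1:3, function(k)
            stats::runif(1, margin + 1, d[k] - margin), numeric(1)))
        blobs <- lapply(centres, blob_field)
        m <- Reduce(`+`, blobs)
        pk <- max(m)
        m <- m / pk
        blobs <- lapply(blobs, function(b) b / pk)
        rs <- if (i > 1)
          vapply(maps[seq_len(i - 1)],
                 function(p) abs(cor(as.vector(p), as.vector(m))), numeric(1))
        else 0
        if (all(rs < max_overlap_r)) { ok <- TRUE; break }
      }
      if (!ok)
        stop_named(paste("make_network_maps: could not place network %d with",
                         "pairwise spatial |r| < %.2f after %d tries;",
                         "grid too small for this many networks"),
                   i, max_overlap_r, max_tries)
      attr(m, "blobs") <- blobs
      attr(m, "centres") <- centres
      maps[[i]] <- m
    }
    names(maps) <- names
    maps
  })
}

#' Generate shared structured nuisance sources
#'
#' Real resting-state data contain, beyond the networks of interest, many
#' spatially structured non-neural sources (vascular, CSF pulsation,
#' residual physiological noise) that an order-20 decomposition absorbs into
#' its remaining components. The generator emulates them as smooth random
#' fields shared across subjects, each driven by an independent per-subject
#' band-limited time course.
#'
#' @param grid A [voxel_grid()].
#' @param n_nuisance Number of nuisance sources.
#' @param seed Integer seed.
#' @param smooth_fwhm_mm Smoothness of the random fields, mm.
#' @param orthogonal_to Optional list/matrix of network maps; nuisance fields
#'   are projected spatially orthogonal to them. On a desk-scale grid a
#'   random smooth field can correlate with a compact network map by chance
#'   alone (few spatial degrees of freedom), which a whole-brain field would
#'   not; orthogonalizing keeps the ground-truth sources spatially distinct,
#'   as the spatial ICA model assumes.
#' @return V x n matrix of unit-variance nuisance maps (V voxels).
#' @export
make_nuisance_maps <- function(grid, n_nuisance = 10L, seed = 1L,
                               smooth_fwhm_mm = 12, orthogonal_to = NULL) {
  if (n_nuisance < 1L) return(NULL)
  V <- n_voxels(grid)
  M <- if (is.null(orthogonal_to)) NULL
       else if (is.list(orthogonal_to))
         vapply(orthogonal_to, as.vector, numeric(V))
       else as.matrix(orthogonal_to)
  with_seed(seed, {
    vapply(seq_len(n_nuisance), function(i) {
      a <- array(rnorm(V * 2), c(grid$dims, 2))   # 2 frames: smoother wants 4-D
      s <- as.vector(smooth_run(bold_run(a, 1, grid),
                                smooth_fwhm_mm)$data[, , , 1])
      if (!is.null(M)) s <- qr.resid(qr(cbind(1, M)), s)
      s / sd(s)
    }, numeric(V))
  })
}

# Band-limited unit-variance noise via an FFT frequency mask.
band_noise <- function(T, tr_s, band_hz) {
  f <- (seq_len(T) - 1) / (T * tr_s)
  f <- pmin(f, 1 / tr_s - f)                 # two-sided frequency axis
  keep <- f >= band_hz[1] & f <= band_hz[2]
  x <- stats::fft(rnorm(T))
  x[!keep] <- 0
  x <- Re(stats::fft(x, inverse = TRUE)) / T
  x / sd(x)
}

check_coupling <- function(coupling, coupling_lags, T) {
  k <- nrow(coupling)
  stopifnot(ncol(coupling) == k, all(dim(coupling_lags) == c(k, k)))
  if (any(abs(coupling) >= 1))
    stop_named("coupling: |coupling| must be < 1")
  if (max(abs(coupling - t(coupling))) > 1e-12)
    stop_named("coupling: matrix must be symmetric in magnitude and sign")
  if (max(abs(coupling_lags + t(coupling_lags))) > 0)
    stop_named("coupling_lags: matrix must be antisymmetric")
  if (any(abs(coupling_lags) >= T))
    stop_named("coupling_lags: |lag| must be < T")
  if (2 * max(abs(coupling_lags)) >= T)
    stop_named("coupling_lags: need T > 2*max|lag| (T = %d, max lag = %d)",
               T, max(abs(coupling_lags)))
  rs <- rowSums(abs(coupling)) - abs(diag(coupling))
  if (any(rs > 1))
    stop_named(paste("coupling: sum of |coupling| in row %d is %.2f > 1;",
                     "the shared-noise construction needs row sums <= 1"),
               which.max(rs), max(rs))
  invisible(TRUE)
}

#' Simulate coupled band-limited network time courses
#'
#' Builds `k` unit-variance, band-limited time courses such that each pair
#' `(a, b)` attains its maximal circular lagged correlation at
#' `coupling_lags[a, b]` with value close to `coupling[a, b]`. Construction:
#' each pair shares an independent band-limited noise source, injected into
#' `a` unshifted and into `b` circularly shifted by the pair lag, with weight
#' `sqrt(|coupling|)` on each side; the remaining variance is idiosyncratic
#' band-limited noise. Because every source is filtered by a circular
#' frequency mask, the injected correlations are exactly circular.
#'
#' @param T Number of time points; must exceed twice the largest |lag|.
#' @param tr_s Sampling interval (repetition time), seconds.
#' @param coupling k x k symmetric matrix, `|coupling| < 1`, off-diagonal row
#'   sums of absolute values at most 1.
#' @param coupling_lags k x k antisymmetric integer matrix of lags in samples.
#' @param band_hz Pass band `(low, high)` in Hz.
#' @param seed Integer seed.
#' @details All noise pieces (shared and idiosyncratic) are orthogonalized in
#'   sample before mixing, so couplings injected at lag zero are realized
#'   exactly in each draw and couplings at other lags up to the (small)
#'   correlation between circularly shifted orthogonal pieces.
#' @return A `T x k` matrix of unit-variance time courses.
#' @export
simulate_network_timecourses <- function(T, tr_s, coupling, coupling_lags,
                                         band_hz = c(0.01, 0.08), seed = 1L) {
  k <- nrow(coupling)
  stopifnot(T > 2, tr_s > 0, band_hz[1] > 0, band_hz[1] < band_hz[2],
            band_hz[2] < 1 / (2 * tr_s))
  check_coupling(coupling, coupling_lags, T)
  with_seed(seed, {
    pairs <- which(upper.tri(coupling) & coupling != 0, arr.ind = TRUE)
    n_src <- nrow(pairs) + k
    raw <- vapply(seq_len(n_src), function(i) band_noise(T, tr_s, band_hz),
                  numeric(T))
    if (n_src > 1) {
      # sample-orthogonalize: band-limited pieces stay band-limited and
      # mean-zero under linear combination
      Q <- qr.Q(qr(raw))
      raw <- sweep(Q, 2, apply(Q, 2, sd), "/")
    }
    tc <- matrix(0, T, k)
    shared_var <- numeric(k)
    if (nrow(pairs)) for (j in seq_len(nrow(pairs))) {
      a <- pairs[j, 1]; b <- pairs[j, 2]
      c_ab <- coupling[a, b]
      s <- raw[, j]
      w <- sqrt(abs(c_ab))
      tc[, a] <- tc[, a] + w * s
      tc[, b] <- tc[, b] + sign(c_ab) * w *
        circular_shift(s, -coupling_lags[a, b])
      shared_var[a] <- shared_var[a] + abs(c_ab)
      shared_var[b] <- shared_var[b] + abs(c_ab)
    }
    for (a in seq_len(k)) {
      w0 <- sqrt(max(0, 1 - shared_var[a]))
      if (w0 > 0) tc[, a] <- tc[, a] + w0 * raw[, nrow(pairs) + a]
      tc[, a] <- tc[, a] / sd(tc[, a])
    }
    colnames(tc) <- rownames(coupling)
    tc
  })
}

#' Ground truth for the synthetic cohort
#'
#' Assembles the quantities the downstream analyses are meant to recover:
#' the network maps, per-group inter-network coupling matrices with lags,
#' per-group per-network per-blob amplitude multipliers, and the noise model.
#'
#' Defaults encode the qualitative study pattern: in controls the default-mode
#' network is anticorrelated with the four task-positive networks; in
#' heterozygous carriers the DMN couplings to SN/rFP/lFP flip positive; in
#' homozygous carriers SN-rFP coupling is increased by 0.2 and intra-network
#' amplitudes are reduced in DMN, ExN (bilateral frontal blobs) and rFP.
#'
#' @param maps Output of [make_network_maps()].
#' @param coupling,coupling_lags Optional per-group lists of k x k matrices.
#' @param group_amplitude Optional per-group list of networks x blobs
#'   multiplier matrices.
#' @param noise List with `rho` (AR(1) coefficient), `sd` (noise SD),
#'   `drift_sd` (SD of the per-voxel linear drift total excursion) and
#'   `baseline` (additive constant).
#' @param nuisance_maps Optional V x n matrix of shared structured nuisance
#'   sources (see [make_nuisance_maps()]); `NULL` for none.
#' @param nuisance_amp Amplitude of the nuisance sources.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(maps, coupling = NULL, coupling_lags = NULL,
                         group_amplitude = NULL,
                         noise = list(rho = 0.3, sd = 1, drift_sd = 0.5,
                                      baseline = 100),
                         nuisance_maps = NULL, nuisance_amp = 0.3,
                         seed = 1L) {
  nets <- names(maps)
  k <- length(nets)
  nb <- length(attr(maps[[1]], "blobs"))
  groups <- c("HC", "HET", "HOM")
  pairm <- function(entries) {
    m <- matrix(0, k, k, dimnames = list(nets, nets))
    for (e in entries) { m[e[[1]], e[[2]]] <- e[[3]]; m[e[[2]], e[[1]]] <- e[[3]] }
    m
  }
  lagm <- function(entries) {
    m <- matrix(0L, k, k, dimnames = list(nets, nets))
    for (e in entries) { m[e[[1]], e[[2]]] <- e[[3]]; m[e[[2]], e[[1]]] <- -e[[3]] }
    m
  }
  if (is.null(coupling) && k == 5L && all(nets == c("DMN", "SN", "ExN", "rFP", "lFP"))) {
    # Control pattern: DMN anticorrelated with the task-positive networks,
    # positive coupling among them, magnitudes in the 0.10-0.30 range typical
    # of maximal lagged inter-network correlations; row sums of |coupling|
    # stay below 1 as the shared-noise construction requires.
    base <- list(list("DMN", "SN", -0.15), list("DMN", "ExN", -0.30),
                 list("DMN", "rFP", -0.15), list("DMN", "lFP", -0.15),
                 list("SN", "ExN", 0.10), list("SN", "rFP", 0.40),
                 list("SN", "lFP", 0.10), list("ExN", "rFP", 0.10),
                 list("ExN", "lFP", 0.15), list("rFP", "lFP", 0.10))
    het <- base
    for (i in seq_along(het))   # carriers: DMN couplings flip positive
      if (het[[i]][[1]] == "DMN" && het[[i]][[2]] %in% c("SN", "rFP", "lFP"))
        het[[i]][[3]] <- abs(het[[i]][[3]])
    hom <- base
    hom[[6]][[3]] <- 0.60                       # SN-rFP increased by 0.2
    coupling <- list(HC = pairm(base), HET = pairm(het), HOM = pairm(hom))
  } else if (is.null(coupling)) {
    coupling <- stats::setNames(rep(list(matrix(0, k, k,
      dimnames = list(nets, nets))), 3), groups)
  }
  if (is.null(coupling_lags)) {
    lag_entries <- list(list("DMN", "SN", -1L), list("DMN", "ExN", 0L),
                        list("DMN", "rFP", -1L), list("DMN", "lFP", 1L),
                        list("SN", "ExN", -1L), list("SN", "rFP", 0L),
                        list("SN", "lFP", 0L), list("ExN", "rFP", 2L),
                        list("ExN", "lFP", 0L), list("rFP", "lFP", 1L))
    lags <- if (k == 5L) lagm(lag_entries)
            else matrix(0L, k, k, dimnames = list(nets, nets))
    coupling_lags <- stats::setNames(rep(list(lags), 3), groups)
  }
  if (is.null(group_amplitude)) {
    amp1 <- matrix(1, k, nb, dimnames = list(nets, NULL))
    het <- amp1; hom <- amp1
    if ("DMN" %in% nets) { het["DMN", 1] <- 0.75; hom["DMN", 1] <- 0.70 }
    if ("ExN" %in% nets && nb >= 2) { hom["ExN", 1] <- 0.70; hom["ExN", 2] <- 0.75 }
    if ("rFP" %in% nets && nb >= 2) { hom["rFP", 1] <- 0.75; hom["rFP", 2] <- 0.80 }
    group_amplitude <- list(HC = amp1, HET = het, HOM = hom)
  }
  structure(list(network_maps = maps, coupling = coupling,
                 coupling_lags = coupling_lags,
                 group_amplitude = group_amplitude, noise = noise,
                 nuisance_maps = nuisance_maps, nuisance_amp = nuisance_amp,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Effective network maps for one group: blob fields scaled by the group's
# per-blob amplitude multipliers.
effective_maps <- function(truth, group) {
  amp <- truth$group_amplitude[[group]]
  out <- lapply(seq_along(truth$network_maps), function(i) {
    blobs <- attr(truth$network_maps[[i]], "blobs")
    Reduce(`+`, Map(`*`, blobs, amp[i, seq_along(blobs)]))
  })
  names(out) <- names(truth$network_maps)
  out
}

#' Simulate one subject's BOLD run
#'
#' The run is the sum over networks of (group-scaled spatial map) x (network
#' time course), plus voxelwise AR(1) noise, a random per-voxel linear drift
#' and a constant baseline. The subject's random stream is derived
#' deterministically from the master seed and the subject id.
#'
#' @param phen One-row data frame (or list) with `participant_id` and `group`.
#' @param truth A [ground_truth()].
#' @param grid The [voxel_grid()] the maps live on.
#' @param T Number of frames.
#' @param tr_s Repetition time, seconds.
#' @param seed Master seed.
#' @param band_hz Pass band of the simulated network signals.
#' @return A [bold_run()]; attribute `timecourses` holds the noise-free
#'   network time courses (ground truth for lag-recovery checks).
#' @export
simulate_subject <- function(phen, truth, grid, T = 220L, tr_s = 2.08,
                             seed = 1L, band_hz = c(0.01, 0.08)) {
  group <- as.character(phen$group)
  if (!group %in% names(truth$coupling))
    stop_named("simulate_subject: no ground truth for group '%s'", group)
  sid <- as.character(phen$participant_id)
  s <- derive_seed(seed, sid)
  tc <- simulate_network_timecourses(T, tr_s, truth$coupling[[group]],
                                     truth$coupling_lags[[group]], band_hz,
                                     seed = s)
  emaps <- effective_maps(truth, group)
  V <- n_voxels(grid)
  M <- vapply(emaps, as.vector, numeric(V))      # V x k
  Y <- tcrossprod(tc, M)                          # T x V
  if (!is.null(truth$nuisance_maps) && truth$nuisance_amp > 0) {
    nn <- ncol(truth$nuisance_maps)
    ntc <- with_seed(derive_seed(seed, paste0(sid, ":nuisance")),
      vapply(seq_len(nn), function(j) band_noise(T, tr_s, band_hz),
             numeric(T)))
    Y <- Y + truth$nuisance_amp * tcrossprod(ntc, truth$nuisance_maps)
  }
  nz <- truth$noise
  with_seed(derive_seed(seed, paste0(sid, ":noise")), {
    if (nz$sd > 0) {
      e <- matrix(rnorm(T * V, sd = nz$sd * sqrt(1 - nz$rho^2)), T, V)
      if (nz$rho != 0) for (t in 2:T) e[t, ] <- nz$rho * e[t - 1, ] + e[t, ]
      Y <- Y + e
    }
    if (nz$drift_sd > 0) {
      ramp <- seq(-0.5, 0.5, length.out = T)
      Y <- Y + outer(ramp, rnorm(V, sd = nz$drift_sd))
    }
  })
  Y <- Y + (nz$baseline %||% 0)
  run <- bold_run(array(t(Y), c(grid$dims, T)), tr_s, grid)
  attr(run, "timecourses") <- tc
  run
}

group_table1 <- function() {
  # Group-level calibration of the phenotype generator (means and SDs).
  list(
    HC  = list(n = 22L, age = c(47.0, 12.2), edu = c(14.7, 3.2),
               sex_mf = c(10L, 12L), gm = c(620, 45), corsi = NULL,
               moca = NULL, ledd = NULL, gene = NULL),
    HET = list(n = 12L, age = c(41.9, 14.8), edu = c(12.3, 2.1),
               sex_mf = c(5L, 7L), gm = c(605, 45), corsi = c(4.6, 0.5),
               moca = c(23.8, 1.8), ledd = NULL,
               gene = c(PINK1 = 10L, Park2 = 2L)),
    HOM = list(n = 8L, age = c(51.4, 8.1), edu = c(11.4, 2.3),
               sex_mf = c(6L, 2L), gm = c(580, 45), corsi = c(3.9, 0.3),
               moca = c(23.0, 2.6), ledd = c(590.9, 358.1),
               gene = c(PINK1 = 5L, Park2 = 3L))
  )
}

#' Cohort configuration
#'
#' Collects every knob of the synthetic cohort with defaults emulating the
#' study conditions: 22 controls, 12 heterozygous and 8 homozygous mutation
#' carriers, TR = 2.08 s, 220 volumes, five networks on a desk-scale grid.
#'
#' @param group_sizes Named integer vector (`HC`, `HET`, `HOM`).
#' @param grid A [voxel_grid()].
#' @param T Frames per run. @param tr_s Repetition time, seconds.
#' @param n_networks,blobs_per_network Passed to [make_network_maps()].
#' @param band_hz Network signal pass band.
#' @param noise Noise model, see [ground_truth()].
#' @param n_nuisance Number of shared structured nuisance sources
#'   ([make_nuisance_maps()]); 0 for none.
#' @param nuisance_amp Amplitude of the nuisance sources.
#' @param sigma_vox,max_overlap_r Blob width (voxels) and pairwise spatial
#'   correlation bound for [make_network_maps()].
#' @param seed Master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(HC = 22L, HET = 12L, HOM = 8L),
                          grid = voxel_grid(), T = 220L, tr_s = 2.08,
                          n_networks = 5L, blobs_per_network = 3L,
                          band_hz = c(0.01, 0.08),
                          noise = list(rho = 0.3, sd = 1, drift_sd = 0.5,
                                       baseline = 100),
                          n_nuisance = 10L, nuisance_amp = 0.3,
                          sigma_vox = 1.4, max_overlap_r = 0.1,
                          seed = 1L) {
  stopifnot(all(c("HC", "HET", "HOM") %in% names(group_sizes)))
  if (any(group_sizes < 2L))
    stop_named("cohort_config: every group needs >= 2 subjects (GLM df)")
  structure(list(group_sizes = group_sizes, grid = grid, T = as.integer(T),
                 tr_s = tr_s, n_networks = as.integer(n_networks),
                 blobs_per_network = as.integer(blobs_per_network),
                 band_hz = band_hz, noise = noise,
                 n_nuisance = as.integer(n_nuisance),
                 nuisance_amp = nuisance_amp, sigma_vox = sigma_vox,
                 max_overlap_r = max_overlap_r, seed = as.integer(seed)),
            class = "cohort_config")
}

rtrunc0 <- function(n, mean, sd) pmax(0, rnorm(n, mean, sd))

simulate_participants <- function(config) {
  cal <- group_table1()
  gs <- config$group_sizes
  rows <- list()
  with_seed(derive_seed(config$seed, "participants"), {
    for (g in c("HC", "HET", "HOM")) {
      n <- gs[[g]]
      cc <- cal[[g]]
      ids <- sprintf("sub-%s%02d", g, seq_len(n))
      sexes <- rep(c("M", "F"), times = round(cc$sex_mf / sum(cc$sex_mf) * n))
      sexes <- c(sexes, rep("F", max(0, n - length(sexes))))[seq_len(n)]
      genes <- if (is.null(cc$gene)) rep("none", n) else {
        gv <- rep(names(cc$gene), times = round(cc$gene / sum(cc$gene) * n))
        c(gv, rep(names(cc$gene)[1], max(0, n - length(gv))))[seq_len(n)]
      }
      rows[[g]] <- data.frame(
        participant_id = ids, group = g, gene = genes,
        age = round(pmax(18, rnorm(n, cc$age[1], cc$age[2])), 1),
        sex = sexes,
        education = round(pmax(5, rnorm(n, cc$edu[1], cc$edu[2])), 1),
        gm_volume = round(rnorm(n, cc$gm[1], cc$gm[2]), 1),
        corsi = if (is.null(cc$corsi)) NA_real_
                else round(rnorm(n, cc$corsi[1], cc$corsi[2]), 1),
        moca = if (is.null(cc$moca)) NA_real_
               else round(pmin(30, rnorm(n, cc$moca[1], cc$moca[2])), 1),
        ledd = if (is.null(cc$ledd)) NA_real_
               else round(rtrunc0(n, cc$ledd[1], cc$ledd[2]), 1),
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the full synthetic cohort
#'
#' Draws the phenotype table, the ground-truth networks and couplings, and one
#' BOLD run per subject. Deterministic given the config (which contains the
#' master seed).
#'
#' @param config A [cohort_config()].
#' @return List with `runs` (named list of [bold_run()]), `participants`
#'   (data frame), `truth` ([ground_truth()]) and `grid`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  participants <- simulate_participants(config)
  maps <- make_network_maps(config$grid, config$n_networks,
                            config$blobs_per_network,
                            seed = derive_seed(config$seed, "maps"),
                            sigma_vox = config$sigma_vox,
                            max_overlap_r = config$max_overlap_r)
  nm <- if (config$n_nuisance > 0L)
    make_nuisance_maps(config$grid, config$n_nuisance,
                       seed = derive_seed(config$seed, "nuisance"))
  else NULL
  truth <- ground_truth(maps, noise = config$noise, nuisance_maps = nm,
                        nuisance_amp = config$nuisance_amp,
                        seed = config$seed)
  runs <- lapply(seq_len(nrow(participants)), function(i)
    simulate_subject(participants[i, ], truth, config$grid, config$T,
                     config$tr_s, seed = config$seed,
                     band_hz = config$band_hz))
  names(runs) <- participants$participant_id
  list(runs = runs, participants = participants, truth = truth,
       grid = config$grid)
}
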