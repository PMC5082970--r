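#' Remove a linear trend and the mean from a time course
#'
#' Least-squares projection onto `{1, t}` removed; idempotent.
#'
#' @param tc Numeric vector, length at least 3.
#' @return Detrended vector.
#' @export
detrend_timecourse <- function(tc) {
  T <- length(tc)
  if (T < 3L) stop_named("detrend_timecourse: need at least 3 samples")
  if (sd(tc) == 0) {
    warning("detrend_timecourse: constant series; returning zeros")
    return(numeric(T))
  }
  t <- seq_len(T) - (T + 1) / 2
  tc <- tc - mean(tc)
  tc - t * sum(t * tc) / sum(t^2)
}

#' Circularly lagged Pearson correlation
#'
#' Correlation of `x[t]` with `y[(t + lag) mod T]`; the shift is circular, so
#' all `T` samples contribute at every lag.
#'
#' @param x,y Numeric vectors of equal length (at least 3), non-constant.
#' @param lag Integer lag in samples.
#' @return Pearson correlation at that lag.
#' @export
circular_lagged_r <- function(x, y, lag = 0L) {
  T <- length(x)
  stopifnot(length(y) == T, T >= 3L)
  if (sd(x) == 0) stop_named("circular_lagged_r: first series is constant")
  if (sd(y) == 0) stop_named("circular_lagged_r: second series is constant")
  cor(x, circular_shift(y, lag))
}

r_to_p <- function(r, df) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(tval), df)
}

#' Constrained maximal lagged correlation between two time courses
#'
#' Evaluates the circular lagged Pearson correlation at every integer lag in
#' `[-max_lag, max_lag]` and returns the lag with the best (smallest) p value
#' - for fixed length this is the lag maximizing `|r|`. Ties are broken by
#' the smaller `|lag|`, then by the negative lag. The parametric p uses the t
#' transform of r with `T - 2` degrees of freedom; because maximizing over
#' `2 max_lag + 1` lags inflates that naive p, a circular-rotation
#' permutation p (rotation null preserving autocorrelation) can be computed
#' alongside.
#'
#' @param x,y Numeric vectors, `length > 2 * max_lag`.
#' @param max_lag Largest lag magnitude searched (default 12 samples).
#' @param n_rotations If positive, also compute `p_rotation` from this many
#'   circular-rotation surrogates.
#' @param seed Seed for the rotation draw.
#' @return List: `optimal_lag`, `r`, `p`, `z` (Fisher), `df`, and optionally
#'   `p_rotation`.
#' @export
max_lagged_correlation <- function(x, y, max_lag = 12L, n_rotations = 0L,
                                   seed = 1L) {
  T <- length(x)
  max_lag <- as.integer(max_lag)
  if (T <= 2L * max_lag)
    stop_named("max_lagged_correlation: need T > 2*max_lag (T = %d, max_lag = %d)",
               T, max_lag)
  lags <- (-max_lag):max_lag
  rs <- vapply(lags, function(l) circular_lagged_r(x, y, l), numeric(1))
  # best |r|; ties -> smaller |lag|, then negative lag
  ord <- order(-abs(rs), abs(lags), lags)
  best <- ord[1]
  r <- rs[best]
  # clamp for the z transform: a numerically perfect |r| = 1 (constructed
  # shifts) would otherwise map to an infinite z
  rc <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  out <- list(optimal_lag = lags[best], r = r, p = r_to_p(r, T - 2),
              z = fisher_z(rc), df = T - 2L)
  if (n_rotations > 0L) {
    # Full circular correlation function via FFT (numerically equivalent to
    # the direct scan); rotating y by d shifts the lag axis by d, so each
    # surrogate maximum is a windowed maximum of the same function.
    rho <- circ_corr_fun(x, y)
    obs <- max(abs(rs))
    rots <- with_seed(seed, sample.int(T - 1L, min(n_rotations, T - 1L)))
    null_max <- vapply(rots, function(d)
      max(abs(rho[((d + lags) %% T) + 1L])), numeric(1))
    out$p_rotation <- (1 + sum(null_max >= obs - 1e-12)) / (length(rots) + 1)
  }
  out
}

# Circular correlation function at all lags 0..T-1 via FFT.
circ_corr_fun <- function(x, y) {
  T <- length(x)
  xs <- x - mean(x); ys <- y - mean(y)
  num <- Re(stats::fft(Conj(stats::fft(xs)) * stats::fft(ys),
                       inverse = TRUE)) / T
  num / (sqrt(sum(xs^2)) * sqrt(sum(ys^2)))
}

#' Fisher z-transformation of a correlation coefficient
#' @param r Correlation, `|r| < 1`.
#' @return `atanh(r) = 0.5 log((1 + r) / (1 - r))`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop_named("fisher_z: |r| must be < 1")
  atanh(r)
}

#' Per-subject lagged correlations for all network pairs
#'
#' Detrends each network time course and computes the constrained maximal
#' lagged correlation for every unordered pair of networks, for every
#' subject.
#'
#' @param timecourses Named list (per subject) of T x k matrices with network
#'   names as columns.
#' @param max_lag Lag bound (samples).
#' @param n_rotations,seed Optional rotation-null p, see
#'   [max_lagged_correlation()].
#' @return Long data frame: `participant_id`, `pair`, `network_a`,
#'   `network_b`, `optimal_lag`, `r`, `p`, `z` (and `p_rotation` if asked).
#' @export
lagged_correlation_table <- function(timecourses, max_lag = 12L,
                                     n_rotations = 0L, seed = 1L) {
  stopifnot(length(timecourses) >= 1L)
  nets <- colnames(timecourses[[1]])
  pairs <- utils::combn(nets, 2)
  rows <- vector("list", length(timecourses) * ncol(pairs))
  i <- 0L
  for (sid in names(timecourses)) {
    tc <- apply(timecourses[[sid]], 2, detrend_timecourse)
    colnames(tc) <- nets
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      res <- max_lagged_correlation(tc[, a], tc[, b], max_lag = max_lag,
                                    n_rotations = n_rotations,
                                    seed = derive_seed(seed,
                                                       paste(sid, a, b)))
      i <- i + 1L
      rows[[i]] <- data.frame(participant_id = sid,
                              pair = paste(a, b, sep = "_"),
                              network_a = a, network_b = b,
                              optimal_lag = res$optimal_lag, r = res$r,
                              p = res$p, z = res$z,
                              p_rotation = res$p_rotation %||% NA_real_,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Design pieces shared by the z-score ANCOVA and contrasts.
z_model_matrices <- function(phen, nuisance) {
  n <- nrow(phen)
  Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in nuisance) {
    col <- as.numeric(phen[[v]])
    Z <- cbind(Z, col - mean(col))
    colnames(Z)[ncol(Z)] <- v
  }
  g <- factor(phen$group)
  D <- sapply(levels(g)[-1], function(l) as.numeric(g == l))
  X <- cbind(Z, D)
  colnames(X) <- c(colnames(Z), paste0("group", levels(g)[-1]))
  cn <- kappa(crossprod(X))
  if (cn > 1e8)
    warning(sprintf("group model nearly collinear (condition number %.3g)", cn))
  list(Z = Z, X = X, g = g)
}

#' Group ANCOVA on Fisher-z inter-network scores
#'
#' Tests the group factor on per-subject z scores for one network pair after
#' adjusting for nuisance covariates (education and grey-matter volume by
#' default). Bonferroni correction is applied over the number of pairs
#' actually tested in the run.
#'
#' @param z Per-subject Fisher z values (phenotype order).
#' @param phen Phenotype table with `group` and the nuisance columns.
#' @param nuisance Nuisance covariate names.
#' @param n_pairs Bonferroni scope (number of pairs in the run).
#' @return List: `F`, `df1`, `df2`, `p`, `p_bonferroni`.
#' @export
group_anova_z <- function(z, phen, nuisance = c("education", "gm_volume"),
                          n_pairs = 1L) {
  tab <- table(phen$group)
  if (length(tab) < 2L || any(tab < 2L))
    stop_named("group_anova_z: need >= 2 groups with >= 2 subjects each")
  mm <- z_model_matrices(phen, nuisance)
  n <- length(z)
  rss <- function(X) {
    fit <- qr(X)
    sum(qr.resid(fit, z)^2)
  }
  rss0 <- rss(mm$Z)
  rss1 <- rss(mm$X)
  df1 <- ncol(mm$X) - ncol(mm$Z)
  df2 <- n - ncol(mm$X)
  F <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- pf(F, df1, df2, lower.tail = FALSE)
  list(F = F, df1 = df1, df2 = df2, p = p,
       p_bonferroni = min(1, p * n_pairs))
}

#' Covariate-adjusted pairwise group contrasts on Fisher-z scores
#'
#' t statistics for all group differences, using the residual variance of the
#' full model (all groups plus nuisance).
#'
#' @inheritParams group_anova_z
#' @return Data frame: `contrast`, `estimate`, `t`, `df`, `p`.
#' @export
pairwise_contrasts <- function(z, phen, nuisance = c("education", "gm_volume")) {
  mm <- z_model_matrices(phen, nuisance)
  X <- mm$X
  n <- length(z)
  qx <- qr(X)
  beta <- qr.coef(qx, z)
  df <- n - ncol(X)
  s2 <- sum(qr.resid(qx, z)^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  XtXinv[qx$pivot, qx$pivot] <- XtXinv
  levs <- levels(mm$g)
  # coefficient vector position of each group's offset (reference = 0)
  pos <- stats::setNames(match(paste0("group", levs), colnames(X)), levs)
  combs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    cv <- numeric(ncol(X))
    if (!is.na(pos[g2])) cv[pos[g2]] <- 1
    if (!is.na(pos[g1])) cv[pos[g1]] <- -1
    est <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% XtXinv %*% cv) * s2)
    tval <- est / se
    data.frame(contrast = paste(g2, g1, sep = "-"), estimate = est,
               t = tval, df = df, p = 2 * pt(-abs(tval), df),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Partial correlation of inter-network z scores with a behavioural score
#'
#' Residualizes both the z scores and the score on the nuisance covariates
#' (grey-matter volume by default) and correlates the residuals; the
#' two-sided p uses `n - 2 - q` degrees of freedom for `q` nuisance columns.
#' Subjects with missing values are excluded and logged.
#'
#' @param z Per-subject z scores.
#' @param score Behavioural score (e.g. Corsi span), same order.
#' @param nuisance Numeric vector or matrix of nuisance covariates.
#' @return List: `r`, `p`, `n`, `df`.
#' @export
behavior_partial_correlation <- function(z, score, nuisance) {
  nz <- cbind(nuisance)
  keep <- stats::complete.cases(z, score, nz)
  if (sum(!keep) > 0)
    message(sprintf("behavior_partial_correlation: excluding %d incomplete cases",
                    sum(!keep)))
  z <- z[keep]; score <- score[keep]
  nz <- nz[keep, , drop = FALSE]
  n <- length(z)
  if (n < 5L) stop_named("behavior_partial_correlation: need >= 5 complete cases")
  X <- cbind(1, nz)
  rz <- qr.resid(qr(X), z)
  rs <- qr.resid(qr(X), score)
  if (sd(rz) == 0 || sd(rs) == 0)
    stop_named("behavior_partial_correlation: zero-variance residuals")
  r <- cor(rz, rs)
  df <- n - 2L - ncol(nz)
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df), n = n, df = df)
}

#' Correlation of levodopa dose with functional connectivity summaries
#'
#' Sensitivity analysis: per-network Pearson correlation between LEDD and an
#' FC summary in the treated group; reported uncorrected.
#'
#' @param fc Subjects x networks matrix of FC summaries.
#' @param ledd Per-subject levodopa equivalent daily dose.
#' @return Data frame: `network`, `r`, `p`, `n`; `NULL` (with a warning) if
#'   fewer than 4 subjects.
#' @export
ledd_fc_check <- function(fc, ledd) {
  fc <- as.matrix(fc)
  keep <- !is.na(ledd)
  fc <- fc[keep, , drop = FALSE]; ledd <- ledd[keep]
  n <- length(ledd)
  if (n < 4L) {
    warning("ledd_fc_check: fewer than 4 subjects with LEDD; skipped")
    return(NULL)
  }
  if (sd(ledd) == 0) stop_named("ledd_fc_check: LEDD is constant")
  rows <- lapply(seq_len(ncol(fc)), function(j) {
    r <- cor(ledd, fc[, j])
    df <- n - 2L
    tval <- r * sqrt(df / (1 - r^2))
    data.frame(network = colnames(fc)[j] %||% paste0("net", j), r = r,
               p = 2 * pt(-abs(tval), df), n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full inter-network group analysis
#'
#' Runs the whole inter-network stage on per-subject network time courses:
#' per-subject constrained maximal lagged correlations for all pairs, group
#' summary per pair (mean lag, mean r, one-sample p of the group z scores),
#' group ANCOVA with Bonferroni over the tested pairs, and all pairwise
#' contrasts.
#'
#' @param timecourses Named list (per subject, order matching `phen`) of
#'   T x k matrices with network columns.
#' @param phen Phenotype table.
#' @param max_lag Lag bound in samples (default 12).
#' @param nuisance Nuisance covariates for the ANCOVA.
#' @param n_rotations,seed Optional rotation-calibrated per-subject p.
#' @return List of class `inter_network_result`: `subject_table` (long per
#'   subject x pair), `group_table` (pair x group means), `anova_table`
#'   (per pair F/p/Bonferroni), `contrast_table`.
#' @export
inter_network_analysis <- function(timecourses, phen, max_lag = 12L,
                                   nuisance = c("education", "gm_volume"),
                                   n_rotations = 0L, seed = 1L) {
  stopifnot(length(timecourses) == nrow(phen))
  if (is.null(names(timecourses)))
    names(timecourses) <- phen$participant_id
  subject <- lagged_correlation_table(timecourses, max_lag = max_lag,
                                      n_rotations = n_rotations, seed = seed)
  pairs <- unique(subject$pair)
  groups <- unique(as.character(phen$group))
  gidx <- match(subject$participant_id, phen$participant_id)
  subject$group <- as.character(phen$group)[gidx]
  grows <- list(); arows <- list(); crows <- list()
  for (pr in pairs) {
    sub <- subject[subject$pair == pr, ]
    sub <- sub[match(phen$participant_id, sub$participant_id), ]
    for (g in groups) {
      zg <- sub$z[sub$group == g]
      tt <- stats::t.test(zg)
      grows[[paste(pr, g)]] <- data.frame(
        pair = pr, group = g, n = length(zg),
        mean_lag = mean(sub$optimal_lag[sub$group == g]),
        mean_r = mean(sub$r[sub$group == g]),
        mean_z = mean(zg), p = tt$p.value, stringsAsFactors = FALSE)
    }
    av <- group_anova_z(sub$z, phen, nuisance = nuisance,
                        n_pairs = length(pairs))
    arows[[pr]] <- data.frame(pair = pr, F = av$F, df1 = av$df1,
                              df2 = av$df2, p = av$p,
                              p_bonferroni = av$p_bonferroni,
                              stringsAsFactors = FALSE)
    ct <- pairwise_contrasts(sub$z, phen, nuisance = nuisance)
    ct$pair <- pr
    crows[[pr]] <- ct
  }
  structure(list(subject_table = subject,
                 group_table = do.call(rbind, c(grows,
                                                make.row.names = FALSE)),
                 anova_table = do.call(rbind, c(arows,
                                                make.row.names = FALSE)),
                 contrast_table = do.call(rbind, c(crows,
                                                   make.row.names = FALSE))),
            class = "inter_network_result")
}

#' @export
print.inter_network_result <- function(x, ...) {
  cat(sprintf("inter_network_result: %d pairs, %d subjects\n",
              nrow(x$anova_table),
              length(unique(x$subject_table$participant_id))))
  print(x$anova_table, row.names = FALSE)
  invisible(x)
}
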