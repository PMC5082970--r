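#' Subject-level PCA reduction
#'
#' Projects one preprocessed run onto its leading temporal principal subspace.
#' With `X` the frames x voxels matrix (each voxel demeaned over time), the
#' reduction keeps `k_subject` components: `X ~ basis %*% scores` with `basis`
#' the top temporal eigenvectors (T x k) and `scores` the reduced spatial data
#' (k x V). The basis is retained for back-reconstruction.
#'
#' @param run A [bold_run()] (or a frames x voxels matrix).
#' @param k_subject Number of components to keep (at most T).
#' @param mask Optional logical 3-D mask restricting the voxels used.
#' @return List of class `subject_reduction` with `scores`, `basis`, `sdev`
#'   (component standard deviations, non-increasing), `voxel_means`, `T`, `V`.
#' @export
subject_reduce <- function(run, k_subject = 30L, mask = NULL) {
  X <- if (inherits(run, "bold_run")) run_matrix(run, mask) else as.matrix(run)
  T <- nrow(X); V <- ncol(X)
  k <- min(as.integer(k_subject), T)
  if (k < 1L) stop_named("subject_reduce: k_subject must be >= 1")
  mu <- colMeans(X)
  X <- sweep(X, 2, mu)
  tv <- sum(X^2)
  if (tv == 0) stop_named("subject_reduce: data have zero variance")
  ev <- eigen(tcrossprod(X), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  basis <- ev$vectors[, seq_len(k), drop = FALSE]
  scores <- crossprod(basis, X)
  structure(list(scores = scores, basis = basis,
                 sdev = sqrt(vals[seq_len(k)] / max(1, V)),
                 voxel_means = mu, T = T, V = V),
            class = "subject_reduction")
}

sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(W)) %*% t(e$vectors) %*% W
}

# Fixed-point (FastICA) estimation of an orthogonal unmixing matrix for
# whitened data Z (k x V), logcosh/tanh contrast, symmetric decorrelation.
# Symmetric updates can cycle from an unlucky initialisation, so a few
# deterministic restarts (seeds derived from `seed`) are attempted before
# declaring non-convergence.
fastica_symm <- function(Z, seed, max_iter = 500L, tol = 1e-6,
                         restarts = 6L) {
  k <- nrow(Z); V <- ncol(Z)
  delta <- Inf
  for (attempt in seq_len(restarts)) {
    s <- if (attempt == 1L) seed
         else derive_seed(seed, paste0("ica_restart_", attempt))
    W <- with_seed(s, qr.Q(qr(matrix(rnorm(k * k), k, k))))
    for (it in seq_len(max_iter)) {
      S <- W %*% Z
      G <- tanh(S)
      W1 <- G %*% t(Z) / V - diag(rowMeans(1 - G^2)) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- 1 - min(abs(diag(W1 %*% t(W))))
      # a persistent large step signals a period-2 cycle of the symmetric
      # update; a damped (averaged) step collapses the cycle
      if (it > 50L && delta > 0.05)
        W1 <- sym_decorrelate(W1 + W)
      W <- W1
      if (delta < tol)
        return(list(W = W, iterations = it, converged = TRUE,
                    restarts = attempt - 1L))
    }
  }
  stop_named(paste("group_decompose: fixed-point ICA did not converge after",
                   "%d iterations in %d attempts (last step tolerance %.2e,",
                   "target %.2e)"),
             max_iter, restarts, delta, tol)
}

#' Temporal-concatenation group spatial ICA with back-reconstruction
#'
#' Stacks the subject-reduced spatial data over (reduced) time, performs a
#' second PCA down to `n_components`, estimates spatially independent
#' components by fixed-point ICA (tanh contrast, symmetric decorrelation),
#' and back-reconstructs subject-specific maps and time courses through the
#' stored reduction matrices. The sign of each component is fixed so that its
#' group map has positive skewness (networks are sparse positive activations).
#'
#' @param reductions List of [subject_reduce()] results, one per subject.
#' @param n_components Model order (number of components).
#' @param seed Integer seed for the ICA initialisation.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return Object of class `ica_decomposition`: `group_maps`
#'   (n_components x V, unit variance over voxels), `subject_maps` (list of
#'   n_components x V), `subject_timecourses` (list of T x n_components),
#'   `mixing` (stacked mixing matrix), `iterations`, `n_components`.
#' @export
group_decompose <- function(reductions, n_components = 20L, seed = 1L,
                            max_iter = 500L, tol = 1e-6) {
  stopifnot(length(reductions) >= 1L,
            all(vapply(reductions, inherits, TRUE, "subject_reduction")))
  k2 <- as.integer(n_components)
  ks <- vapply(reductions, function(r) nrow(r$scores), integer(1))
  if (sum(ks) < k2)
    stop_named("group_decompose: total reduced dimension %d < n_components %d",
               sum(ks), k2)
  V <- reductions[[1]]$V
  Xc <- do.call(rbind, lapply(reductions, function(r)
    r$scores - rowMeans(r$scores)))
  ev <- eigen(tcrossprod(Xc) / V, symmetric = TRUE)
  d <- pmax(ev$values[seq_len(k2)], .Machine$double.eps)
  G <- ev$vectors[, seq_len(k2), drop = FALSE]
  Zw <- diag(1 / sqrt(d), k2) %*% crossprod(G, Xc)   # whitened k2 x V
  fit <- fastica_symm(Zw, seed = seed, max_iter = max_iter, tol = tol)
  S <- fit$W %*% Zw                                   # group maps, var 1
  A <- G %*% diag(sqrt(d), k2) %*% t(fit$W)           # (sum k) x k2 mixing
  flip <- vapply(seq_len(k2), function(i) skewness(S[i, ]) < 0, logical(1))
  S[flip, ] <- -S[flip, , drop = FALSE]
  A[, flip] <- -A[, flip, drop = FALSE]
  offs <- c(0L, cumsum(ks))
  subject_maps <- vector("list", length(reductions))
  subject_tcs <- vector("list", length(reductions))
  for (i in seq_along(reductions)) {
    rows <- (offs[i] + 1):offs[i + 1]
    Ai <- A[rows, , drop = FALSE]
    Xi <- Xc[rows, , drop = FALSE]
    subject_maps[[i]] <- qr.solve(Ai, Xi)
    subject_tcs[[i]] <- reductions[[i]]$basis %*% Ai
  }
  names(subject_maps) <- names(reductions)
  names(subject_tcs) <- names(reductions)
  structure(list(group_maps = S, subject_maps = subject_maps,
                 subject_timecourses = subject_tcs, mixing = A,
                 n_components = k2, iterations = fit$iterations),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("ica_decomposition: %d components, %d subjects, %d voxels (converged in %d iterations)\n",
              x$n_components, length(x$subject_maps),
              ncol(x$group_maps), x$iterations))
  invisible(x)
}

#' Convert component maps to z-scores
#'
#' Standardizes each group map and each subject map to zero mean and unit
#' variance over the mask voxels.
#'
#' @param dec An [group_decompose()] result.
#' @return The decomposition with standardized maps.
#' @export
zscore_maps <- function(dec) {
  zrows <- function(M) {
    s <- apply(M, 1, sd)
    if (any(s == 0))
      stop_named("zscore_maps: component %d is constant over the mask",
                 which(s == 0)[1])
    (M - rowMeans(M)) / s
  }
  dec$group_maps <- zrows(dec$group_maps)
  dec$subject_maps <- lapply(dec$subject_maps, zrows)
  dec
}

# Exact maximum-sum injective assignment of templates to components by
# dynamic programming over template subsets (templates n small, components m).
# val[j+1, state+1]: best total using components 1..j with `state` templates
# assigned. Components are scanned in order and an equal-value later
# assignment never replaces an earlier one, so ties resolve toward the lower
# component index.
assign_templates <- function(R) {
  n <- nrow(R); m <- ncol(R)
  nstate <- bitwShiftL(1L, n)
  val <- matrix(-Inf, m + 1L, nstate)
  val[1L, 1L] <- 0
  take <- matrix(0L, m + 1L, nstate)   # template taken by component j (0 = skip)
  for (j in seq_len(m)) {
    for (st in 0:(nstate - 1L)) {
      v0 <- val[j, st + 1L]
      if (v0 == -Inf) next
      if (v0 >= val[j + 1L, st + 1L] - 1e-12) { # skip component j (ties: skip)
        val[j + 1L, st + 1L] <- v0
        take[j + 1L, st + 1L] <- 0L
      }
      for (t in seq_len(n)) {
        bit <- bitwShiftL(1L, t - 1L)
        if (bitwAnd(st, bit) != 0L) next
        ns <- bitwOr(st, bit)
        v <- v0 + R[t, j]
        if (v > val[j + 1L, ns + 1L] + 1e-12) {  # strict: earlier comp wins ties
          val[j + 1L, ns + 1L] <- v
          take[j + 1L, ns + 1L] <- t
        }
      }
    }
  }
  assign <- integer(n)
  st <- nstate - 1L
  for (j in rev(seq_len(m))) {
    t <- take[j + 1L, st + 1L]
    if (t > 0L) {
      assign[t] <- j
      st <- bitwAnd(st, bitwNot(bitwShiftL(1L, t - 1L)))
    }
  }
  assign
}

#' Match components to network templates
#'
#' Computes the spatial correlation of every (z-scored) group map with every
#' template over the mask, and selects the injective assignment of templates
#' to components maximizing the total correlation (optimal bipartite
#' matching, exact). Ties are broken toward the lower component index. Any
#' network whose best match falls below `floor_r` flags the assignment for
#' review.
#'
#' @param dec A [group_decompose()] result (ideally after [zscore_maps()]).
#' @param templates Named list of 3-D arrays, or a named matrix
#'   (templates x voxels) on the same voxel set as the decomposition.
#' @param mask Optional logical 3-D mask (applied to array templates).
#' @param floor_r Audit floor for the per-network match correlation.
#' @return Object of class `network_assignment`: `assignment` (data frame
#'   with network, component, match_r), `unassigned` component indices,
#'   `flagged` logical.
#' @export
match_components <- function(dec, templates, mask = NULL, floor_r = 0.3) {
  Tm <- if (is.list(templates))
    do.call(rbind, lapply(templates, function(a) {
      v <- as.vector(a)
      if (!is.null(mask)) v <- v[as.vector(mask)]
      v
    }))
  else as.matrix(templates)
  if (is.null(rownames(Tm)) && is.list(templates))
    rownames(Tm) <- names(templates)
  n <- nrow(Tm); m <- nrow(dec$group_maps)
  if (n > m)
    stop_named("match_components: %d templates but only %d components", n, m)
  if (ncol(Tm) != ncol(dec$group_maps))
    stop_named("match_components: template voxel count %d != map voxel count %d",
               ncol(Tm), ncol(dec$group_maps))
  R <- matrix(0, n, m)
  for (t in seq_len(n)) R[t, ] <- col_cor(t(dec$group_maps), Tm[t, ])
  assign <- assign_templates(R)
  df <- data.frame(network = rownames(Tm), component = assign,
                   match_r = R[cbind(seq_len(n), assign)],
                   stringsAsFactors = FALSE)
  flagged <- any(df$match_r < floor_r)
  if (flagged)
    warning(sprintf("match_components: networks below match floor %.2f: %s",
                    floor_r,
                    paste(df$network[df$match_r < floor_r], collapse = ", ")))
  structure(list(assignment = df,
                 unassigned = setdiff(seq_len(m), assign),
                 flagged = flagged),
            class = "network_assignment")
}

#' @export
print.network_assignment <- function(x, ...) {
  cat("network_assignment:\n")
  print(x$assignment, row.names = FALSE)
  invisible(x)
}
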