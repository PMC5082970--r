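#' Build a design matrix for voxelwise group statistics
#'
#' Constructs an intercept + treatment-coded design from a phenotype table,
#' with columns labelled as being of interest or nuisance. The default mirrors
#' the cross-sectional intra-network model: group (HC/HET/HOM) as the factor
#' of interest, grey-matter volume and years of education as nuisance
#' covariates.
#'
#' @param phen Phenotype data frame (one row per subject, in map order).
#' @param interest Character vector of columns of interest (factors are
#'   dummy-coded against their first level).
#' @param nuisance Character vector of nuisance covariate columns.
#' @return List of class `fc_design`: `X` (n x p), `interest_cols`,
#'   `nuisance_cols` (column indices), `terms` (per-column kind).
#' @export
build_design <- function(phen, interest = "group",
                         nuisance = c("gm_volume", "education")) {
  n <- nrow(phen)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  kinds <- "nuisance"
  add <- function(X, kinds, vars, kind) {
    for (v in vars) {
      col <- phen[[v]]
      if (is.null(col)) stop_named("build_design: no column '%s'", v)
      if (is.character(col) || is.factor(col)) {
        f <- factor(col)
        for (lev in levels(f)[-1]) {
          X <- cbind(X, as.numeric(f == lev))
          colnames(X)[ncol(X)] <- paste0(v, lev)
          kinds <- c(kinds, kind)
        }
      } else {
        X <- cbind(X, as.numeric(col) - mean(as.numeric(col)))
        colnames(X)[ncol(X)] <- v
        kinds <- c(kinds, kind)
      }
    }
    list(X = X, kinds = kinds)
  }
  r <- add(X, kinds, nuisance, "nuisance")
  r <- add(r$X, r$kinds, interest, "interest")
  X <- r$X; kinds <- r$kinds
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_named("build_design: rank-deficient design; collinear columns: %s",
               paste(bad, collapse = ", "))
  }
  structure(list(X = X, terms = kinds,
                 interest_cols = which(kinds == "interest"),
                 nuisance_cols = which(kinds == "nuisance")),
            class = "fc_design")
}

#' Fit a voxelwise ordinary least squares model
#'
#' Fits `Y = X B + E` independently at every voxel (column of `maps`).
#'
#' @param maps Subjects x voxels matrix of (subject-specific) network maps.
#' @param design An [build_design()] result or a plain design matrix.
#' @return Object of class `voxel_glm`: `beta` (p x V), `sigma2` (residual
#'   variance per voxel), `df` (residual degrees of freedom), `XtXinv`, `X`.
#' @export
fit_voxelwise_glm <- function(maps, design) {
  X <- if (inherits(design, "fc_design")) design$X else as.matrix(design)
  maps <- as.matrix(maps)
  n <- nrow(maps); p <- ncol(X)
  if (nrow(X) != n)
    stop_named("fit_voxelwise_glm: %d subjects in maps but %d design rows",
               n, nrow(X))
  if (n <= p)
    stop_named("fit_voxelwise_glm: need more subjects (%d) than columns (%d)",
               n, p)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop_named("fit_voxelwise_glm: rank-deficient design (collinear: %s)",
               paste(bad, collapse = ", "))
  }
  XtXinv <- chol2inv(qr.R(qx))
  # undo pivoting
  XtXinv[qx$pivot, qx$pivot] <- XtXinv
  beta <- XtXinv %*% crossprod(X, maps)
  res <- maps - X %*% beta
  df <- n - p
  structure(list(beta = beta, sigma2 = colSums(res^2) / df, df = df,
                 XtXinv = XtXinv, X = X, design = design),
            class = "voxel_glm")
}

#' Voxelwise t map for a linear contrast
#' @param fit A [fit_voxelwise_glm()] object.
#' @param contrast Numeric vector of length p.
#' @return Numeric vector of t statistics (one per voxel).
#' @export
contrast_tmap <- function(fit, contrast) {
  cv <- as.numeric(contrast)
  se2 <- drop(t(cv) %*% fit$XtXinv %*% cv) * fit$sigma2
  drop(crossprod(cv, fit$beta)) / sqrt(se2)
}

#' Voxelwise F map for a multi-row contrast
#' @param fit A [fit_voxelwise_glm()] object.
#' @param contrast q x p contrast matrix (or vector for q = 1).
#' @return Numeric vector of F statistics with `(q, df)` degrees of freedom.
#' @export
contrast_fmap <- function(fit, contrast) {
  C <- rbind(contrast)
  q <- nrow(C)
  M <- C %*% fit$XtXinv %*% t(C)
  B <- C %*% fit$beta
  colSums(B * solve(M, B)) / (q * fit$sigma2)
}

# Contrast selecting the group-of-interest columns (F test of the factor).
interest_contrast <- function(design) {
  p <- ncol(design$X)
  C <- matrix(0, length(design$interest_cols), p)
  C[cbind(seq_along(design$interest_cols), design$interest_cols)] <- 1
  C
}

# 26-connectivity labelling of a logical 3-D volume. Returns an integer
# vector of labels over the supra-threshold voxels plus their linear indices.
label_clusters <- function(supra, dims) {
  idx <- which(supra)
  if (length(idx) == 0L)
    return(list(labels = integer(0), idx = integer(0), sizes = integer(0)))
  vol <- array(0L, dims)
  vol[idx] <- seq_along(idx)   # position of each supra voxel in `idx`
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  co <- arrayInd(idx, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  labels <- integer(length(idx))
  lab <- 0L
  for (s in seq_along(idx)) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      x <- co[v, 1]; y <- co[v, 2]; z <- co[v, 3]
      nb <- cbind(x + offs[, 1], y + offs[, 2], z + offs[, 3])
      ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny &
            nb[, 3] >= 1 & nb[, 3] <= nz
      if (!any(ok)) next
      lin <- nb[ok, 1] + nx * (nb[ok, 2] - 1) + nx * ny * (nb[ok, 3] - 1)
      pos <- vol[lin]
      pos <- pos[pos > 0L]
      pos <- pos[labels[pos] == 0L]
      if (length(pos)) {
        labels[pos] <- lab
        queue <- c(queue, pos)
      }
    }
  }
  list(labels = labels, idx = idx, sizes = tabulate(labels, lab))
}

stat_threshold <- function(type, cluster_forming_p, df, q = 1L) {
  if (type == "t") qt(1 - cluster_forming_p / 2, df)  # two-sided on |t|
  else qf(1 - cluster_forming_p, q, df)
}

#' Permutation cluster-level inference for a voxelwise GLM
#'
#' Forms clusters of supra-threshold voxels (voxelwise p below
#' `cluster_forming_p`; two-sided for t contrasts) with 26-neighbour
#' connectivity, and assigns each cluster a familywise-error corrected p as
#' the proportion of permutations whose maximal cluster size reaches the
#' observed size. Permutations follow the Freedman-Lane scheme: nuisance
#' effects are estimated once, nuisance residuals are permuted, and the full
#' model is refit, which respects nuisance covariates under exchangeability.
#'
#' @param maps Subjects x voxels matrix.
#' @param design An [build_design()] result.
#' @param contrast Contrast vector (t) or matrix (F); default the F test of
#'   all columns of interest.
#' @param dims 3-D grid dims for connectivity.
#' @param cluster_forming_p Voxelwise threshold (default 0.001).
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame of class `cluster_result` with one row per cluster:
#'   `cluster_id`, `size_voxels`, peak voxel coordinates, `peak_stat`,
#'   `corrected_p`; attribute `stat_map` holds the observed statistic map.
#' @export
cluster_inference <- function(maps, design, contrast = NULL, dims,
                              cluster_forming_p = 0.001, n_perm = 1000L,
                              seed = 1L) {
  stopifnot(inherits(design, "fc_design"))
  if (n_perm < 100L) stop_named("cluster_inference: need n_perm >= 100")
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (is.null(contrast)) contrast <- interest_contrast(design)
  C <- rbind(contrast)
  type <- if (nrow(C) == 1L) "t" else "F"
  fit <- fit_voxelwise_glm(maps, design)
  stat <- if (type == "t") contrast_tmap(fit, drop(C))
          else contrast_fmap(fit, C)
  u <- stat_threshold(type, cluster_forming_p, fit$df, nrow(C))
  supra_fun <- function(s) if (type == "t") abs(s) >= u else s >= u
  obs <- label_clusters(array(supra_fun(stat), dims), dims)
  # Freedman-Lane: permute residuals from the nuisance-only model.
  Z <- design$X[, design$nuisance_cols, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z), t(Z))
  Yz <- Hz %*% maps
  Rz <- maps - Yz
  max_sizes <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    pm <- sample.int(n)
    Yb <- Yz + Rz[pm, , drop = FALSE]
    fb <- fit_voxelwise_glm(Yb, design)
    sb <- if (type == "t") contrast_tmap(fb, drop(C)) else contrast_fmap(fb, C)
    cl <- label_clusters(array(supra_fun(sb), dims), dims)
    if (length(cl$sizes)) max(cl$sizes) else 0L
  }, numeric(1)))
  if (length(obs$sizes) == 0L) {
    out <- data.frame(cluster_id = integer(0), size_voxels = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_stat = numeric(0),
                      corrected_p = numeric(0))
  } else {
    rows <- lapply(seq_along(obs$sizes), function(l) {
      vox <- obs$idx[obs$labels == l]
      pk <- vox[which.max(abs(stat[vox]))]
      pc <- arrayInd(pk, dims)
      data.frame(cluster_id = l, size_voxels = obs$sizes[l],
                 peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
                 peak_stat = stat[pk],
                 corrected_p = (1 + sum(max_sizes >= obs$sizes[l])) /
                               (n_perm + 1))
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$size_voxels), ]
    out$cluster_id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  attr(out, "stat_map") <- stat
  attr(out, "threshold") <- u
  attr(out, "stat_type") <- type
  attr(out, "df") <- c(nrow(C), fit$df)
  class(out) <- c("cluster_result", class(out))
  out
}

#' Corsi-span covariate analysis of intra-network connectivity
#'
#' Within the mutation-carrier groups, models subject maps with the group
#' factor, group-specific Corsi slopes as the effect of interest, and
#' grey-matter volume and mutated gene as nuisance covariates. Subjects with
#' missing Corsi scores are excluded (listwise) and logged. The positive
#' Corsi slope of each carrier group is tested with permutation cluster
#' inference.
#'
#' @param maps Subjects x voxels matrix for one network (carrier subjects in
#'   phenotype order).
#' @param phen Phenotype rows matching `maps` (groups HET/HOM).
#' @param dims Grid dims.
#' @param cluster_forming_p,n_perm,seed As in [cluster_inference()].
#' @return Named list (per carrier group) of `cluster_result` tables; groups
#'   with fewer than 4 scored subjects are skipped with a warning.
#' @export
corsi_correlation_analysis <- function(maps, phen, dims,
                                       cluster_forming_p = 0.001,
                                       n_perm = 1000L, seed = 1L) {
  keep <- phen$group %in% c("HET", "HOM")
  phen <- phen[keep, , drop = FALSE]
  maps <- as.matrix(maps)[keep, , drop = FALSE]
  miss <- is.na(phen$corsi)
  if (any(miss)) {
    message(sprintf("corsi_correlation_analysis: excluding %d subjects with missing Corsi: %s",
                    sum(miss),
                    paste(phen$participant_id[miss], collapse = ", ")))
    phen <- phen[!miss, , drop = FALSE]
    maps <- maps[!miss, , drop = FALSE]
  }
  out <- list()
  for (g in c("HET", "HOM")) {
    ng <- sum(phen$group == g)
    if (ng < 4L) {
      warning(sprintf("corsi_correlation_analysis: only %d %s subjects with Corsi; slope skipped",
                      ng, g))
      next
    }
    n <- nrow(phen)
    corsi_c <- phen$corsi - mean(phen$corsi)
    X <- cbind(1, as.numeric(phen$group == "HOM"),
               as.numeric(phen$gene == "Park2"),
               phen$gm_volume - mean(phen$gm_volume),
               corsi_c * (phen$group == "HET"),
               corsi_c * (phen$group == "HOM"))
    colnames(X) <- c("(Intercept)", "groupHOM", "genePark2", "gm_volume",
                     "corsi_HET", "corsi_HOM")
    slope_col <- if (g == "HET") 5L else 6L
    design <- structure(list(X = X,
                             terms = ifelse(seq_len(6L) == slope_col,
                                            "interest", "nuisance"),
                             interest_cols = slope_col,
                             nuisance_cols = setdiff(seq_len(6L), slope_col)),
                        class = "fc_design")
    cv <- numeric(6L); cv[slope_col] <- 1
    out[[g]] <- cluster_inference(maps, design, contrast = cv, dims = dims,
                                  cluster_forming_p = cluster_forming_p,
                                  n_perm = n_perm,
                                  seed = derive_seed(seed, paste0("corsi_", g)))
  }
  out
}
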