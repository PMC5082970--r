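#' Pipeline run configuration
#'
#' Collects every stage's parameters plus the master seed. Per-stage seeds
#' are derived from the master seed and the stage name via [derive_seed()],
#' so any stage can be rerun in isolation reproducibly.
#'
#' @param cohort A [cohort_config()].
#' @param n_discard,band_hz,smooth_fwhm_mm,bandpass_method Preprocessing.
#' @param k_subject,n_components ICA reduction sizes.
#' @param cluster_forming_p,n_perm Intra-network inference.
#' @param max_lag,n_rotations Inter-network statistic.
#' @param stages Character vector of stages to execute, a subset of
#'   `simulate`, `preprocess`, `ica`, `intra`, `inter`, `report`. Stages not
#'   listed are loaded from a previous run's outputs in the same directory.
#' @param compress Write `.nii.gz` (TRUE) or plain `.nii` (FALSE, default:
#'   plain files make checksum manifests byte-stable).
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       n_discard = 4L, band_hz = c(0.01, 0.08),
                       smooth_fwhm_mm = 8, bandpass_method = "fft",
                       k_subject = 30L, n_components = 20L,
                       cluster_forming_p = 0.001, n_perm = 1000L,
                       max_lag = 12L, n_rotations = 0L,
                       stages = c("simulate", "preprocess", "ica", "intra",
                                  "inter", "report"),
                       compress = FALSE, seed = 1L) {
  structure(list(cohort = cohort, n_discard = as.integer(n_discard),
                 band_hz = band_hz, smooth_fwhm_mm = smooth_fwhm_mm,
                 bandpass_method = bandpass_method,
                 k_subject = as.integer(k_subject),
                 n_components = as.integer(n_components),
                 cluster_forming_p = cluster_forming_p,
                 n_perm = as.integer(n_perm), max_lag = as.integer(max_lag),
                 n_rotations = as.integer(n_rotations), stages = stages,
                 compress = isTRUE(compress), seed = as.integer(seed)),
            class = "run_config")
}

nii_ext <- function(config) if (config$compress) ".nii.gz" else ".nii"

write_map_stack <- function(maps_matrix, dims, voxel_size_mm, path) {
  a <- array(t(maps_matrix), c(dims, nrow(maps_matrix)))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(voxel_size_mm, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_map_stack <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  t(matrix(a, prod(dim(a)[1:3]), dim(a)[4]))
}

stage_msg <- function(stage, what) message(sprintf("[%s] %s", stage, what))

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_named("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, ICA, intra-network, inter-network and
#' report stages into `out_dir`, writing every artifact to disk (NIfTI, TSV,
#' JSON, YAML) plus an md5 checksum manifest. Stages omitted from
#' `config$stages` are loaded from the directory, so a cached run can be
#' resumed or partially recomputed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage outputs and the manifest path.
#' @export
run_all <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("runs", "preproc", "ica", "intra", "inter", "truth"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  ext <- nii_ext(config)
  cfg_plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml"))
  st <- config$stages
  grid <- config$cohort$grid
  dims <- grid$dims
  # ---- simulate ------------------------------------------------------------
  ppath <- file.path(out_dir, "participants.tsv")
  tpath <- file.path(out_dir, "truth", paste0("templates", ext))
  if ("simulate" %in% st) run_stage("simulate", {
    stage_msg("simulate", "generating synthetic cohort")
    cohort <- simulate_cohort(config$cohort)
    write_participants(cohort$participants, ppath)
    write_templates(cohort$truth$network_maps, tpath, grid$voxel_size_mm)
    jsonlite::write_json(
      list(coupling = lapply(cohort$truth$coupling, unclass),
           coupling_lags = lapply(cohort$truth$coupling_lags, unclass),
           noise = cohort$truth$noise, seed = cohort$truth$seed),
      file.path(out_dir, "truth", "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
    for (sid in names(cohort$runs))
      write_bold(cohort$runs[[sid]],
                 file.path(out_dir, "runs", paste0(sid, ext)))
    participants <- cohort$participants
    runs <- cohort$runs
  }) else {
    participants <- read_participants(ppath)
    runs <- NULL
  }
  sids <- participants$participant_id
  # ---- preprocess ----------------------------------------------------------
  pp_file <- function(sid) file.path(out_dir, "preproc", paste0(sid, ext))
  if ("preprocess" %in% st) run_stage("preprocess", {
    stage_msg("preprocess", "discard + band-pass + smooth")
    for (sid in sids) {
      run <- if (!is.null(runs)) runs[[sid]]
             else read_bold(file.path(out_dir, "runs", paste0(sid, ext)))
      pp <- preprocess_run(run, config$n_discard, config$band_hz,
                           config$smooth_fwhm_mm, config$bandpass_method)
      write_bold(pp, pp_file(sid))
    }
  })
  # ---- group ICA -----------------------------------------------------------
  assign_path <- file.path(out_dir, "ica", "assignment.json")
  tc_file <- function(sid) file.path(out_dir, "ica", paste0(sid, "_tc.tsv"))
  netmap_file <- function(net)
    file.path(out_dir, "ica", paste0("subject_maps_", net, ext))
  if ("ica" %in% st) run_stage("ica", {
    stage_msg("ica", sprintf("group ICA, %d components", config$n_components))
    reductions <- lapply(sids, function(sid)
      subject_reduce(read_bold(pp_file(sid)), config$k_subject))
    names(reductions) <- sids
    dec <- group_decompose(reductions, config$n_components,
                           seed = derive_seed(config$seed, "ica"))
    dec <- zscore_maps(dec)
    templates <- read_templates(tpath)
    assignment <- match_components(dec, templates)
    write_map_stack(dec$group_maps, dims, grid$voxel_size_mm,
                    file.path(out_dir, "ica", paste0("group_maps", ext)))
    jsonlite::write_json(assignment$assignment, assign_path, digits = NA)
    for (sid in sids) {
      tc <- dec$subject_timecourses[[sid]]
      colnames(tc) <- paste0("IC", seq_len(ncol(tc)))
      write.table(round(tc, 8), tc_file(sid), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    for (i in seq_len(nrow(assignment$assignment))) {
      net <- assignment$assignment$network[i]
      comp <- assignment$assignment$component[i]
      stack <- do.call(rbind, lapply(dec$subject_maps,
                                     function(m) m[comp, ]))
      write_map_stack(stack, dims, grid$voxel_size_mm, netmap_file(net))
    }
  })
  assignment_df <- as.data.frame(jsonlite::read_json(assign_path,
                                                     simplifyVector = TRUE))
  networks <- assignment_df$network
  # ---- intra-network -------------------------------------------------------
  if ("intra" %in% st) run_stage("intra", {
    stage_msg("intra", "voxelwise group GLM + permutation cluster inference")
    design <- build_design(participants, interest = "group",
                           nuisance = c("gm_volume", "education"))
    for (net in networks) {
      stack <- read_map_stack(netmap_file(net))
      cl <- cluster_inference(stack, design, dims = dims,
                              cluster_forming_p = config$cluster_forming_p,
                              n_perm = config$n_perm,
                              seed = derive_seed(config$seed,
                                                 paste0("intra_", net)))
      write.table(as.data.frame(cl),
                  file.path(out_dir, "intra", paste0(net, "_clusters.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      cr <- corsi_correlation_analysis(stack, participants, dims,
                                       config$cluster_forming_p,
                                       config$n_perm,
                                       seed = derive_seed(config$seed,
                                                          paste0("corsi_", net)))
      for (g in names(cr))
        write.table(as.data.frame(cr[[g]]),
                    file.path(out_dir, "intra",
                              paste0("corsi_", net, "_", g, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  # ---- inter-network -------------------------------------------------------
  if ("inter" %in% st) run_stage("inter", {
    stage_msg("inter", "constrained maximal lagged correlation analysis")
    tcs <- lapply(sids, function(sid) {
      tc <- as.matrix(read.delim(tc_file(sid)))
      sel <- tc[, assignment_df$component, drop = FALSE]
      sel <- scale(sel)   # unit-variance network time courses
      colnames(sel) <- networks
      sel
    })
    names(tcs) <- sids
    inter <- inter_network_analysis(tcs, participants,
                                    max_lag = config$max_lag,
                                    n_rotations = config$n_rotations,
                                    seed = derive_seed(config$seed, "inter"))
    for (nm in c("subject_table", "group_table", "anova_table",
                 "contrast_table"))
      write.table(inter[[nm]],
                  file.path(out_dir, "inter", paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(n_pairs = nrow(inter$anova_table),
           significant_pairs =
             inter$anova_table$pair[inter$anova_table$p_bonferroni < 0.05],
           anova = inter$anova_table),
      file.path(out_dir, "inter", "summary.json"), digits = NA)
    # brain-behaviour: z of each pair vs Corsi in carriers, GM as nuisance
    carriers <- participants$group %in% c("HET", "HOM")
    beh <- lapply(unique(inter$subject_table$pair), function(pr) {
      sub <- inter$subject_table[inter$subject_table$pair == pr, ]
      sub <- sub[match(sids, sub$participant_id), ]
      ok <- carriers & !is.na(participants$corsi)
      if (sum(ok) < 5L) return(NULL)
      bp <- behavior_partial_correlation(sub$z[ok], participants$corsi[ok],
                                         participants$gm_volume[ok])
      data.frame(pair = pr, r = bp$r, p = bp$p, n = bp$n)
    })
    beh <- do.call(rbind, beh)
    write.table(beh, file.path(out_dir, "inter", "behavior.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    # LEDD sensitivity: per-network intra-FC summary in the treated group
    hom <- participants$group == "HOM" & !is.na(participants$ledd)
    if (sum(hom) >= 4L) {
      fc <- vapply(networks, function(net) {
        stack <- read_map_stack(netmap_file(net))
        rowMeans(stack[hom, , drop = FALSE])
      }, numeric(sum(hom)))
      ledd <- ledd_fc_check(fc, participants$ledd[hom])
      write.table(ledd, file.path(out_dir, "inter", "ledd.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  # ---- report --------------------------------------------------------------
  if ("report" %in% st) run_stage("report", {
    stage_msg("report", "writing markdown report")
    read_tsv <- function(p) if (file.exists(p))
      read.delim(p, stringsAsFactors = FALSE) else NULL
    intra <- lapply(networks, function(net)
      read_tsv(file.path(out_dir, "intra", paste0(net, "_clusters.tsv"))))
    names(intra) <- networks
    inter <- list(
      group_table = read_tsv(file.path(out_dir, "inter", "group_table.tsv")),
      anova_table = read_tsv(file.path(out_dir, "inter", "anova_table.tsv")),
      contrast_table = read_tsv(file.path(out_dir, "inter",
                                          "contrast_table.tsv")))
    write_report(list(intra = intra, inter = inter,
                      behavior = read_tsv(file.path(out_dir, "inter",
                                                    "behavior.tsv")),
                      ledd = read_tsv(file.path(out_dir, "inter",
                                                "ledd.tsv"))),
                 file.path(out_dir, "report.md"))
  })
  # ---- checksum manifest ---------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest_md5.tsv"))
  md5 <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(file = files, md5 = unname(md5))
  write.table(manifest, file.path(out_dir, "manifest_md5.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(out_dir = out_dir, manifest = manifest))
}
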