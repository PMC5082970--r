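#' Write a BOLD run as NIfTI-1
#'
#' Stores the 4-D data with the voxel size and TR in `pixdim` (TR in
#' `pixdim[4]`, seconds). Data are written as 64-bit floats, so the
#' round-trip is bit-exact.
#'
#' @param run A [bold_run()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$grid$voxel_size_mm, run$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a BOLD run from NIfTI-1
#'
#' @param path NIfTI file (.nii or .nii.gz), 4-D.
#' @param tr_s Override for the repetition time; by default taken from
#'   `pixdim[4]` of the header (an error if that is not positive).
#' @param mask Optional logical 3-D array; by default voxels with nonzero
#'   temporal variance.
#' @param grid Optional [voxel_grid()]; by default built from the header.
#' @return A [bold_run()].
#' @export
read_bold <- function(path, tr_s = NULL, mask = NULL, grid = NULL) {
  if (!file.exists(path)) stop_named("read_bold: no such file: %s", path)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim(img))
  if (length(dim(a)) != 4L)
    stop_named("read_bold: %s is %d-D, expected a 4-D run", path,
               length(dim(a)))
  if (any(!is.finite(a)))
    stop_named("read_bold: %s contains %d non-finite values", path,
               sum(!is.finite(a)))
  pd <- RNifti::niftiHeader(img)$pixdim[2:5]   # spatial sizes then TR
  if (is.null(tr_s)) {
    raw_tr <- nifti_raw_tr(path)               # header readers sanitize zeros
    if (!is.finite(raw_tr) || raw_tr <= 0)
      stop_named("read_bold: %s has no usable TR in pixdim[4] (%s); pass tr_s",
                 path, format(raw_tr))
    tr_s <- raw_tr
  }
  if (is.null(grid))
    grid <- voxel_grid(dims = dim(a)[1:3], voxel_size_mm = pd[1:3])
  if (is.null(mask)) {
    v <- matrix(a, prod(dim(a)[1:3]), dim(a)[4])
    mask <- array(matrixStats_rowVars(v) > 0, dim(a)[1:3])
  }
  bold_run(a, tr_s, grid, mask)
}

# Repetition time as stored on disk (NIfTI-1 pixdim[4], byte offset 92).
# Read from the raw bytes because image libraries normalize a zero pixdim to
# 1 on load, hiding an absent TR.
nifti_raw_tr <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) return(NA_real_)
  endian <- if (identical(as.integer(readBin(hdr[1:4], "integer",
                                             endian = "little")), 348L))
    "little" else "big"
  readBin(hdr[93:96], "numeric", size = 4L, endian = endian)
}

# Row variances without matrixStats.
matrixStats_rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Write the participants table (BIDS-style TSV)
#' @param participants Data frame as produced by [simulate_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  write.table(participants, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a participants table
#'
#' Requires the columns `participant_id`, `group`, `gene`, `age`, `sex`,
#' `education`, `gm_volume`, `corsi`, `moca`, `ledd`. Blank cells become
#' missing values. Unknown group labels or duplicated ids are errors that
#' list the offending rows.
#'
#' @param path TSV file.
#' @return Validated data frame.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop_named("read_participants: no such file: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  req <- c("participant_id", "group", "gene", "age", "sex", "education",
           "gm_volume", "corsi", "moca", "ledd")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_named("read_participants: missing columns: %s",
               paste(missing_cols, collapse = ", "))
  bad <- which(!df$group %in% c("HC", "HET", "HOM"))
  if (length(bad))
    stop_named("read_participants: unknown group label in rows %s (%s)",
               paste(bad, collapse = ", "),
               paste(unique(df$group[bad]), collapse = ", "))
  dup <- which(duplicated(df$participant_id))
  if (length(dup))
    stop_named("read_participants: duplicated participant_id in rows %s (%s)",
               paste(dup, collapse = ", "),
               paste(unique(df$participant_id[dup]), collapse = ", "))
  for (v in c("age", "education", "gm_volume", "corsi", "moca", "ledd"))
    df[[v]] <- as.numeric(df[[v]])
  df
}

#' Write network template maps as one 4-D NIfTI plus a JSON sidecar
#' @param maps Named list of 3-D arrays (e.g. [make_network_maps()] output).
#' @param path Output `.nii`/`.nii.gz` path; the sidecar replaces the
#'   extension with `.json`.
#' @param voxel_size_mm Voxel size recorded in the header.
#' @return `path`, invisibly.
#' @export
write_templates <- function(maps, path, voxel_size_mm = c(3, 3, 3)) {
  a <- array(unlist(maps, use.names = FALSE),
             c(dim(maps[[1]]), length(maps)))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(voxel_size_mm, 1)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(networks = names(maps)), side, auto_unbox = FALSE)
  invisible(path)
}

#' Read network templates written by [write_templates()]
#' @param path The `.nii`/`.nii.gz` path.
#' @return Named list of 3-D arrays.
#' @export
read_templates <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  nm <- if (file.exists(side)) unlist(jsonlite::read_json(side)$networks)
        else paste0("N", seq_len(dim(a)[4]))
  out <- lapply(seq_len(dim(a)[4]), function(i) a[, , , i])
  names(out) <- nm
  out
}

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "f")

md_table <- function(df, digits = 3) {
  if (nrow(df) == 0L) return(character(0))
  cells <- vapply(seq_along(df), function(j) {
    col <- df[[j]]
    if (is.numeric(col) && !is.integer(col)) fmt_num(col, digits)
    else as.character(col)
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write a markdown analysis report
#'
#' Renders the cluster tables of the intra-network stage, the pair x group
#' table and ANOVA/contrast tables of the inter-network stage, and any
#' behaviour correlations, as plain markdown. Sections with no significant
#' clusters say so explicitly.
#'
#' @param results List with any of: `intra` (named list of `cluster_result`
#'   per network), `corsi` (per network, per group cluster tables), `inter`
#'   (an [inter_network_analysis()] result), `behavior` (data frame),
#'   `ledd` (data frame).
#' @param path Output `.md` path.
#' @param title Report title.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, title = "Network connectivity report") {
  lines <- c(paste("#", title), "")
  if (!is.null(results$intra)) {
    lines <- c(lines, "## Intra-network group comparisons", "")
    for (net in names(results$intra)) {
      tab <- results$intra[[net]]
      lines <- c(lines, paste("###", net), "")
      lines <- c(lines,
                 if (is.null(tab) || nrow(tab) == 0L) "No significant clusters."
                 else md_table(as.data.frame(tab)), "")
    }
  }
  if (!is.null(results$corsi)) {
    lines <- c(lines, "## Corsi covariate clusters", "")
    for (net in names(results$corsi)) for (g in names(results$corsi[[net]])) {
      tab <- results$corsi[[net]][[g]]
      lines <- c(lines, paste0("### ", net, ", ", g), "")
      lines <- c(lines,
                 if (is.null(tab) || nrow(tab) == 0L) "No significant clusters."
                 else md_table(as.data.frame(tab)), "")
    }
  }
  if (!is.null(results$inter)) {
    lines <- c(lines, "## Inter-network lagged correlations", "",
               md_table(results$inter$group_table), "",
               "## Inter-network group ANOVA", "",
               md_table(results$inter$anova_table, digits = 4), "",
               "## Pairwise contrasts", "",
               md_table(results$inter$contrast_table), "")
  }
  if (!is.null(results$behavior))
    lines <- c(lines, "## Brain-behaviour correlations", "",
               md_table(results$behavior), "")
  if (!is.null(results$ledd)) {
    lines <- c(lines, "## LEDD sensitivity analysis", "")
    lines <- c(lines,
               if (is.null(results$ledd) || nrow(results$ledd) == 0L)
                 "Not computed."
               else md_table(results$ledd), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a run manifest
#'
#' A manifest is a TSV with columns `participant_id` and `path` (one 4-D
#' NIfTI per subject). Paths are checked to exist and ids to be unique and
#' present in the participants table when one is given.
#'
#' @param path Manifest TSV.
#' @param participants Optional participants data frame for id validation.
#' @return Data frame with `participant_id` and `path`.
#' @export
read_manifest <- function(path, participants = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("participant_id", "path") %in% names(df)))
    stop_named("read_manifest: need columns participant_id, path")
  gone <- !file.exists(df$path)
  if (any(gone))
    stop_named("read_manifest: missing files: %s",
               paste(df$path[gone], collapse = ", "))
  if (anyDuplicated(df$participant_id))
    stop_named("read_manifest: duplicated participant_id")
  if (!is.null(participants)) {
    unknown <- setdiff(df$participant_id, participants$participant_id)
    if (length(unknown))
      stop_named("read_manifest: ids not in participants table: %s",
                 paste(unknown, collapse = ", "))
  }
  df
}
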