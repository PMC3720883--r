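#' Region parcellation and cohort table I/O
#'
#' The pipeline's node set is a fixed, ordered parcellation of the brain into
#' anatomical regions (the shipped table is the 90-region AAL parcellation of
#' Tzourio-Mazoyer and colleagues). Region order in this table is the single
#' source of truth: every matrix produced downstream is indexed in atlas order.
#'
#' @name atlas_io
NULL

.lobe_levels <- c("Frontal", "Temporal", "Occipital", "Limbic", "Parietal",
                  "Central", "Subcortical")
.group_levels <- c("NC", "MCI", "AD")

#' Load and validate a region atlas
#'
#' Reads a regions CSV (columns `abbreviation`, `name`, `hemisphere`, `lobe`)
#' and validates it: unique abbreviations, known hemisphere/lobe tokens, and a
#' complete homologous pairing (every left region has exactly one right
#' counterpart sharing its abbreviation stem). Region order is taken from file
#' order and preserved everywhere downstream.
#'
#' @param path Path to a regions CSV, or the builtin token `"aal90"` (default)
#'   for the shipped 90-region AAL table.
#' @param n_expected If non-`NULL`, the loader errors unless the table has
#'   exactly this many regions. Defaults to 90 for the builtin table.
#' @return A `region_atlas` object: list with `regions` (data.frame with
#'   0-based `index`, `abbreviation`, `name`, `hemisphere`, `lobe`, `stem`),
#'   `n_regions`, and `pairs` (data.frame of homologous L/R index pairs).
#' @examples
#' atlas <- load_atlas()
#' atlas$n_regions  # 90
#' @export
load_atlas <- function(path = "aal90", n_expected = NULL) {
  if (identical(path, "aal90")) {
    path <- system.file("extdata", "aal90_regions.csv", package = "metabnet",
                        mustWork = TRUE)
    if (is.null(n_expected)) n_expected <- 90L
  }
  if (!file.exists(path)) stop("atlas file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("abbreviation", "name", "hemisphere", "lobe")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("atlas file is missing column(s): ", paste(miss, collapse = ", "))

  dup <- df$abbreviation[duplicated(df$abbreviation)]
  if (length(dup) > 0)
    stop("duplicate region abbreviation(s) in atlas: ",
         paste(unique(dup), collapse = ", "))
  bad_hemi <- which(!df$hemisphere %in% c("L", "R"))
  if (length(bad_hemi) > 0)
    stop("unknown hemisphere token at row(s) ",
         paste(bad_hemi, collapse = ", "), " (expected L or R)")
  bad_lobe <- which(!df$lobe %in% .lobe_levels)
  if (length(bad_lobe) > 0)
    stop("unknown lobe token at row(s) ", paste(bad_lobe, collapse = ", "),
         ": ", paste(unique(df$lobe[bad_lobe]), collapse = ", "))
  if (!is.null(n_expected) && nrow(df) != n_expected)
    stop("atlas has ", nrow(df), " regions, expected ", n_expected)

  df$index <- seq_len(nrow(df)) - 1L
  df$stem <- sub("\\.[LR]$", "", df$abbreviation)

  # homologous pairing must be a bijection between hemispheres
  pairs <- lapply(unique(df$stem), function(s) {
    rows <- df[df$stem == s, ]
    if (nrow(rows) != 2 || !setequal(rows$hemisphere, c("L", "R")))
      stop("homologous pairing broken for stem '", s,
           "': need exactly one L and one R region")
    data.frame(stem = s,
               left = rows$index[rows$hemisphere == "L"],
               right = rows$index[rows$hemisphere == "R"])
  })
  pairs <- do.call(rbind, pairs)

  structure(list(regions = df[, c("index", "abbreviation", "name",
                                  "hemisphere", "lobe", "stem")],
                 n_regions = nrow(df),
                 pairs = pairs),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas:", x$n_regions, "regions,",
      nrow(x$pairs), "homologous pairs\n")
  print(table(x$regions$lobe))
  invisible(x)
}

#' Number of unordered region pairs (the edge universe)
#'
#' @param atlas A `region_atlas`, or an integer region count.
#' @return `N * (N - 1) / 2`; 4005 for the 90-region atlas.
#' @export
n_region_pairs <- function(atlas) {
  n <- if (inherits(atlas, "region_atlas")) atlas$n_regions else as.integer(atlas)
  n * (n - 1) / 2
}

#' Map region abbreviations to 1-based atlas positions
#'
#' @param atlas A `region_atlas`.
#' @param abbreviations Character vector of region abbreviations.
#' @return Integer vector of positions into atlas order.
#' @export
region_index <- function(atlas, abbreviations) {
  idx <- match(abbreviations, atlas$regions$abbreviation)
  if (anyNA(idx))
    stop("unknown region abbreviation(s): ",
         paste(abbreviations[is.na(idx)], collapse = ", "))
  idx
}

#' Load a cohort table
#'
#' Reads a cohort CSV/TSV with one row per subject: `subject_id`, `group`
#' (NC/MCI/AD), `age` (years), `sex` (M/F), `education` (years),
#' `ref_brainstem` (reference-region mean uptake), and per-region columns
#' `cmrgl_<abbr>` and `vol_<abbr>` for every atlas abbreviation. Region
#' columns are re-ordered to atlas order regardless of file order.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from extension).
#' @param atlas A `region_atlas`.
#' @return A `cohort_table`: list with `subjects` (data.frame of metadata),
#'   `cmrgl` and `volumes` (subjects x N matrices in atlas order),
#'   `reference` (per-subject reference uptake), and `atlas`.
#' @export
load_cohort <- function(path, atlas) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("subject_id", "group", "age", "sex", "education", "ref_brainstem")
  miss <- setdiff(meta, names(df))
  if (length(miss) > 0)
    stop("cohort file is missing metadata column(s): ",
         paste(miss, collapse = ", "))
  abbr <- atlas$regions$abbreviation
  cm_cols <- paste0("cmrgl_", abbr)
  vol_cols <- paste0("vol_", abbr)
  miss <- setdiff(c(cm_cols, vol_cols), names(df))
  if (length(miss) > 0)
    stop("cohort file is missing region column(s): ",
         paste(miss, collapse = ", "))
  cohort_table(subject_id = df$subject_id,
               group = df$group,
               age = df$age, sex = df$sex, education = df$education,
               cmrgl = as.matrix(df[, cm_cols]),
               volumes = as.matrix(df[, vol_cols]),
               reference = df$ref_brainstem,
               atlas = atlas)
}

#' Construct and validate a cohort table
#'
#' @param subject_id Character vector of subject identifiers.
#' @param group Character vector of group labels (`NC`, `MCI`, `AD`).
#' @param age,education Numeric vectors (years).
#' @param sex Character vector (`M`/`F`).
#' @param cmrgl,volumes Numeric subjects x N matrices in atlas order.
#' @param reference Per-subject reference-region mean uptake (must be > 0).
#' @param atlas A `region_atlas`.
#' @return A validated `cohort_table`.
#' @export
cohort_table <- function(subject_id, group, age, sex, education,
                         cmrgl, volumes, reference, atlas) {
  n <- length(subject_id)
  cmrgl <- as.matrix(cmrgl); volumes <- as.matrix(volumes)
  if (!all(dim(cmrgl) == c(n, atlas$n_regions)) ||
      !all(dim(volumes) == c(n, atlas$n_regions)))
    stop("cmrgl and volumes must both be ", n, " x ", atlas$n_regions)
  bad <- which(!group %in% .group_levels)
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(unique(group[bad]), collapse = ", "))
  if (!all(sex %in% c("M", "F"))) stop("sex must be coded M/F")
  vals <- list(age = age, education = education, reference = reference,
               cmrgl = cmrgl, volumes = volumes)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v)) stop("non-numeric values in ", nm)
    if (anyNA(v)) stop("missing values in ", nm, "; loader rejects rows with gaps")
  }
  if (any(reference <= 0))
    stop("non-positive reference value for subject(s): ",
         paste(subject_id[reference <= 0], collapse = ", "))
  colnames(cmrgl) <- colnames(volumes) <- atlas$regions$abbreviation
  structure(list(subjects = data.frame(subject_id = subject_id, group = group,
                                       age = age, sex = sex,
                                       education = education,
                                       stringsAsFactors = FALSE),
                 cmrgl = cmrgl, volumes = volumes,
                 reference = reference, atlas = atlas),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$subjects), "subjects x",
      x$atlas$n_regions, "regions\n")
  print(table(x$subjects$group))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `cohort_table`.
#' @export
n_subjects <- function(cohort) nrow(cohort$subjects)

#' Restrict a cohort to one group
#' @param cohort A `cohort_table`.
#' @param group A group label.
#' @return A `cohort_table` containing only that group's subjects.
#' @export
subset_group <- function(cohort, group) {
  keep <- cohort$subjects$group == group
  if (!any(keep)) stop("group not present in cohort: ", group)
  cohort_table(cohort$subjects$subject_id[keep], cohort$subjects$group[keep],
               cohort$subjects$age[keep], cohort$subjects$sex[keep],
               cohort$subjects$education[keep],
               cohort$cmrgl[keep, , drop = FALSE],
               cohort$volumes[keep, , drop = FALSE],
               cohort$reference[keep], cohort$atlas)
}

#' Write a cohort table to CSV/TSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x, f), atlas)` equals
#' `x` field by field (within float round-trip precision).
#'
#' @param cohort A `cohort_table`.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  abbr <- cohort$atlas$regions$abbreviation
  cm <- as.data.frame(cohort$cmrgl); names(cm) <- paste0("cmrgl_", abbr)
  vol <- as.data.frame(cohort$volumes); names(vol) <- paste0("vol_", abbr)
  df <- cbind(cohort$subjects,
              data.frame(ref_brainstem = cohort$reference), cm, vol)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a binary graph as an edge-list TSV
#'
#' Edges are written as `region_a`, `region_b`, `weight` with `region_a`
#' before `region_b` in atlas order.
#'
#' @param adjacency Symmetric 0/1 (or weighted) matrix in atlas order.
#' @param atlas A `region_atlas`.
#' @param path Output TSV path.
#' @param weights Optional matrix of edge weights to report (defaults to the
#'   adjacency values).
#' @export
write_edge_list <- function(adjacency, atlas, path, weights = adjacency) {
  idx <- which(upper.tri(adjacency) & adjacency != 0, arr.ind = TRUE)
  df <- data.frame(region_a = atlas$regions$abbreviation[idx[, 1]],
                   region_b = atlas$regions$abbreviation[idx[, 2]],
                   weight = weights[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
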