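# Manifest handling: the canonical CSV interchange for radiograph studies.
#
# A manifest is a data.frame with one row per image and columns
# image_id, path, patient_id, study_id, region, label, split, carrying the
# ordered region set as an attribute. Grouping rows by study_id yields
# studies: one examination of one patient/region, with >= 1 views sharing a
# single normal/abnormal label.

#' The seven standard upper-extremity regions
#' @export
UPPER_EXTREMITY_REGIONS <- c("Elbow", "Finger", "Forearm", "Hand",
                             "Humerus", "Shoulder", "Wrist")

MANIFEST_COLUMNS <- c("image_id", "path", "patient_id", "study_id",
                      "region", "label", "split")
SPLITS <- c("train", "validation", "test")

#' Construct and validate a manifest
#'
#' @param records data.frame with columns `image_id`, `path`, `patient_id`,
#'   `study_id`, `region`, `label` (0 = normal, 1 = abnormal) and `split`
#'   (`train`, `validation` or `test`).
#' @param region_set Ordered character vector of permitted regions.
#' @return The validated data.frame with class `radcal_manifest` and the
#'   region set attached as attribute `region_set`.
#' @export
as_manifest <- function(records, region_set = UPPER_EXTREMITY_REGIONS) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  records <- as.data.frame(records)[MANIFEST_COLUMNS]
  for (col in c("image_id", "path", "patient_id", "study_id", "region", "split")) {
    records[[col]] <- as.character(records[[col]])
  }
  bad <- which(!(as.character(records$label) %in% c("0", "1")))
  if (length(bad)) {
    stop(sprintf("label must be 0 or 1; offending row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  records$label <- as.integer(as.character(records$label))
  dup <- records$image_id[duplicated(records$image_id)]
  if (length(dup)) {
    stop(sprintf("duplicate image_id(s): %s",
                 paste(unique(utils::head(dup, 5)), collapse = ", ")),
         call. = FALSE)
  }
  bad_region <- setdiff(unique(records$region), region_set)
  if (length(bad_region)) {
    stop(sprintf("region(s) outside the configured region set: %s",
                 paste(bad_region, collapse = ", ")), call. = FALSE)
  }
  bad_split <- setdiff(unique(records$split), SPLITS)
  if (length(bad_split)) {
    stop(sprintf("split must be one of %s; found: %s",
                 paste(SPLITS, collapse = "/"),
                 paste(bad_split, collapse = ", ")), call. = FALSE)
  }
  # study consistency: all views of a study share region, label, patient
  for (col in c("region", "label", "patient_id")) {
    n_distinct <- tapply(records[[col]], records$study_id,
                         function(v) length(unique(v)))
    bad_study <- names(n_distinct)[n_distinct > 1]
    if (length(bad_study)) {
      stop(sprintf("study(ies) with inconsistent %s: %s", col,
                   paste(utils::head(bad_study, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(records, region_set = region_set,
            class = c("radcal_manifest", "data.frame"))
}

#' Load a manifest from CSV
#'
#' @param path CSV file with header
#'   `image_id,path,patient_id,study_id,region,label,split`.
#' @param region_set Ordered character vector of permitted regions.
#' @return A `radcal_manifest` (see [as_manifest()]).
#' @export
load_manifest <- function(path, region_set = UPPER_EXTREMITY_REGIONS) {
  assert_that(file.exists(path), sprintf("manifest file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#")
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("manifest %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(df$label %in% c("0", "1")))
  if (length(bad)) {
    stop(sprintf("label must be 0 or 1; offending row(s) in %s: %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  as_manifest(df, region_set = region_set)
}

#' Write a manifest to CSV
#'
#' @param manifest A `radcal_manifest`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[MANIFEST_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count images by split, region and class
#'
#' @param manifest A `radcal_manifest`.
#' @param split Optional split filter.
#' @return data.frame with columns `split`, `region`, `abnormal`, `normal`.
#' @export
manifest_counts <- function(manifest, split = NULL) {
  df <- as.data.frame(manifest)
  if (!is.null(split)) df <- df[df$split %in% split, , drop = FALSE]
  if (!nrow(df)) {
    return(data.frame(split = character(), region = character(),
                      abnormal = integer(), normal = integer()))
  }
  agg <- stats::aggregate(cbind(abnormal = df$label == 1,
                                normal = df$label == 0),
                          by = list(split = df$split, region = df$region),
                          FUN = sum)
  agg$abnormal <- as.integer(agg$abnormal)
  agg$normal <- as.integer(agg$normal)
  agg[order(agg$split, agg$region), , drop = FALSE]
}

#' Split a manifest into studies
#'
#' @param manifest A `radcal_manifest`.
#' @return Named list (by `study_id`) of data.frames, one per study, each with
#'   `>= 1` view rows sharing region, label and patient.
#' @export
manifest_studies <- function(manifest) {
  df <- as.data.frame(manifest)
  split(df, df$study_id)
}

#' Import a MURA-style directory tree
#'
#' Walks a directory tree laid out as
#' `<split>/XR_<REGION>/patient<id>/study<k>_<positive|negative>/*.png`,
#' the layout used by the public MURA musculoskeletal radiograph dataset.
#' The label is 1 iff the study folder suffix is `positive`.
#'
#' @param root Root directory.
#' @param region_set Permitted regions; folder names are matched
#'   case-insensitively against `XR_<REGION>`.
#' @param on_unknown_region `"error"` or `"skip"` (skips with a warning).
#' @return A `radcal_manifest`.
#' @export
scan_mura_tree <- function(root, region_set = UPPER_EXTREMITY_REGIONS,
                           on_unknown_region = c("error", "skip")) {
  on_unknown_region <- match.arg(on_unknown_region)
  assert_that(dir.exists(root), sprintf("directory not found: %s", root))
  files <- list.files(root, pattern = "\\.png$", recursive = TRUE,
                      full.names = FALSE)
  rows <- list()
  for (f in files) {
    parts <- strsplit(f, "/", fixed = TRUE)[[1]]
    if (length(parts) < 4L) next
    # layout: [split /] XR_REGION / patientNNN / studyK_label / image.png
    study_dir <- parts[length(parts) - 1L]
    patient_dir <- parts[length(parts) - 2L]
    region_dir <- parts[length(parts) - 3L]
    split_dir <- if (length(parts) >= 5L) parts[length(parts) - 4L] else "train"
    if (!grepl("^XR_", region_dir, ignore.case = TRUE)) next
    region_raw <- sub("^XR_", "", region_dir, ignore.case = TRUE)
    region <- region_set[match(tolower(region_raw), tolower(region_set))]
    if (is.na(region)) {
      msg <- sprintf("unknown region folder: %s", region_dir)
      if (on_unknown_region == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      next
    }
    m <- regmatches(study_dir,
                    regexec("^study([0-9]+)_(positive|negative)$", study_dir))[[1]]
    if (length(m) != 3L) {
      warning(sprintf("study folder without positive/negative suffix skipped: %s",
                      study_dir), call. = FALSE)
      next
    }
    split_name <- switch(tolower(split_dir),
                         train = "train", valid = "validation",
                         validation = "validation", test = "test", "train")
    study_id <- paste0(patient_dir, "_study", m[2])
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = paste0(study_id, "_", sub("\\.png$", "", basename(f))),
      path = file.path(root, f),
      patient_id = patient_dir,
      study_id = study_id,
      region = region,
      label = if (m[3] == "positive") 1L else 0L,
      split = split_name,
      stringsAsFactors = FALSE
    )
  }
  assert_that(length(rows) > 0, "no radiograph images found under the tree")
  as_manifest(do.call(rbind, rows), region_set = region_set)
}
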