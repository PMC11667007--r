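VALID_SPLITS <- c("train", "val", "test_true", "test_apparent", "external")

#' Load a cohort manifest
#'
#' The manifest is a CSV with header columns `case_id,volume,mask,split,
#' corrupted,quality`. Unknown extra columns are preserved but ignored by the
#' package. Split labels must come from
#' `train, val, test_true, test_apparent, external`.
#'
#' @param path path to a manifest CSV.
#' @param check_paths if `TRUE`, every `volume`/`mask` path must resolve
#'   (relative paths are resolved against the manifest's directory).
#' @return data.frame of class `seg_manifest`, with per-split counts in
#'   attribute `"split_counts"`.
#' @export
load_cohort <- function(path, check_paths = FALSE) {
  if (!file.exists(path)) stop("missing manifest: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "volume", "mask", "split", "corrupted", "quality")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("manifest missing required columns: ", paste(missing_cols, collapse = ", "))
  df$case_id <- as.character(df$case_id)
  if (anyDuplicated(df$case_id))
    stop("duplicate case_id in manifest: ",
         paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", "))
  bad <- setdiff(unique(df$split), VALID_SPLITS)
  if (length(bad))
    stop("unknown split label(s): ", paste(bad, collapse = ", "))
  df$corrupted <- as.logical(df$corrupted)
  df$quality <- suppressWarnings(as.integer(df$quality))
  if (check_paths) {
    base <- dirname(path)
    resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    paths <- c(resolve(df$volume), resolve(df$mask))
    absent <- paths[!file.exists(paths)]
    if (length(absent)) stop("unresolvable paths: ", paste(absent, collapse = ", "))
  }
  counts <- table(factor(df$split, levels = VALID_SPLITS))
  structure(df, class = c("seg_manifest", "data.frame"),
            split_counts = as.integer(counts)[counts > 0] |>
              stats::setNames(names(counts)[counts > 0]))
}

#' Save a cohort manifest
#'
#' @param manifest a data.frame with the manifest columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a manifest data.frame from a list of cases
#'
#' @param cases list of `seg_case` objects.
#' @param dir directory the volume/mask files live in (paths are recorded as
#'   `<dir>/<case_id>_{vol,mask}.nii.gz`); use `""` for placeholder paths.
#' @param splits character vector of split labels, one per case.
#' @return data.frame with the standard manifest columns.
#' @export
cases_manifest <- function(cases, splits, dir = "") {
  ids <- vapply(cases, function(cc) cc$case_id, character(1))
  prefix <- function(f) if (nzchar(dir)) file.path(dir, f) else f
  data.frame(
    case_id = ids,
    volume = prefix(paste0(ids, "_vol.nii.gz")),
    mask = prefix(paste0(ids, "_mask.nii.gz")),
    split = splits,
    corrupted = vapply(cases, function(cc) isTRUE(cc$corrupted), logical(1)),
    side = vapply(cases, function(cc) cc$side %||% NA_character_, character(1)),
    quality = vapply(cases, function(cc) {
      q <- cc$quality_score
      if (is.null(q)) NA_integer_ else as.integer(q)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
}
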