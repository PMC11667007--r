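#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks agree perfectly (DSC 1, by
#' convention, documented); empty-vs-nonempty is 0.
#'
#' @param a,b [seg_mask()] objects on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  stopifnot(inherits(a, "seg_mask"), inherits(b, "seg_mask"))
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("shape mismatch between masks")
  sa <- sum(a$voxels); sb <- sum(b$voxels)
  if (sa + sb == 0) return(1)
  2 * sum(a$voxels & b$voxels) / (sa + sb)
}

#' Surface voxels of a binary mask
#'
#' A foreground voxel belongs to the surface iff at least one of its six
#' face-neighbours is background; the grid boundary counts as background.
#'
#' @param mask a nonempty [seg_mask()].
#' @return integer matrix, one row per surface voxel (columns = grid indices).
#' @export
surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  arr <- mask$voxels
  if (sum(arr) == 0) stop("empty mask has no surface")
  d <- dim(arr)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core == 1L & !nb, arr.ind = TRUE)
}

# directed nearest-surface distances (mm) from each row of `from` to the set
# `to`, voxel-centre to voxel-centre, chunked vectorized cross-distance
directed_surface_dists <- function(from, to, spacing) {
  A <- sweep(from, 2, spacing, `*`)
  B <- sweep(to, 2, spacing, `*`)
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  chunk <- max(1L, floor(2e6 / nrow(B)))
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ai <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), nb2, `+`) - 2 * Ai %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Mean surface distance between two masks (mm)
#'
#' Symmetric average of the two directed mean nearest-surface-voxel
#' distances, measured between surface-voxel centres scaled by spacing.
#'
#' @param a,b nonempty [seg_mask()] objects on the same grid.
#' @param spacing voxel spacing in mm; defaults to the masks' spacing.
#' @return MSD in mm.
#' @export
msd <- function(a, b, spacing = a$spacing) {
  stopifnot(inherits(a, "seg_mask"), inherits(b, "seg_mask"))
  if (!identical(dim(a$voxels), dim(b$voxels))) stop("shape mismatch")
  sa <- surface_voxels(a); sb <- surface_voxels(b)
  dab <- directed_surface_dists(sa, sb, spacing)
  dba <- directed_surface_dists(sb, sa, spacing)
  (mean(dab) + mean(dba)) / 2
}

#' Maximum Hausdorff distance between two masks (mm)
#'
#' Max over both directions of the maximum nearest-surface distance; always
#' `>=` the mean surface distance for the same pair.
#'
#' @inheritParams msd
#' @return HD in mm.
#' @export
hausdorff <- function(a, b, spacing = a$spacing) {
  stopifnot(inherits(a, "seg_mask"), inherits(b, "seg_mask"))
  if (!identical(dim(a$voxels), dim(b$voxels))) stop("shape mismatch")
  sa <- surface_voxels(a); sb <- surface_voxels(b)
  max(max(directed_surface_dists(sa, sb, spacing)),
      max(directed_surface_dists(sb, sa, spacing)))
}

#' Curation efficacy: curated minus non-curated DSC
#'
#' @param curated,noncurated named numeric vectors of per-case DSC, keyed by
#'   case id (order-independent; joined on names).
#' @return list with `per_case` (named differences, curated order) and
#'   `median`.
#' @export
curation_efficacy <- function(curated, noncurated) {
  if (is.null(names(curated)) || is.null(names(noncurated)))
    stop("inputs must be named by case id")
  if (!setequal(names(curated), names(noncurated)))
    stop("case id mismatch between curated and non-curated results")
  delta <- curated - noncurated[names(curated)]
  list(per_case = delta, median = stats::median(delta))
}

#' Evaluate a segmenter over a set of cases
#'
#' @param segmenter a trained segmenter (see [predict_mask()]), or the string
#'   `"oracle"` to score each reference against itself.
#' @param cases list of `seg_case` objects with reference masks.
#' @param with_distances if `TRUE` also compute MSD and HD (skipped when the
#'   prediction is empty, reported as `NA`).
#' @return data.frame of class `metrics_report` with one row per case
#'   (`case_id`, `dsc`, and optionally `msd_mm`, `hd_mm`); aggregates
#'   (median, IQR) in attribute `"aggregates"`.
#' @export
evaluate_cohort <- function(segmenter, cases, with_distances = FALSE) {
  rows <- lapply(cases, function(cc) {
    pred <- if (identical(segmenter, "oracle")) cc$mask
            else predict_mask(segmenter, cc$volume)
    row <- data.frame(case_id = cc$case_id, dsc = dsc(pred, cc$mask))
    if (with_distances) {
      ok <- sum(pred$voxels) > 0 && sum(cc$mask$voxels) > 0
      row$msd_mm <- if (ok) msd(pred, cc$mask) else NA_real_
      row$hd_mm <- if (ok) hausdorff(pred, cc$mask) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  agg <- lapply(setdiff(names(out), "case_id"), function(m) {
    q <- stats::quantile(out[[m]], c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(metric = m, median = q[2], q1 = q[1], q3 = q[3])
  })
  structure(out, class = c("metrics_report", "data.frame"),
            aggregates = do.call(rbind, agg))
}
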