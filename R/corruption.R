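#' Corruption specification
#'
#' Parameters of the cohort-level segmentation-corruption simulator:
#' systematic corruption laterally dilates the reference mask, random
#' corruption dilates or erodes (p = 1/2 each) along a uniformly sampled
#' signed Cartesian axis (p = 1/6 per direction). Erosion magnitudes are
#' shrunk by `erosion_factor` to compensate for the size sensitivity of
#' overlap agreement.
#'
#' @param mode `"systematic_lateral"` or `"random"`.
#' @param magnitude dilation magnitude in voxels (default 10, i.e. 1.0 cm at
#'   1 mm spacing).
#' @param erosion_factor erosion magnitudes are
#'   `round(erosion_factor * magnitude)` (default 0.8, so 8 for magnitude 10).
#' @param fraction fraction of training cases corrupted, in `[0, 1]`.
#' @param seed integer seed for case selection and random-mode sampling.
#' @return list of class `corruption_spec`.
#' @export
corruption_spec <- function(mode = c("systematic_lateral", "random"),
                            magnitude = 10L, erosion_factor = 0.8,
                            fraction = 0.3, seed = 1L) {
  mode <- match.arg(mode)
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (erosion_factor <= 0 || erosion_factor > 1)
    stop("erosion_factor must be in (0, 1]")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  structure(list(mode = mode, magnitude = as.integer(magnitude),
                 erosion_factor = erosion_factor, fraction = fraction,
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

# The six signed Cartesian unit steps, as (axis, sign) pairs.
CARDINAL_DIRECTIONS <- list(c(1, 1), c(1, -1), c(2, 1), c(2, -1), c(3, 1), c(3, -1))

check_direction <- function(direction) {
  if (length(direction) != 2L || !direction[1] %in% 1:3 ||
      !direction[2] %in% c(-1, 1))
    stop("direction must be c(axis in 1:3, sign in {-1, 1})")
  as.integer(direction)
}

# shift a 3D array k voxels along `axis` in direction `sgn`, zero fill
shift_arr <- function(arr, axis, sgn, k) {
  if (k == 0) return(arr)
  d <- dim(arr)
  n <- d[axis]
  if (k >= n) return(array(0L, dim = d))
  out <- array(0L, dim = d)
  src <- 1:(n - k); dst <- (k + 1):n
  if (sgn < 0) { tmp <- src; src <- dst; dst <- tmp }
  idx_src <- rep(list(quote(expr = )), 3); idx_dst <- idx_src
  idx_src[[axis]] <- src; idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(do.call(`[`, c(list(arr), idx_src)))))
  out
}

#' Directionally dilate a binary mask
#'
#' Dilation with a line structuring element anchored at the origin and
#' extending `m` voxels in `direction`: the result is the union of the mask
#' shifted by `k * direction` for `k = 0..m`, always a superset of the input.
#'
#' @param mask a [seg_mask()].
#' @param direction `c(axis, sign)` with axis in 1:3 and sign +1/-1.
#' @param m magnitude in voxels (>= 0).
#' @param clip if `FALSE` (default, the corruption semantics) dilating a
#'   mask whose foreground lies within `m` voxels of the target face is an
#'   error; if `TRUE` the dilation is silently clipped at the grid boundary
#'   (the plain morphological semantics).
#' @return the dilated [seg_mask()].
#' @export
directional_dilate <- function(mask, direction, m, clip = FALSE) {
  stopifnot(inherits(mask, "seg_mask"), m >= 0)
  direction <- check_direction(direction)
  m <- as.integer(m)
  if (m == 0L) return(mask)
  arr <- mask$voxels
  d <- dim(arr)
  axis <- direction[1]; sgn <- direction[2]
  if (!clip) {
    # boundary check: no foreground within m voxels of the target face
    n <- d[axis]
    idx <- rep(list(quote(expr = )), 3)
    idx[[axis]] <- if (sgn > 0) (max(n - m + 1, 1)):n else 1:(min(m, n))
    if (m >= n || sum(do.call(`[`, c(list(arr), idx))) > 0)
      stop("dilation would cross the grid boundary")
  }
  out <- arr
  for (k in seq_len(m)) out <- out | shift_arr(arr, axis, sgn, k)
  seg_mask(array(as.integer(out), dim = d), mask$spacing)
}

#' Directionally erode a binary mask
#'
#' Keeps voxel v iff `v + k * direction` is foreground for all `k = 0..m`
#' (grid exterior counts as background); always a subset of the input, and
#' the complement-dual of [directional_dilate()] in the opposite direction
#' (exactly so when the grid is embedded in a background ring, since the
#' exterior is background for the mask but foreground for its complement).
#'
#' @inheritParams directional_dilate
#' @return the eroded [seg_mask()] (possibly empty).
#' @export
directional_erode <- function(mask, direction, m) {
  stopifnot(inherits(mask, "seg_mask"), m >= 0)
  direction <- check_direction(direction)
  m <- as.integer(m)
  if (m == 0L) return(mask)
  arr <- mask$voxels
  axis <- direction[1]; sgn <- direction[2]
  out <- arr
  for (k in seq_len(m)) out <- out & shift_arr(arr, axis, -sgn, k)
  seg_mask(array(as.integer(out), dim = dim(arr)), mask$spacing)
}

new_corruption_record <- function(op, direction, magnitude, agreement) {
  structure(list(op = op, direction = check_direction(direction),
                 magnitude = as.integer(magnitude),
                 agreement = agreement),
            class = "corruption_record")
}

attach_corruption <- function(case, new_mask, op, direction, magnitude) {
  agreement <- dsc(case$mask, new_mask)
  case$mask <- new_mask
  case$corrupted <- TRUE
  case$corruption <- new_corruption_record(op, direction, magnitude, agreement)
  case$quality_score <- quality_from_record(case$corruption)$score
  case
}

#' Apply the systematic lateral corruption to a case
#'
#' Lateral means along axis 1, signed away from the mid-sagittal plane:
#' `+axis1` for a right-sided organ, `-axis1` for a left-sided one. A case
#' without a recorded side gets it inferred from the mask centroid relative
#' to the grid midline (an exactly-centred mask is an error). The corrupted
#' case carries a `corruption_record` with the agreement DSC against the
#' clean mask and a synthetic rubric quality score.
#'
#' @param case a `seg_case` with a clean mask and a `side`.
#' @param m dilation magnitude in voxels.
#' @return the corrupted `seg_case`.
#' @export
corrupt_systematic <- function(case, m = 10L) {
  stopifnot(inherits(case, "seg_case"))
  side <- case$side
  if (is.null(side)) {
    cx <- mean(which(case$mask$voxels == 1, arr.ind = TRUE)[, 1])
    mid <- (dim(case$mask$voxels)[1] + 1) / 2
    if (cx == mid) stop("case has no side and a centred mask; lateral is undefined")
    side <- if (cx > mid) "right" else "left"
  }
  direction <- c(1L, if (side == "right") 1L else -1L)
  new_mask <- directional_dilate(case$mask, direction, m)
  attach_corruption(case, new_mask, "dilate", direction, m)
}

#' Apply a random corruption to a case
#'
#' Samples dilate/erode with probability 1/2 each and one of the six signed
#' Cartesian directions with probability 1/6 each. Dilations use magnitude
#' `m`; erosions use `round(erosion_factor * m)` (round half away from
#' zero). An erosion that would empty the mask triggers a direction resample
#' (up to 6 attempts) before failing.
#'
#' @inheritParams corrupt_systematic
#' @param erosion_factor see [corruption_spec()].
#' @param seed integer seed.
#' @return the corrupted `seg_case`.
#' @export
corrupt_random <- function(case, m = 10L, erosion_factor = 0.8, seed = 1L) {
  stopifnot(inherits(case, "seg_case"))
  m_erode <- as.integer(round_half_up(erosion_factor * m))
  with_seed(seed, {
    op <- if (stats::runif(1) < 0.5) "dilate" else "erode"
    for (attempt in 1:6) {
      direction <- CARDINAL_DIRECTIONS[[sample.int(6L, 1L)]]
      if (op == "dilate") {
        new_mask <- directional_dilate(case$mask, direction, m)
      } else {
        new_mask <- directional_erode(case$mask, direction, m_erode)
        if (sum(new_mask$voxels) == 0L) {
          if (attempt == 6L)
            stop("erosion emptied the mask in 6 direction attempts")
          message("erosion emptied mask for case ", case$case_id,
                  "; resampling direction")
          next
        }
      }
      return(attach_corruption(case, new_mask, op, direction,
                               if (op == "dilate") m else m_erode))
    }
  })
}

#' Corrupt a fraction of a cohort
#'
#' Selects exactly `round(fraction * N)` distinct cases uniformly without
#' replacement (round half away from zero) and corrupts them according to the
#' spec's mode; all other cases are returned untouched.
#'
#' @param cases list of `seg_case` objects (clean).
#' @param spec a [corruption_spec()].
#' @return list with `cases` (same order, selected ones corrupted) and
#'   `corrupted_ids` (character vector, the ground-truth corrupted set).
#' @export
corrupt_cohort <- function(cases, spec) {
  stopifnot(inherits(spec, "corruption_spec"))
  N <- length(cases)
  n_sel <- as.integer(round_half_up(spec$fraction * N))
  if (n_sel == 0L && spec$fraction > 0)
    warning("fraction * N rounds to 0; no cases corrupted")
  sel <- with_seed(derive_seed(spec$seed, "select"),
                   sort(sample.int(N, n_sel)))
  ids <- vapply(cases, `[[`, "", "case_id")
  out <- cases
  for (i in sel) {
    out[[i]] <- switch(spec$mode,
      systematic_lateral = corrupt_systematic(out[[i]], spec$magnitude),
      random = corrupt_random(out[[i]], spec$magnitude, spec$erosion_factor,
                              derive_seed(spec$seed, paste0("corrupt/", ids[i]))))
  }
  list(cases = out, corrupted_ids = ids[sel])
}

#' Calibrate the corruption magnitude to a target agreement DSC
#'
#' Searches integer magnitudes for the one whose median agreement DSC under
#' 100% cohort corruption is closest to `target_dsc`, ties broken toward the
#' smaller magnitude. This mirrors matching the median agreement of fully
#' perturbed data to the median of the poorest-agreement quartile of a real
#' cohort.
#'
#' @param cases list of clean `seg_case` objects.
#' @param target_dsc target median agreement in `(0, 1]`.
#' @param mode corruption mode (see [corruption_spec()]).
#' @param search_range integer magnitudes to try.
#' @param erosion_factor see [corruption_spec()].
#' @param seed seed used for random-mode sampling.
#' @return list with `magnitude` (m*), `median_dsc` at m*, and the full
#'   `profile` data.frame (magnitude, median agreement).
#' @export
calibrate_magnitude <- function(cases, target_dsc,
                                mode = c("systematic_lateral", "random"),
                                search_range = 0:12, erosion_factor = 0.8,
                                seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(target_dsc > 0, target_dsc <= 1, length(cases) >= 1)
  med <- vapply(search_range, function(m) {
    sp <- corruption_spec(mode, magnitude = m, erosion_factor = erosion_factor,
                          fraction = 1, seed = seed)
    cc <- corrupt_cohort(cases, sp)$cases
    stats::median(vapply(cc, function(x) x$corruption$agreement, numeric(1)))
  }, numeric(1))
  err <- abs(med - target_dsc)
  best <- which(err == min(err))[1]   # ties toward smaller m (range ascending)
  if (any(diff(med) > 1e-12))
    warning("median agreement not monotone over search_range; reporting best m")
  if (min(med) > target_dsc && search_range[best] == max(search_range))
    warning("target below achievable agreement at max magnitude; returning max")
  list(magnitude = as.integer(search_range[best]), median_dsc = med[best],
       profile = data.frame(magnitude = as.integer(search_range),
                            median_dsc = med))
}

#' Synthetic quality-score oracle
#'
#' Maps a corruption record onto the 1-5 specialist rubric via its agreement
#' DSC: 0 shortcoming flags at agreement >= 0.95, one at >= 0.85, two at
#' >= 0.70, three below. Flag identities follow the corruption geometry:
#' dilations (which sweep bone/skin/air laterally on the phantom) flag `e`
#' first; erosions flag the lobe/tissue facing the eroded face (`a` medial,
#' `b` anterior, `d` dorsal, `c` caudal/cranial tissue). Scores: >= 3 flags
#' is 1 (defective), 2 flags is 2 (poor), 1 flag is 3 (insufficient), no
#' flags is 4 (satisfactory) or 5 (good, agreement 1).
#'
#' @param record a `corruption_record` (or NULL for a pristine case).
#' @return list with `score` (integer 1-5) and `flags` (character subset of
#'   `a`-`e`).
#' @export
quality_from_record <- function(record) {
  if (is.null(record)) return(list(score = 5L, flags = character(0)))
  agr <- record$agreement
  n_flags <- if (agr >= 0.95) 0L else if (agr >= 0.85) 1L else if (agr >= 0.70) 2L else 3L
  primary <- if (record$op == "dilate") "e" else
    switch(paste0(record$direction[1], ifelse(record$direction[2] > 0, "+", "-")),
           "1+" = "a", "1-" = "a", "2+" = "d", "2-" = "b", "3+" = "c", "3-" = "c")
  pool <- unique(c(primary, c("e", "a", "b", "c", "d")))
  flags <- pool[seq_len(min(n_flags, 5L))]
  score <- if (n_flags >= 3L) 1L else if (n_flags == 2L) 2L else if (n_flags == 1L) 3L
           else if (agr >= 1) 5L else 4L
  list(score = score, flags = flags)
}
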