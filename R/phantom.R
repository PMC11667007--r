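#' Phantom generator parameters
#'
#' Describes the synthetic CT-like cohort: a single deformed-ellipsoid organ
#' (parotid-like, lateral to the grid midline) embedded in soft tissue, with a
#' high-intensity bone/skin slab and a low-intensity air pocket placed
#' laterally adjacent to the organ so that lateral over-segmentation sweeps
#' through tissue the organ model never contains.
#'
#' @param grid_shape integer length-3, grid size in voxels.
#' @param spacing numeric length-3, voxel size in mm.
#' @param radius_range organ mean radius range in mm, drawn uniformly per case.
#' @param eccentricity_range per-axis ellipsoid eccentricity range (unitless).
#' @param deform_amplitude amplitude (mm) of the low-frequency radial
#'   boundary perturbation; `0` gives an exact ellipsoid.
#' @param center_offset lateral offset of the organ centre from the
#'   mid-sagittal plane, voxels (signed by `side`).
#' @param center_jitter max per-axis uniform jitter of the centre, voxels.
#' @param intensity named list of mean intensities: `organ`, `background`,
#'   `bone`, `air` (CT-like arbitrary units).
#' @param noise_sd additive Gaussian intensity noise standard deviation.
#' @param smooth_sigma Gaussian smoothing scale of the intensity model, mm.
#' @param side `"left"` or `"right"`: which side of the midline the organ
#'   sits on (determines the lateral direction, away from the midline).
#' @param max_corruption largest corruption magnitude (voxels) the cohort
#'   must tolerate: every mask must keep at least this margin + 1 voxel from
#'   the grid boundary.
#' @param observer_jitter if `TRUE`, reference masks get a +/-1 voxel random
#'   boundary jitter emulating observer noise; off by default so the
#'   clean/corrupt distinction stays sharp.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(48, 48, 48),
                           spacing = c(1, 1, 1),
                           radius_range = c(5.5, 6.5),
                           eccentricity_range = c(0.9, 1.08),
                           deform_amplitude = 1,
                           center_offset = 3,
                           center_jitter = 1,
                           intensity = list(organ = 80, background = 30,
                                            bone = 700, air = -800),
                           noise_sd = 15,
                           smooth_sigma = 1,
                           side = "right",
                           max_corruption = 10,
                           observer_jitter = FALSE) {
  p <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
            radius_range = radius_range, eccentricity_range = eccentricity_range,
            deform_amplitude = deform_amplitude, center_offset = center_offset,
            center_jitter = center_jitter, intensity = intensity,
            noise_sd = noise_sd, smooth_sigma = smooth_sigma, side = side,
            max_corruption = max_corruption, observer_jitter = observer_jitter)
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (any(p$radius_range <= 0)) stop("radii must be positive")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!p$side %in% c("left", "right")) stop("side must be 'left' or 'right'")
  # worst-case organ extent from the grid centre along any axis, voxels
  worst <- (max(p$radius_range) * max(p$eccentricity_range) +
              p$deform_amplitude) / min(p$spacing) +
    p$center_jitter + abs(p$center_offset)
  margin <- min(p$grid_shape) / 2 - worst
  if (margin < p$max_corruption + 1)
    stop(sprintf(paste0("interior-margin invariant violated: worst-case organ ",
                        "extent leaves %.1f voxels to the boundary but ",
                        "max_corruption + 1 = %d is required"),
                 margin, p$max_corruption + 1L))
  invisible(p)
}

# 3D Gaussian smoothing via FFT (circular boundary; all phantom structure
# sits well inside the grid so wrap-around leakage is negligible).
gauss_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  if (all(sigma_vox <= 0)) return(arr)
  k1 <- function(n, s) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # wraparound distances
    if (s <= 0) return(as.numeric(x == 0))
    g <- exp(-x^2 / (2 * s^2))
    g / sum(g)
  }
  kern <- outer(outer(k1(d[1], sigma_vox[1]), k1(d[2], sigma_vox[2])),
                k1(d[3], sigma_vox[3]))
  dim(kern) <- d
  Re(fft(fft(arr) * fft(kern), inverse = TRUE)) / prod(d)
}

#' Generate one synthetic phantom case
#'
#' Deterministic for a fixed `(params, seed)`: the organ shape, its placement
#' and the intensity noise are all drawn from a locally seeded RNG.
#'
#' @param params a [phantom_params()].
#' @param seed integer seed.
#' @param case_id case identifier string.
#' @return list of class `seg_case` with fields `case_id`, `volume`
#'   ([seg_volume()]), `mask` ([seg_mask()]), `side`, `corrupted` (FALSE),
#'   `corruption` (NULL), `quality_score` (NULL).
#' @export
generate_case <- function(params, seed, case_id = sprintf("case%06d", seed)) {
  validate_phantom_params(params)
  with_seed(seed, {
    d <- params$grid_shape
    sp <- params$spacing
    sgn <- if (params$side == "right") 1 else -1
    mid <- (d + 1) / 2
    center <- mid + stats::runif(3, -params$center_jitter, params$center_jitter)
    center[1] <- center[1] + sgn * params$center_offset

    r <- stats::runif(1, params$radius_range[1], params$radius_range[2])
    ecc <- stats::runif(3, params$eccentricity_range[1], params$eccentricity_range[2])
    # low-frequency radial perturbation: random first+second order harmonics
    coef <- stats::rnorm(8)
    coef <- coef / max(1, sqrt(sum(coef^2)))

    ax <- lapply(1:3, function(i) ((1:d[i]) - center[i]) * sp[i])
    X <- array(rep(ax[[1]], times = d[2] * d[3]), dim = d)
    Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), dim = d)
    Z <- array(rep(ax[[3]], each = d[1] * d[2]), dim = d)
    rr <- sqrt(X^2 + Y^2 + Z^2)
    rr[rr == 0] <- 1e-9
    u1 <- X / rr; u2 <- Y / rr; u3 <- Z / rr
    g <- coef[1] * u1 + coef[2] * u2 + coef[3] * u3 +
      coef[4] * u1 * u2 + coef[5] * u1 * u3 + coef[6] * u2 * u3 +
      coef[7] * (u1^2 - u2^2) + coef[8] * (2 * u3^2 - u1^2 - u2^2) / 2
    radial <- sqrt((X / (r * ecc[1]))^2 + (Y / (r * ecc[2]))^2 +
                     (Z / (r * ecc[3]))^2)
    mask_arr <- array(as.integer(radial <= 1 + params$deform_amplitude * g / r),
                      dim = d)
    if (sum(mask_arr) == 0) stop("degenerate phantom: empty mask")

    if (isTRUE(params$observer_jitter)) {
      # +/-1 voxel boundary jitter: random thin dilate/erode along one axis
      dir <- c(sample(1:3, 1), sample(c(-1, 1), 1))
      m0 <- seg_mask(mask_arr, sp)
      m0 <- if (stats::runif(1) < 0.5) directional_dilate(m0, dir, 1L)
            else directional_erode(m0, dir, 1L)
      mask_arr <- m0$voxels
    }

    ints <- params$intensity
    vol <- array(ints$background, dim = d)
    vol[mask_arr == 1] <- ints$organ
    # lateral air pocket then bone/skin slab, relative to the organ centre
    cx <- round(center[1])
    air_x <- cx + sgn * (12:13)
    bone_x <- cx + sgn * (15:18)
    air_x <- air_x[air_x >= 1 & air_x <= d[1]]
    bone_x <- bone_x[bone_x >= 1 & bone_x <= d[1]]
    yz_y <- pmax(1, round(center[2]) - 6):pmin(d[2], round(center[2]) + 6)
    yz_z <- pmax(1, round(center[3]) - 6):pmin(d[3], round(center[3]) + 6)
    by <- pmax(1, round(center[2]) - 10):pmin(d[2], round(center[2]) + 10)
    bz <- pmax(1, round(center[3]) - 10):pmin(d[3], round(center[3]) + 10)
    if (length(air_x)) vol[air_x, yz_y, yz_z] <- ints$air
    if (length(bone_x)) vol[bone_x, by, bz] <- ints$bone

    vol <- gauss_smooth(vol, params$smooth_sigma / sp)
    vol <- vol + stats::rnorm(length(vol), 0, params$noise_sd)
    dim(vol) <- d

    structure(list(case_id = case_id,
                   volume = seg_volume(vol, sp),
                   mask = seg_mask(mask_arr, sp),
                   side = params$side,
                   corrupted = FALSE,
                   corruption = NULL,
                   quality_score = NULL),
              class = "seg_case")
  })
}

#' Allocate n cases over splits in stated proportions
#'
#' Exact when the proportions sum to `n`; otherwise largest-split-first
#' rounding (floor, remainders to the largest fractional parts, ties to the
#' earlier split).
#'
#' @param n number of cases.
#' @param proportions numeric vector, one entry per split, interpreted as
#'   relative weights.
#' @return integer vector of counts summing to `n`.
#' @keywords internal
split_counts <- function(n, proportions) {
  w <- proportions / sum(proportions)
  raw <- n * w
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(-(raw - cnt), seq_along(raw))
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Generate a synthetic phantom cohort
#'
#' Per-case seeds are derived deterministically from the master seed, so the
#' cohort is a pure function of `(params, n, proportions, seed)`.
#'
#' @param n number of cases.
#' @param params a [phantom_params()].
#' @param seed master seed.
#' @param proportions relative split sizes, named by split label (defaults to
#'   the 100/40/40 train/val/test_true allocation).
#' @param id_prefix prefix for case identifiers.
#' @return list with `cases` (list of `seg_case`) and `manifest`
#'   (data.frame with placeholder paths; see [cases_manifest()]).
#' @export
generate_cohort <- function(n, params, seed,
                            proportions = c(train = 100, val = 40, test_true = 40),
                            id_prefix = "pg") {
  stopifnot(n >= 1)
  if (is.null(names(proportions)) || !all(names(proportions) %in% VALID_SPLITS))
    stop("proportions must be named by split label")
  counts <- split_counts(n, proportions)
  splits <- rep(names(proportions), counts)
  cases <- lapply(seq_len(n), function(i) {
    generate_case(params, derive_seed(seed, paste0("case", i)),
                  case_id = sprintf("%s%04d", id_prefix, i))
  })
  list(cases = cases,
       manifest = cases_manifest(cases, splits = splits),
       splits = stats::setNames(splits, vapply(cases, `[[`, "", "case_id")))
}

#' Shift a phantom parameter distribution
#'
#' Produces the out-of-distribution variant of a cohort by adding offsets to
#' named numeric parameters (offsets on range parameters shift both ends).
#'
#' @param params a [phantom_params()].
#' @param shift_spec named list of additive offsets, e.g.
#'   `list(radius_range = 1.5, noise_sd = 5)`. Entries under `intensity`
#'   shift the corresponding intensity mean.
#' @return a new validated [phantom_params()].
#' @export
shift_distribution <- function(params, shift_spec) {
  p <- unclass(params)
  for (nm in names(shift_spec)) {
    if (nm == "intensity") {
      for (k in names(shift_spec$intensity))
        p$intensity[[k]] <- p$intensity[[k]] + shift_spec$intensity[[k]]
    } else if (!nm %in% names(p)) {
      stop("unknown phantom parameter: ", nm)
    } else {
      p[[nm]] <- p[[nm]] + shift_spec[[nm]]
    }
  }
  do.call(phantom_params, p[setdiff(names(p), character(0))])
}
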