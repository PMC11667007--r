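#' Segmenter configuration
#'
#' Describes the trainable-segmenter family. `depth`, `base_filters` and
#' `kernel` parameterize the classical 3D U-Net filter plan (filters doubling
#' per depth layer, batch-norm after the nonlinear activation), exposed
#' through [stage_filters()] and [unet_parameter_count()]. The package's
#' built-in desk-scale backend is a shallow convolutional scorer (see
#' [init_segmenter()]); the curation machinery is backend-agnostic and only
#' relies on the `init`/`train`/`predict_logits` contract.
#'
#' @param depth number of depth layers (>= 1); the classical default is 4.
#' @param base_filters filters in the input layer (classical default 32).
#' @param kernel convolution kernel size in voxels.
#' @param patch training crop size in voxels (NULL = whole grid); must be at
#'   least `2^depth` so the deepest stage keeps a nonzero spatial extent.
#' @param epochs full-training epoch count E (>= 4, so a 25% prompt phase is
#'   at least one epoch).
#' @param learning_rate Adam step size for the built-in backend.
#' @param smooth_sigma the fixed Gaussian smoothing scale (mm) applied to
#'   the normalized intensities before the basis expansion.
#' @param rbf_centers centers of the radial-basis intensity bank, in robust
#'   z-score units (intensities are clipped to the centers' range).
#' @param rbf_width Gaussian width of each basis, in z-score units.
#' @param prior_shift lateral offset in voxels of the two shifted copies of
#'   the spatial-prior channel. These give the scorer the capacity to
#'   represent a systematic lateral displacement of the cohort's shape
#'   prior, so biased (laterally over-segmented) training labels can
#'   actually be learned and reproduced rather than silently averaged away.
#' @param crop_margin margin in voxels added around the training masks'
#'   bounding box to form the training crop.
#' @param loss loss name; only `"soft_dice"` (overlap-based, no distance
#'   term) is built in.
#' @return list of class `segmenter_config`.
#' @export
segmenter_config <- function(depth = 3, base_filters = 8, kernel = c(3, 3, 3),
                             patch = NULL, epochs = 40, learning_rate = 0.3,
                             smooth_sigma = 1,
                             rbf_centers = seq(-6, 6, by = 1.5),
                             rbf_width = 1.5, prior_shift = 3,
                             crop_margin = 14, loss = "soft_dice") {
  if (depth < 1) stop("depth must be >= 1")
  if (base_filters < 1) stop("base_filters must be >= 1")
  if (epochs < 4) stop("epochs must be >= 4 (25% prompt phase needs >= 1 epoch)")
  if (!identical(loss, "soft_dice")) stop("unknown loss: ", loss)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 kernel = as.integer(kernel), patch = patch,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 smooth_sigma = smooth_sigma, rbf_centers = rbf_centers,
                 rbf_width = rbf_width, prior_shift = as.integer(prior_shift),
                 crop_margin = as.integer(crop_margin), loss = loss),
            class = "segmenter_config")
}

#' Filters per encoder stage
#'
#' `base_filters * 2^(stage)` for stages `0..depth-1` (filters double at each
#' depth layer).
#'
#' @param config a [segmenter_config()].
#' @return integer vector of length `depth`.
#' @export
stage_filters <- function(config) {
  as.integer(config$base_filters * 2^(0:(config$depth - 1)))
}

#' Parameter count of the described U-Net filter plan
#'
#' Pure arithmetic over the config: two `kernel`-sized convolutions per
#' encoder stage and per decoder stage (each followed by batch-norm), a
#' transposed-convolution upsampling per decoder stage, and a final 1-voxel
#' convolution onto a single-channel pre-sigmoid score map.
#'
#' @param config a [segmenter_config()].
#' @param in_channels input image channels.
#' @return total trainable parameter count.
#' @export
unet_parameter_count <- function(config, in_channels = 1) {
  k <- prod(config$kernel)
  f <- stage_filters(config)
  conv <- function(cin, cout, kk = k) kk * cin * cout + cout
  bn <- function(cout) 2 * cout
  total <- 0
  cin <- in_channels
  for (s in seq_along(f)) {          # encoder
    total <- total + conv(cin, f[s]) + bn(f[s]) + conv(f[s], f[s]) + bn(f[s])
    cin <- f[s]
  }
  for (s in rev(seq_len(length(f) - 1))) {   # decoder with skip concat
    total <- total + conv(cin, f[s], 8) + bn(f[s])       # 2x2x2 up-conv
    total <- total + conv(2 * f[s], f[s]) + bn(f[s]) + conv(f[s], f[s]) + bn(f[s])
    cin <- f[s]
  }
  total + conv(cin, 1, 1)
}

#' Initialize a fresh segmenter
#'
#' The built-in backend is a shallow convolutional scorer: the intensities
#' are robust-normalized, smoothed with a fixed Gaussian filter, expanded
#' into a radial-basis intensity bank (so the scorer can represent an
#' intensity band, not just a threshold), concatenated with a cohort
#' spatial-prior channel, and combined by a trainable 1x1x1 convolution into
#' a per-voxel pre-sigmoid score. Training is full-batch Adam on soft-Dice
#' loss over a crop around the training masks. Weight initialization is
#' reproducible for a fixed `(config, seed)`.
#'
#' @param config a [segmenter_config()].
#' @param seed integer seed.
#' @return object of class `seg_segmenter` (untrained).
#' @export
init_segmenter <- function(config, seed = 1L) {
  stopifnot(inherits(config, "segmenter_config"))
  if (!is.null(config$patch) && min(config$patch) < 2^config$depth)
    stop("patch smaller than 2^depth: spatial size underflow at deepest stage")
  # bias + basis bank + prior + two laterally shifted priors
  n_w <- 4L + length(config$rbf_centers)
  w <- with_seed(seed, stats::rnorm(n_w, 0, 0.01))
  structure(list(config = config, weights = w, atlas = NULL, norm = NULL,
                 trained = FALSE,
                 provenance = list(init_seed = as.integer(seed),
                                   train_seed = NULL, case_ids = NULL,
                                   epochs_trained = 0L)),
            class = "seg_segmenter")
}

# shift a numeric 3D array along axis 1, padding with `fill`
shift_axis1 <- function(arr, k, fill = -1) {
  if (k == 0) return(arr)
  d <- dim(arr)
  out <- array(fill, dim = d)
  if (abs(k) >= d[1]) return(out)
  if (k > 0) out[(k + 1):d[1], , ] <- arr[1:(d[1] - k), , ]
  else out[1:(d[1] + k), , ] <- arr[(1 - k):d[1], , ]
  out
}

# feature channels for one volume: bias, RBF bank over the smoothed robust
# z-score (clipped to the centers' range), spatial prior, and the prior
# shifted laterally by +/- prior_shift voxels. `keep` optionally restricts
# to a voxel subset (training crop).
scorer_features <- function(segmenter, volume, keep = NULL) {
  cfg <- segmenter$config
  nm <- segmenter$norm
  z <- (volume$voxels - nm$center) / nm$scale
  z <- gauss_smooth(z, cfg$smooth_sigma / volume$spacing)
  z <- pmin(pmax(as.vector(z), min(cfg$rbf_centers)), max(cfg$rbf_centers))
  prior <- as.vector(segmenter$atlas)
  prior_p <- as.vector(shift_axis1(segmenter$atlas, cfg$prior_shift))
  prior_m <- as.vector(shift_axis1(segmenter$atlas, -cfg$prior_shift))
  if (!is.null(keep)) {
    z <- z[keep]; prior <- prior[keep]
    prior_p <- prior_p[keep]; prior_m <- prior_m[keep]
  }
  nc <- 4L + length(cfg$rbf_centers)
  X <- matrix(0, nrow = length(z), ncol = nc)
  X[, 1] <- 1
  for (j in seq_along(cfg$rbf_centers))
    X[, 1L + j] <- exp(-(z - cfg$rbf_centers[j])^2 / (2 * cfg$rbf_width^2))
  X[, nc - 2L] <- prior
  X[, nc - 1L] <- prior_p
  X[, nc] <- prior_m
  X
}

# linear voxel indices of the bounding box of the union of training masks,
# expanded by `margin` voxels and clipped to the grid
crop_indices <- function(masks, margin) {
  d <- dim(masks[[1]]$voxels)
  un <- Reduce(`|`, lapply(masks, `[[`, "voxels"))
  w <- which(un == 1, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - margin, 1L)
  hi <- pmin(apply(w, 2, max) + margin, d)
  arr <- array(FALSE, dim = d)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  which(arr)
}

#' Train a segmenter
#'
#' Fits the scorer weights by full-batch Adam on mean per-case soft-Dice
#' loss. The spatial prior channel and the intensity normalization constants
#' (median and robust sd of the training intensities) are estimated from the
#' training cases and frozen into the model, so inference is deterministic.
#'
#' @param segmenter a `seg_segmenter` from [init_segmenter()].
#' @param cases nonempty list of `seg_case` training cases.
#' @param epochs number of epochs (full-batch gradient steps); defaults to
#'   the config's `epochs`.
#' @param seed integer seed (recorded; training itself is deterministic
#'   given the initialized weights).
#' @return the trained `seg_segmenter`.
#' @export
train_segmenter <- function(segmenter, cases, epochs = NULL, seed = 1L) {
  stopifnot(inherits(segmenter, "seg_segmenter"))
  if (length(cases) == 0) stop("empty training set")
  epochs <- as.integer(epochs %||% segmenter$config$epochs)
  if (epochs < 1) stop("epochs must be >= 1")

  ints <- unlist(lapply(cases, function(cc) as.vector(cc$volume$voxels)))
  center <- stats::median(ints)
  scale <- max(stats::IQR(ints) / 1.349, 1e-6)
  rm(ints)
  segmenter$norm <- list(center = center, scale = scale)
  atlas_mean <- Reduce(`+`, lapply(cases, function(cc) cc$mask$voxels)) / length(cases)
  atlas <- 2 * gauss_smooth(atlas_mean, 1 / cases[[1]]$volume$spacing) - 1
  segmenter$atlas <- atlas

  keep <- crop_indices(lapply(cases, `[[`, "mask"), segmenter$config$crop_margin)
  X <- do.call(rbind, lapply(cases, function(cc)
    scorer_features(segmenter, cc$volume, keep = keep)))
  y <- unlist(lapply(cases, function(cc) as.vector(cc$mask$voxels)[keep]))
  case_of <- rep(seq_along(cases), each = length(keep))
  sum_y <- rowsum(y, case_of)[, 1]

  w <- segmenter$weights
  mo <- numeric(length(w)); vo <- numeric(length(w))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- segmenter$config$learning_rate
  smooth_eps <- 1
  for (t in seq_len(epochs)) {
    z <- as.vector(X %*% w)
    p <- stats::plogis(z)
    sum_p <- rowsum(p, case_of)[, 1]
    sum_py <- rowsum(p * y, case_of)[, 1]
    denom <- sum_p + sum_y + smooth_eps
    num <- 2 * sum_py + smooth_eps
    # d(loss_c)/dp_v = -(2 y_v denom - num) / denom^2, loss averaged per case
    dldp <- -(2 * y * denom[case_of] - num[case_of]) / denom[case_of]^2
    dldz <- dldp * p * (1 - p) / length(cases)
    g <- as.vector(crossprod(X, dldz))
    mo <- b1 * mo + (1 - b1) * g
    vo <- b2 * vo + (1 - b2) * g^2
    w <- w - lr * (mo / (1 - b1^t)) / (sqrt(vo / (1 - b2^t)) + eps)
  }
  segmenter$weights <- w
  segmenter$trained <- TRUE
  segmenter$provenance$train_seed <- as.integer(seed)
  segmenter$provenance$case_ids <- vapply(cases, `[[`, "", "case_id")
  segmenter$provenance$epochs_trained <-
    segmenter$provenance$epochs_trained + epochs
  segmenter
}

#' Per-voxel pre-sigmoid scores for a volume
#'
#' @param trained a trained `seg_segmenter`.
#' @param volume a [seg_volume()] on the training grid shape.
#' @return numeric array of logits, same shape as the input grid.
#' @export
predict_logits <- function(trained, volume) {
  stopifnot(inherits(trained, "seg_segmenter"))
  if (!isTRUE(trained$trained)) stop("segmenter has not been trained")
  if (!identical(dim(volume$voxels), dim(trained$atlas)))
    stop("shape mismatch between volume and model grid")
  X <- scorer_features(trained, volume)
  array(as.vector(X %*% trained$weights), dim = dim(volume$voxels))
}

#' Predicted binary mask (logits thresholded at 0)
#'
#' @inheritParams predict_logits
#' @return a [seg_mask()].
#' @export
predict_mask <- function(trained, volume) {
  lg <- predict_logits(trained, volume)
  seg_mask(array(as.integer(lg > 0), dim = dim(lg)), volume$spacing)
}
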