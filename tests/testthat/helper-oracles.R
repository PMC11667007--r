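# Independent brute-force oracles, written from the definitions rather than
# sharing any code path with the package implementation.

random_mask <- function(d, p = 0.3, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  v <- array(as.integer(stats::runif(prod(d)) < p), dim = d)
  if (sum(v) == 0) v[ceiling(d / 2)[1], ceiling(d / 2)[2], ceiling(d / 2)[3]] <- 1L
  seg_mask(v, spacing)
}

# voxel lookup with out-of-grid treated as background
mask_at <- function(arr, i, j, k) {
  d <- dim(arr)
  if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) 0L else arr[i, j, k]
}

# dilation oracle: v foreground iff exists k in 0..m with v - k*dir in mask
bf_dilate <- function(mask, direction, m) {
  arr <- mask$voxels
  d <- dim(arr)
  step <- c(0, 0, 0); step[direction[1]] <- direction[2]
  out <- array(0L, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    for (s in 0:m) {
      if (mask_at(arr, i - s * step[1], j - s * step[2], k - s * step[3]) == 1L) {
        out[i, j, k] <- 1L
        break
      }
    }
  }
  seg_mask(out, mask$spacing)
}

# erosion oracle: v kept iff for all k in 0..m, v + k*dir in mask
bf_erode <- function(mask, direction, m) {
  arr <- mask$voxels
  d <- dim(arr)
  step <- c(0, 0, 0); step[direction[1]] <- direction[2]
  out <- array(0L, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    keep <- TRUE
    for (s in 0:m) {
      if (mask_at(arr, i + s * step[1], j + s * step[2], k + s * step[3]) == 0L) {
        keep <- FALSE
        break
      }
    }
    out[i, j, k] <- as.integer(keep)
  }
  seg_mask(out, mask$spacing)
}

# surface oracle: foreground voxel with any of 6 face neighbours background
bf_surface <- function(mask) {
  arr <- mask$voxels
  d <- dim(arr)
  out <- NULL
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (arr[i, j, k] == 1L) {
      nb <- c(mask_at(arr, i - 1, j, k), mask_at(arr, i + 1, j, k),
              mask_at(arr, i, j - 1, k), mask_at(arr, i, j + 1, k),
              mask_at(arr, i, j, k - 1), mask_at(arr, i, j, k + 1))
      if (any(nb == 0L)) out <- rbind(out, c(i, j, k))
    }
  }
  out
}

# all-pairs nearest-surface-distance oracle (per-point scan over the other
# surface; no shared code with the chunked implementation)
bf_surface_metrics <- function(a, b, spacing) {
  sa <- bf_surface(a); sb <- bf_surface(b)
  pa <- sweep(sa, 2, spacing, `*`); pb <- sweep(sb, 2, spacing, `*`)
  d_ab <- vapply(seq_len(nrow(pa)), function(i)
    min(sqrt((pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2 +
               (pb[, 3] - pa[i, 3])^2)), numeric(1))
  d_ba <- vapply(seq_len(nrow(pb)), function(i)
    min(sqrt((pa[, 1] - pb[i, 1])^2 + (pa[, 2] - pb[i, 2])^2 +
               (pa[, 3] - pb[i, 3])^2)), numeric(1))
  list(msd = (mean(d_ab) + mean(d_ba)) / 2, hd = max(max(d_ab), max(d_ba)))
}

bf_dsc <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (idx in seq_along(a$voxels)) {
    av <- a$voxels[idx]; bv <- b$voxels[idx]
    inter <- inter + (av == 1L && bv == 1L)
    na <- na + av; nb <- nb + bv
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

# exact two-sided signed-rank p by full 2^n sign-flip enumeration
bf_wilcoxon_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- n * (n + 1) / 2
  vs <- vapply(0:(2^n - 1), function(bits) {
    signs <- as.integer(intToBits(bits))[1:n]
    sum(r[signs == 1L])
  }, numeric(1))
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# single 6-connected component check by flood fill
is_single_component <- function(mask) {
  arr <- mask$voxels
  w <- which(arr == 1L, arr.ind = TRUE)
  if (nrow(w) == 0) return(FALSE)
  seen <- array(FALSE, dim = dim(arr))
  queue <- matrix(w[1, ], ncol = 3)
  seen[w[1, 1], w[1, 2], w[1, 3]] <- TRUE
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue) > 0) {
    v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (s in 1:6) {
      u <- v + steps[s, ]
      if (all(u >= 1) && all(u <= dim(arr)) &&
          arr[u[1], u[2], u[3]] == 1L && !seen[u[1], u[2], u[3]]) {
        seen[u[1], u[2], u[3]] <- TRUE
        queue <- rbind(queue, u)
      }
    }
  }
  sum(seen) == sum(arr)
}

# Exact complement duality erode(M, d, m) = !dilate(!M, -d, m) requires the
# complement's exterior to be foreground (the complement of background).
# Embedding the mask in an m-voxel background ring realizes that exactly.
duality_dual_erode <- function(mask, direction, m) {
  d <- dim(mask$voxels)
  if (m == 0) return(mask$voxels)
  P <- array(0L, d + 2L * m)
  core <- lapply(d, function(n) (m + 1):(m + n))
  P[core[[1]], core[[2]], core[[3]]] <- mask$voxels
  comp <- seg_mask(1L - P)
  dil <- directional_dilate(comp, c(direction[1], -direction[2]), m,
                            clip = TRUE)
  out <- 1L - dil$voxels[core[[1]], core[[2]], core[[3]]]
  array(as.integer(out), dim = d)
}
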