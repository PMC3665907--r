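#' Resting-state time-series dataset of one participant
#'
#' 4D BOLD-like data on a [brain_grid()] together with the nuisance tables
#' acquired alongside: per-volume realignment (motion) parameters and mean
#' tissue-class signals. Motion correction, normalization and segmentation
#' are assumed to have happened upstream; this package consumes their
#' outputs.
#'
#' @param data 4D numeric array (x, y, z, time), time dimension >= 32.
#' @param tr_seconds repetition time (s).
#' @param motion per-timepoint 6-column matrix of realignment parameters.
#' @param tissue_means per-timepoint 3-column matrix (gray, white, CSF).
#' @param grid the [brain_grid()] of the spatial dimensions.
#' @param id participant identifier.
#' @return An object of class `ts_dataset`.
#' @export
ts_dataset <- function(data, tr_seconds, motion, tissue_means, grid,
                       id = "sub") {
  stopifnot(inherits(grid, "brain_grid"))
  if (length(dim(data)) != 4L || !all(dim(data)[1:3] == grid$shape))
    stop("data must be a 4D array on the grid")
  nt <- dim(data)[4]
  if (nt < 32L) stop("time dimension must be >= 32")
  if (tr_seconds <= 0) stop("tr_seconds must be > 0")
  motion <- as.matrix(motion)
  tissue_means <- as.matrix(tissue_means)
  if (nrow(motion) != nt || ncol(motion) != 6L)
    stop("motion must have one 6-column row per volume")
  if (nrow(tissue_means) != nt || ncol(tissue_means) != 3L)
    stop("tissue_means must have one 3-column row per volume")
  structure(list(data = data, tr_seconds = tr_seconds, motion = motion,
                 tissue_means = tissue_means, grid = grid,
                 id = as.character(id)),
            class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat(sprintf("<ts_dataset> '%s': %dx%dx%d x %d volumes, TR %.3g s\n",
              x$id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              dim(x$data)[4], x$tr_seconds))
  invisible(x)
}

# time x in-mask-voxel view of the data
.ts_matrix <- function(ds) {
  nt <- dim(ds$data)[4]
  m <- matrix(ds$data, nrow = prod(ds$grid$shape), ncol = nt)
  t(m[which(ds$grid$mask), , drop = FALSE])
}

.ts_set_matrix <- function(ds, M) {
  nt <- dim(ds$data)[4]
  m <- matrix(0, nrow = prod(ds$grid$shape), ncol = nt)
  m[which(ds$grid$mask), ] <- t(M)
  ds$data <- array(m, dim = c(ds$grid$shape, nt))
  ds
}

#' Discard initial dummy volumes
#'
#' Early volumes acquired before magnetic-field saturation carry a signal
#' offset and are conventionally dropped before analysis.
#'
#' @param ds a [ts_dataset()].
#' @param n number of initial volumes to discard (default 4).
#' @return The shortened dataset (motion and tissue rows dropped in step).
#' @export
drop_dummies <- function(ds, n = 4) {
  nt <- dim(ds$data)[4]
  if (nt - n < 32L) stop("too few volumes would remain")
  keep <- (n + 1):nt
  ts_dataset(ds$data[, , , keep, drop = FALSE], ds$tr_seconds,
             ds$motion[keep, , drop = FALSE],
             ds$tissue_means[keep, , drop = FALSE], ds$grid, ds$id)
}

#' Nuisance design matrix (first- and second-order terms)
#'
#' Columns: the six motion parameters, their first derivatives (backward
#' difference, zero first row), the three tissue means, the element-wise
#' square of each of those fifteen regressors, and an intercept — 31
#' columns in all. Every column except the intercept is mean-centered;
#' columns that are constant after construction carry no information and
#' are dropped with a warning.
#'
#' @param ds a [ts_dataset()].
#' @return A list of class `nuisance_matrix` with fields `x` (matrix) and
#'   `labels`.
#' @export
build_nuisance_matrix <- function(ds) {
  stopifnot(inherits(ds, "ts_dataset"))
  mo <- ds$motion
  dmo <- rbind(0, diff(mo))
  ti <- ds$tissue_means
  first <- cbind(mo, dmo, ti)
  labels1 <- c(paste0("motion", 1:6), paste0("dmotion", 1:6),
               c("gray", "white", "csf"))
  second <- first^2
  x <- cbind(first, second)
  labels <- c(labels1, paste0(labels1, "_sq"))
  keep <- apply(x, 2, function(cl) stats::sd(cl) > 1e-12)
  if (!all(keep)) {
    warning("dropping constant nuisance column(s): ",
            paste(labels[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  x <- sweep(x, 2, colMeans(x))
  x <- cbind(x, 1)
  labels <- c(labels, "intercept")
  colnames(x) <- labels
  structure(list(x = x, labels = labels), class = "nuisance_matrix")
}

#' Remove nuisance variance from every voxel time course
#'
#' Per voxel, the least-squares projection onto the nuisance column space
#' is subtracted. A rank-deficient design keeps a maximal independent
#' column subset (with a warning).
#'
#' @param ds a [ts_dataset()].
#' @param nm a `nuisance_matrix` (built from `ds` when absent).
#' @return The residual dataset.
#' @export
regress_nuisance <- function(ds, nm = build_nuisance_matrix(ds)) {
  X <- nm$x
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warning("nuisance matrix is rank deficient; dropping ",
            ncol(X) - qrx$rank, " dependent column(s)")
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    qrx <- qr(X)
  }
  Y <- .ts_matrix(ds)
  res <- qr.resid(qrx, Y)
  .ts_set_matrix(ds, res)
}

#' Band-pass filter voxel time courses
#'
#' Frequency-domain filter with a cosine-tapered transition band of width
#' `transition_hz` outside the passband: unity gain within
#' `[low_hz, high_hz]`, zero beyond the tapers. The passband is preserved
#' within 5% and frequencies at twice the upper (or half the lower) edge
#' are attenuated by at least 90%.
#'
#' @param ds a [ts_dataset()].
#' @param low_hz,high_hz passband edges (Hz); `high_hz` must lie below the
#'   Nyquist frequency `1/(2 TR)`.
#' @param transition_hz cosine taper width (Hz).
#' @return The filtered dataset (mean removed: gain at 0 Hz is zero).
#' @export
bandpass_filter <- function(ds, low_hz = 0.01, high_hz = 0.08,
                            transition_hz = 0.005) {
  stopifnot(inherits(ds, "ts_dataset"))
  nyq <- 1 / (2 * ds$tr_seconds)
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= nyq)
    stop("band must satisfy 0 < low < high < Nyquist (", signif(nyq, 4),
         " Hz)")
  Y <- .ts_matrix(ds)
  nt <- nrow(Y)
  fr <- (seq_len(nt) - 1) / (nt * ds$tr_seconds)
  fr <- pmin(fr, 1 / ds$tr_seconds - fr)     # fold to [0, Nyquist]
  gain <- .cos_taper_gain(fr, low_hz, high_hz, transition_hz)
  Yf <- stats::mvfft(Y)
  Yf <- Yf * gain
  out <- Re(stats::mvfft(Yf, inverse = TRUE)) / nt
  .ts_set_matrix(ds, out)
}

.cos_taper_gain <- function(f, low, high, w) {
  g <- numeric(length(f))
  inb <- f >= low & f <= high
  g[inb] <- 1
  ramp_lo <- f > low - w & f < low
  g[ramp_lo] <- 0.5 * (1 + cos(pi * (low - f[ramp_lo]) / w))
  ramp_hi <- f > high & f < high + w
  g[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - high) / w))
  g
}

#' Summary time course of a seed: first eigenvariate
#'
#' The first singular direction of the (time x voxel) matrix of the seed's
#' time courses, returned with unit variance and sign chosen so that its
#' correlation with the seed-mean time course is non-negative. More robust
#' than the plain mean when the seed contains heterogeneous voxels.
#'
#' @param ds a preprocessed [ts_dataset()].
#' @param seed a [seed_region()] on the dataset grid.
#' @param method `"eigenvariate"` (default) or `"mean"` for comparison.
#' @return Numeric vector of length `n_timepoints`.
#' @export
seed_eigenvariate <- function(ds, seed, method = c("eigenvariate", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "ts_dataset"), inherits(seed, "seed_region"))
  if (!same_grid(ds$grid, seed$grid))
    stop("dataset and seed live on different grids")
  sel <- seed$mask[which(ds$grid$mask)]
  if (!any(sel)) stop("seed has no voxel inside the grid mask")
  M <- .ts_matrix(ds)[, sel, drop = FALSE]
  if (all(abs(M) < 1e-15)) stop("seed data are all zero")
  mcourse <- rowMeans(M)
  if (method == "mean") {
    s <- mcourse
  } else {
    sv <- svd(M, nu = 1, nv = 0)
    s <- sv$u[, 1]
    if (sum(s * mcourse) < 0) s <- -s
  }
  sdv <- stats::sd(s)
  if (sdv < 1e-15) stop("seed time course is constant")
  as.numeric((s - mean(s)) / sdv)
}

#' Seed-to-voxel correlation and Fisher-z maps
#'
#' Pearson correlation of the seed summary time course with every in-mask
#' voxel, and its Fisher z transform `atanh(r)` (r clipped at
#' `1 - 1e-7` in magnitude so z stays finite). Voxels with zero variance
#' get r = 0 and are flagged, as are voxels inside the seed itself (their
#' correlation is reported but partly self-referential).
#'
#' @param ds a preprocessed (nuisance-regressed, band-passed)
#'   [ts_dataset()].
#' @param seed a [seed_region()].
#' @param method passed to [seed_eigenvariate()].
#' @return A list of class `connectivity_map`: `participant_id`,
#'   `seed_name`, `r` and `z` [stat_map()]s, and logical flag arrays
#'   `flag_zero_variance`, `flag_in_seed`.
#' @export
seed_correlation_map <- function(ds, seed,
                                 method = c("eigenvariate", "mean")) {
  s <- seed_eigenvariate(ds, seed, method)
  Y <- .ts_matrix(ds)
  nt <- nrow(Y)
  ym <- colMeans(Y)
  yc <- sweep(Y, 2, ym)
  sy <- sqrt(colSums(yc^2))
  sc <- s - mean(s)
  ss <- sqrt(sum(sc^2))
  zero_var <- sy < 1e-12
  r <- as.numeric(crossprod(yc, sc)) / (pmax(sy, 1e-300) * ss)
  r[zero_var] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  grid <- ds$grid
  mask_flat <- which(grid$mask)
  rfull <- numeric(prod(grid$shape))
  rfull[mask_flat] <- r
  zfull <- numeric(prod(grid$shape))
  zfull[mask_flat] <- atanh(r)
  zv <- array(FALSE, dim = grid$shape)
  zv[mask_flat[zero_var]] <- TRUE
  structure(list(participant_id = ds$id, seed_name = seed$name,
                 r = stat_map(grid, rfull, kind = "r"),
                 z = stat_map(grid, zfull, kind = "z"),
                 flag_zero_variance = zv, flag_in_seed = seed$mask),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> '%s' ~ seed '%s'\n", x$participant_id,
              x$seed_name))
  invisible(x)
}

# One-sample cluster inference machinery shared by group_inference and
# rs_seed_contrast: one-sided t per voxel on the rows-of-participants
# matrix Z (n x V, V = in-mask voxels), cluster-forming threshold at
# voxel_p, cluster-level correction by a sign-flip maximum-cluster-size
# null.
.one_sample_cluster <- function(Z, grid, voxel_p, cluster_alpha, n_perm,
                                connectivity) {
  n <- nrow(Z)
  df <- n - 1
  ssq <- colSums(Z^2)
  tstat_of <- function(m) {
    v <- (ssq - n * m^2) / df
    ifelse(v < 1e-24, 0, m / sqrt(v / n))
  }
  t_obs <- tstat_of(colMeans(Z))
  tcrit <- stats::qt(voxel_p, df, lower.tail = FALSE)
  mask_flat <- which(grid$mask)
  act <- mask_flat[t_obs > tcrit]
  p <- stats::pt(t_obs, df, lower.tail = FALSE)
  zvals <- numeric(prod(grid$shape))
  zvals[mask_flat] <- stats::qnorm(pmax(p, 1e-15), lower.tail = FALSE)
  zthr <- numeric(prod(grid$shape))
  empty_tab <- function() {
    tab <- label_clusters(stat_map(grid, numeric(prod(grid$shape))),
                          connectivity)
    tab$cluster_p <- numeric(0)
    tab$significant <- logical(0)
    tab
  }
  if (length(act) == 0L)
    return(list(z_map = stat_map(grid, zthr, kind = "z"),
                clusters = empty_tab(), null_max_sizes = integer()))
  zsup <- numeric(prod(grid$shape))
  zsup[act] <- zvals[act]
  tab <- label_clusters(stat_map(grid, zsup, kind = "z"), connectivity)
  labarr <- attr(tab, "labels")
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                  nrow = n_perm)
  Mp <- flips %*% Z / n
  null_max <- integer(n_perm)
  for (it in seq_len(n_perm)) {
    tp <- tstat_of(Mp[it, ])
    hot <- mask_flat[tp > tcrit]
    null_max[it] <- .max_cluster_size(hot, grid$shape, connectivity)
  }
  tab$cluster_p <- (1 + vapply(tab$size_voxels,
                               function(s) sum(null_max >= s), 0L)) /
    (1 + n_perm)
  tab$significant <- tab$cluster_p <= cluster_alpha
  keep_lab <- tab$cluster_id[tab$significant]
  zsup[!(labarr %in% keep_lab)] <- 0
  list(z_map = stat_map(grid, zsup, kind = "z"), clusters = tab,
       null_max_sizes = null_max)
}

.zmat <- function(maps, grid) {
  mask_flat <- which(grid$mask)
  t(vapply(maps, function(m) m$z$values[mask_flat],
           numeric(length(mask_flat))))
}

#' Random-effects group inference on Fisher-z connectivity maps
#'
#' One-sample t-test per voxel for positive deviation from zero across
#' participants, cluster-forming threshold at `voxel_p`, cluster-level
#' familywise correction from a sign-flip maximum-cluster-size null.
#'
#' @param maps list of [seed_correlation_map()] results (>= 2 participants;
#'   a warning is issued below 8).
#' @param voxel_p cluster-forming voxel threshold.
#' @param cluster_alpha cluster-level familywise alpha.
#' @param n_perm number of sign-flip permutations.
#' @param rng_seed RNG seed for the sign flips.
#' @param connectivity cluster connectivity.
#' @return A list of class `group_inference_result`: `z_map` (thresholded),
#'   `clusters`, `null_max_sizes`, `n_participants`.
#' @export
group_inference <- function(maps, voxel_p = 0.001, cluster_alpha = 0.05,
                            n_perm = 1000, rng_seed = NULL,
                            connectivity = 26) {
  stopifnot(length(maps) >= 2L,
            all(vapply(maps, inherits, TRUE, "connectivity_map")))
  if (length(maps) < 8L)
    warning("fewer than 8 participants: group inference will be unstable")
  grid <- maps[[1]]$z$grid
  for (m in maps[-1]) if (!same_grid(grid, m$z$grid))
    stop("connectivity maps live on different grids")
  Z <- .zmat(maps, grid)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  out <- .one_sample_cluster(Z, grid, voxel_p, cluster_alpha, n_perm,
                             connectivity)
  structure(c(out, list(n_participants = length(maps))),
            class = "group_inference_result")
}

#' @export
print.group_inference_result <- function(x, ...) {
  cat(sprintf("<group_inference_result> n=%d, %d significant cluster(s)\n",
              x$n_participants, sum(x$clusters$significant)))
  invisible(x)
}

#' Paired seed contrast on resting-state connectivity
#'
#' Paired t-test per voxel on the participant-wise difference of the two
#' seeds' Fisher-z maps, with the same cluster-forming and sign-flip
#' cluster-correction machinery as [group_inference()], run in both
#' directions. Swapping the two map lists exactly swaps the directions.
#'
#' @param maps_a,maps_b lists of [seed_correlation_map()] results, paired
#'   by participant (ids must match in order).
#' @inheritParams group_inference
#' @return A list of class `rs_contrast_result` with elements `a_gt_b` and
#'   `b_gt_a` (each with `z_map` and `clusters`), and `seed_a`, `seed_b`.
#' @export
rs_seed_contrast <- function(maps_a, maps_b, voxel_p = 0.001,
                             cluster_alpha = 0.05, n_perm = 1000,
                             rng_seed = NULL, connectivity = 26) {
  stopifnot(length(maps_a) == length(maps_b), length(maps_a) >= 2L)
  ids_a <- vapply(maps_a, `[[`, "", "participant_id")
  ids_b <- vapply(maps_b, `[[`, "", "participant_id")
  if (!identical(ids_a, ids_b))
    stop("inputs are not paired by participant")
  grid <- maps_a[[1]]$z$grid
  D <- .zmat(maps_a, grid) - .zmat(maps_b, grid)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ab <- .one_sample_cluster(D, grid, voxel_p, cluster_alpha, n_perm,
                            connectivity)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ba <- .one_sample_cluster(-D, grid, voxel_p, cluster_alpha, n_perm,
                            connectivity)
  structure(list(a_gt_b = ab, b_gt_a = ba,
                 seed_a = maps_a[[1]]$seed_name,
                 seed_b = maps_b[[1]]$seed_name),
            class = "rs_contrast_result")
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing with the stated full width at half maximum,
#' applied to a statistic map or to every volume of a time-series dataset.
#' The kernel is mass-normalized, so interior structures conserve their
#' integral; output is re-restricted to the brain mask.
#'
#' @param x a [stat_map()] or [ts_dataset()].
#' @param fwhm_mm kernel FWHM in mm (> 0).
#' @return Same kind of object as `x`.
#' @export
smooth_volume <- function(x, fwhm_mm = 5) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be > 0")
  if (inherits(x, "stat_map")) {
    v <- .gauss_smooth3(x$values, x$grid, fwhm_mm)
    return(stat_map(x$grid, v, kind = x$kind))
  }
  if (inherits(x, "ts_dataset")) {
    nt <- dim(x$data)[4]
    for (t in seq_len(nt))
      x$data[, , , t] <- .gauss_smooth3(x$data[, , , t], x$grid, fwhm_mm)
    m <- matrix(x$data, nrow = prod(x$grid$shape))
    m[!x$grid$mask, ] <- 0
    x$data <- array(m, dim = dim(x$data))
    return(x)
  }
  stop("x must be a stat_map or ts_dataset")
}

.gauss_smooth3 <- function(arr, grid, fwhm_mm) {
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  for (ax in 1:3) {
    sg <- sigma_mm / vs[ax]
    r <- max(1L, ceiling(3.5 * sg))
    k <- exp(-(-r:r)^2 / (2 * sg^2))
    k <- k / sum(k)
    arr <- .conv1(arr, ax, k)
  }
  arr[!grid$mask] <- 0
  arr
}

# zero-padded 1D convolution of a 3D array along one axis
.conv1 <- function(arr, axis, k) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) {
    sh <- j - r - 1L
    src <- seq_len(n) + sh
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
  }
  b <- array(out, dim = d[perm])
  aperm(b, order(perm))
}
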