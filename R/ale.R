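#' Spatial uncertainty kernel specification
#'
#' ALE models each reported focus as a 3D Gaussian whose width combines two
#' empirically motivated variance components: between-subject variability
#' (shrinking with the square root of the sample size) and between-template
#' variability (a floor that does not shrink). The literature-derived
#' constants are not universal, so both are configurable; the defaults
#' approximate the commonly used empirical estimates.
#'
#' @param sigma_subject_mm between-subject spatial uncertainty scale (mm).
#' @param sigma_template_mm between-template uncertainty scale (mm).
#' @param truncation_sigma kernel support cut-off, in multiples of the
#'   per-experiment sigma (>= 3 so that the discarded mass is negligible).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma_subject_mm = 5.0, sigma_template_mm = 2.4,
                        truncation_sigma = 3.5) {
  if (sigma_subject_mm <= 0 || sigma_template_mm <= 0)
    stop("kernel sigmas must be > 0")
  if (truncation_sigma < 3)
    stop("truncation_sigma must be >= 3")
  structure(list(sigma_subject_mm = sigma_subject_mm,
                 sigma_template_mm = sigma_template_mm,
                 truncation_sigma = truncation_sigma),
            class = "kernel_spec")
}

#' Per-experiment kernel width
#'
#' `sqrt(sigma_template^2 + sigma_subject^2 / n)`: strictly decreasing in
#' the subject count, with the between-template sigma as asymptote.
#'
#' @param n_subjects positive integer subject count.
#' @param spec a [kernel_spec()].
#' @return kernel standard deviation in mm.
#' @export
kernel_sigma <- function(n_subjects, spec = kernel_spec()) {
  if (any(n_subjects < 1)) stop("n_subjects must be >= 1")
  sqrt(spec$sigma_template_mm^2 + spec$sigma_subject_mm^2 / n_subjects)
}

# Truncated, voxel-discretized Gaussian kernel for a given sigma and grid.
# The Gaussian is evaluated at voxel centres within truncation_sigma * sigma
# and normalized to unit sum over that support, so that kernel values are
# probabilities (the mass a focus assigns to each voxel). Cached per
# (sigma, grid geometry).
.kernel_cache <- new.env(parent = emptyenv())

.kernel_offsets <- function(sigma, grid, trunc_sigma = 3.5) {
  key <- paste(sprintf("%.8g", sigma), sprintf("%.6g", trunc_sigma),
               paste(grid$shape, collapse = ","),
               paste(sprintf("%.8g", grid$affine), collapse = ","),
               sep = "|")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  A3 <- grid$affine[1:3, 1:3]
  vs <- sqrt(colSums(A3^2))
  rad <- trunc_sigma * sigma
  rv <- ceiling(rad / vs)
  d <- as.matrix(expand.grid(-rv[1]:rv[1], -rv[2]:rv[2], -rv[3]:rv[3]))
  dmm <- d %*% t(A3)
  d2 <- rowSums(dmm^2)
  keep <- d2 <= rad^2
  d <- d[keep, , drop = FALSE]
  w <- exp(-d2[keep] / (2 * sigma^2))
  w <- w / sum(w)
  out <- list(d = d, w = w)
  .kernel_cache[[key]] <- out
  out
}

# Sparse modeled-activation values for kernels stamped at 0-based voxel
# positions, combined by the voxel-wise maximum (non-additive rule) and
# restricted to the brain mask. Returns list(idx = 1-based flat indices,
# values).
.stamp_max <- function(vox, sigma, grid, trunc_sigma = 3.5) {
  ko <- .kernel_offsets(sigma, grid, trunc_sigma)
  n <- nrow(vox)
  m <- nrow(ko$d)
  ijk <- ko$d[rep(seq_len(m), times = n), , drop = FALSE] +
    vox[rep(seq_len(n), each = m), , drop = FALSE]
  w <- rep(ko$w, times = n)
  ok <- in_grid(grid, ijk)
  ijk <- ijk[ok, , drop = FALSE]
  w <- w[ok]
  if (nrow(ijk) == 0L) return(list(idx = integer(), values = numeric()))
  fl <- flat_index(grid, ijk)
  keep <- grid$mask[fl]
  fl <- fl[keep]
  w <- w[keep]
  if (length(fl) == 0L) return(list(idx = integer(), values = numeric()))
  o <- order(fl, -w)
  fl <- fl[o]
  w <- w[o]
  first <- !duplicated(fl)
  list(idx = fl[first], values = w[first])
}

# Sparse MA map of one experiment (internal workhorse).
.ma_sparse <- function(exp, grid, spec = kernel_spec()) {
  sigma <- kernel_sigma(exp$n_subjects, spec)
  sp <- .stamp_max(foci_voxels(exp, grid), sigma, grid, spec$truncation_sigma)
  sp$experiment_id <- exp$id
  sp$sigma <- sigma
  sp
}

.ma_sparse_list <- function(db, spec = kernel_spec()) {
  lapply(db$experiments, .ma_sparse, grid = db$grid, spec = spec)
}

#' Modeled activation (MA) map of one experiment
#'
#' Each focus contributes a truncated, mass-normalized Gaussian; per voxel
#' the contributions are combined by their maximum, not their sum, so that
#' multiple nearby foci of one experiment cannot inflate local evidence.
#'
#' @param exp an [experiment()].
#' @param grid a [brain_grid()].
#' @param spec a [kernel_spec()].
#' @return A [stat_map()] of kind `"ale"` (probabilities in \[0,1)), with
#'   the experiment id in attribute `experiment_id`.
#' @export
compute_ma_map <- function(exp, grid, spec = kernel_spec()) {
  sp <- .ma_sparse(exp, grid, spec)
  if (length(sp$idx) == 0L)
    warning("experiment '", exp$id,
            "' has no focus within mask + truncation; MA map is all zero")
  v <- numeric(prod(grid$shape))
  v[sp$idx] <- sp$values
  m <- stat_map(grid, v, kind = "ale")
  attr(m, "experiment_id") <- exp$id
  m
}

#' ALE map: voxel-wise union of MA maps
#'
#' `ALE(v) = 1 - prod_i (1 - MA_i(v))`, the probability that at least one
#' experiment activates at the voxel under independence across experiments.
#'
#' @param x a [coordinate_database()] or a list of [experiment()] objects.
#' @param grid a [brain_grid()] (taken from the database when `x` is one).
#' @param spec a [kernel_spec()].
#' @return A [stat_map()] of kind `"ale"`.
#' @export
compute_ale_map <- function(x, grid = NULL, spec = kernel_spec()) {
  if (inherits(x, "coordinate_database")) {
    grid <- x$grid
    exps <- x$experiments
  } else {
    exps <- x
  }
  if (length(exps) == 0L) stop("at least one experiment is required")
  stopifnot(inherits(grid, "brain_grid"))
  sps <- lapply(exps, .ma_sparse, grid = grid, spec = spec)
  .ale_from_sparse(sps, grid)
}

.ale_from_sparse <- function(sps, grid) {
  L <- numeric(prod(grid$shape))
  for (sp in sps) L[sp$idx] <- L[sp$idx] + log1p(-sp$values)
  stat_map(grid, pmax(-expm1(L), 0), kind = "ale")
}

#' Analytic null distribution of the ALE score
#'
#' Null model of random spatial association: each experiment keeps its
#' within-experiment focus pattern (hence its distribution of MA values over
#' in-mask voxels) but experiments are combined at independently drawn
#' voxels. The null is tabulated by successive histogram combination: the
#' running ALE histogram is folded with each experiment's MA histogram via
#' `ale_new = 1 - (1 - ale) (1 - ma)`, with probability mass accumulated
#' into bins of width `bin_width`.
#'
#' @param ma_maps list of MA maps: outputs of [compute_ma_map()] (or the
#'   package's internal sparse form).
#' @param grid the shared [brain_grid()].
#' @param bin_width histogram resolution in ALE units.
#' @return An object of class `ale_null` with fields `bin_width`,
#'   `probabilities` (mass per bin, bin b at index b+1), `values`
#'   (mass-weighted representative ALE value per bin) and `n_experiments`.
#' @export
build_histogram_null <- function(ma_maps, grid, bin_width = 1e-5) {
  stopifnot(inherits(grid, "brain_grid"), bin_width > 0,
            length(ma_maps) >= 1L)
  hs <- lapply(ma_maps, .ma_hist, grid = grid, bw = bin_width)
  maxv <- vapply(hs, `[[`, 0, "maxval")
  Kmax <- as.integer(floor((1 - prod(1 - maxv)) / bin_width)) + 2L
  probs <- numeric(Kmax + 1L)
  vals <- numeric(Kmax + 1L)
  probs[hs[[1]]$bins + 1L] <- hs[[1]]$probs
  vals[hs[[1]]$bins + 1L] <- hs[[1]]$values
  if (length(hs) > 1L) {
    for (h in hs[-1L]) {
      r <- .fold_null(probs, vals, h, bin_width, Kmax)
      probs <- r$probs
      vals <- r$values
    }
  }
  tot <- sum(probs)
  if (abs(tot - 1) > 1e-9)
    stop("null probabilities do not sum to 1 (", format(tot), ")")
  structure(list(bin_width = bin_width, probabilities = probs,
                 values = vals, n_experiments = length(hs)),
            class = "ale_null")
}

# In-mask MA histogram of one experiment: occupied 0-based bins, their
# probability mass, and the mass-weighted mean of the exact MA values per
# bin (bin 0 includes all out-of-support voxels).
.ma_hist <- function(m, grid, bw) {
  if (inherits(m, "stat_map")) {
    v <- m$values[grid$mask]
    n_in <- length(v)
    nz <- v[v > 0]
  } else {
    n_in <- sum(grid$mask)
    nz <- m$values
  }
  bins <- floor(nz / bw)
  agg <- rowsum(rep(1 / n_in, length(bins)), bins)
  vag <- rowsum(nz / n_in, bins)
  b <- as.integer(rownames(agg))
  p <- agg[, 1]
  vsum <- vag[, 1]
  if (!any(b == 0L)) {
    b <- c(0L, b)
    p <- c(0, p)
    vsum <- c(0, vsum)
  }
  p[b == 0L] <- p[b == 0L] + (n_in - length(nz)) / n_in
  list(bins = b, probs = p, values = vsum / p,
       maxval = if (length(nz)) max(nz) else 0)
}

.fold_null <- function(pa_vec, pav, h, bw, Kmax) {
  .fold_null_cpp(pa_vec, pav, as.numeric(h$values), as.numeric(h$probs),
                 bw, as.integer(Kmax))
}

#' @export
print.ale_null <- function(x, ...) {
  cat(sprintf("<ale_null> %d experiments, %d bins of width %g\n",
              x$n_experiments, length(x$probabilities), x$bin_width))
  invisible(x)
}

# Survival function over bins: S[b+1] = P(bin >= b), closed upper tail.
.null_survival <- function(null) {
  rev(cumsum(rev(null$probabilities)))
}

# Smallest 0-based bin whose closed upper tail is below voxel_p
# (suprathreshold iff ALE >= bin * bin_width); Inf when unattainable.
.ale_threshold_bin <- function(null, voxel_p) {
  S <- .null_survival(null)
  b <- which(S < voxel_p)
  if (length(b) == 0L) return(Inf)
  b[1] - 1L
}

#' Voxel-wise p-values of an ALE map under the histogram null
#'
#' `p(v)` is the null mass at bins greater than or equal to the bin of the
#' observed ALE score (the proportion of equal-or-higher random values).
#' Scores above the null support receive the smallest positive tail mass,
#' never exactly zero. Outside-mask voxels carry the zero marker.
#'
#' @param ale a [stat_map()] of kind `"ale"`.
#' @param null an `ale_null` built from the same experiment set.
#' @return A [stat_map()] of kind `"p"`.
#' @export
ale_p_map <- function(ale, null) {
  stopifnot(inherits(ale, "stat_map"), inherits(null, "ale_null"))
  S <- .null_survival(null)
  K <- length(S) - 1L
  pfloor <- min(S[S > 0])
  v <- ale$values[ale$grid$mask]
  bins <- floor(v / null$bin_width)
  p <- ifelse(bins > K, pfloor, S[pmin(bins, K) + 1L])
  p <- pmin(pmax(p, pfloor), 1)
  out <- numeric(prod(ale$grid$shape))
  out[which(ale$grid$mask)] <- p
  stat_map(ale$grid, out, kind = "p")
}

# ---- connected components ----------------------------------------------

.conn_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  deg <- rowSums(offs != 0)
  switch(as.character(connectivity),
         "6" = offs[deg == 1, , drop = FALSE],
         "18" = offs[deg <= 2, , drop = FALSE],
         "26" = offs,
         stop("connectivity must be 6, 18 or 26"))
}

# Label the connected components of a set of 1-based flat indices.
# Returns an integer vector of component labels parallel to `active`
# (provisional ids in discovery order).
.connected_components <- function(active, shape, connectivity = 26) {
  if (length(active) == 0L) return(integer())
  offs <- .conn_offsets(connectivity)
  nx <- shape[1]
  nxy <- shape[1] * shape[2]
  lab <- array(0L, dim = shape)
  lab[active] <- -1L
  nc <- 0L
  m <- nrow(offs)
  for (s in active) {
    if (lab[s] != -1L) next
    nc <- nc + 1L
    lab[s] <- nc
    frontier <- s
    while (length(frontier)) {
      ijk <- arrayInd(frontier, shape)
      n <- nrow(ijk)
      cand <- ijk[rep(seq_len(n), each = m), , drop = FALSE] +
        offs[rep(seq_len(m), times = n), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= shape[1] &
        cand[, 2] >= 1 & cand[, 2] <= shape[2] &
        cand[, 3] >= 1 & cand[, 3] <= shape[3]
      cand <- cand[ok, , drop = FALSE]
      fl <- cand[, 1] + (cand[, 2] - 1L) * nx + (cand[, 3] - 1L) * nxy
      fl <- unique(fl[lab[fl] == -1L])
      if (length(fl)) lab[fl] <- nc
      frontier <- fl
    }
  }
  lab[active]
}

.max_cluster_size <- function(active, shape, connectivity = 26) {
  if (length(active) == 0L) return(0L)
  max(tabulate(.connected_components(active, shape, connectivity)))
}

#' Connected-component cluster table of a thresholded map
#'
#' Groups the nonzero in-mask voxels of a map into connected clusters and
#' tabulates them in the conventional peak-table format. Cluster ids are
#' deterministic: sorted by size (descending), ties broken by peak mm
#' coordinate.
#'
#' @param mask_map a binary or thresholded [stat_map()] (zero means
#'   nonsignificant).
#' @param connectivity neighborhood: 6 (faces), 18 (+edges) or 26
#'   (+corners).
#' @return A data frame with columns `cluster_id`, `size_voxels`, `peak_x`,
#'   `peak_y`, `peak_z` (mm), `peak_value`, sorted by size descending; the
#'   relabeled integer label array is attached as attribute `labels`.
#' @export
label_clusters <- function(mask_map, connectivity = 26) {
  stopifnot(inherits(mask_map, "stat_map"))
  grid <- mask_map$grid
  active <- which(mask_map$values != 0 & grid$mask)
  lab <- .connected_components(active, grid$shape, connectivity)
  nc <- if (length(lab)) max(lab) else 0L
  if (nc == 0L) {
    tab <- data.frame(cluster_id = integer(), size_voxels = integer(),
                      peak_x = numeric(), peak_y = numeric(),
                      peak_z = numeric(), peak_value = numeric())
    attr(tab, "labels") <- array(0L, dim = grid$shape)
    return(tab)
  }
  rows <- lapply(seq_len(nc), function(k) {
    idx <- active[lab == k]
    vals <- mask_map$values[idx]
    pk <- idx[which.max(vals)]            # ties: lowest flat index
    mm <- vox2mm(grid, arrayInd(pk, grid$shape) - 1L)
    data.frame(size_voxels = length(idx), peak_x = mm[1], peak_y = mm[2],
               peak_z = mm[3], peak_value = max(vals), provisional = k)
  })
  tab <- do.call(rbind, rows)
  o <- order(-tab$size_voxels, tab$peak_x, tab$peak_y, tab$peak_z)
  tab <- tab[o, , drop = FALSE]
  tab$cluster_id <- seq_len(nrow(tab))
  relab <- integer(nc)
  relab[tab$provisional] <- tab$cluster_id
  labarr <- array(0L, dim = grid$shape)
  labarr[active] <- relab[lab]
  tab$provisional <- NULL
  rownames(tab) <- NULL
  tab <- tab[, c("cluster_id", "size_voxels", "peak_x", "peak_y", "peak_z",
                 "peak_value")]
  attr(tab, "labels") <- labarr
  tab
}

#' Cluster-level family-wise error thresholding of an ALE p-map
#'
#' Voxels below the cluster-forming threshold are grouped into connected
#' clusters; a Monte Carlo null of the maximum cluster size is built by
#' relocating every experiment's foci to uniformly random in-mask voxels
#' (per-experiment focus counts and kernels preserved) and recording the
#' largest suprathreshold cluster per iteration. A cluster survives when
#' its permutation-style p-value `(1 + #{null >= size}) / (1 + n_mc)` is at
#' most `cluster_alpha`. Surviving voxels are reported as Z scores via the
#' inverse-normal transform of the voxel p-values.
#'
#' @param p_map voxel p-value [stat_map()] from [ale_p_map()].
#' @param db the [coordinate_database()] (the selected experiment subset)
#'   the p-map was computed from.
#' @param spec a [kernel_spec()].
#' @param voxel_p cluster-forming voxel-level threshold.
#' @param cluster_alpha cluster-level familywise alpha.
#' @param n_mc number of Monte Carlo iterations (>= 100).
#' @param seed RNG seed for the Monte Carlo relocation null.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param null optional precomputed `ale_null` for the experiment set
#'   (rebuilt when absent).
#' @return A list of class `cluster_fwe_result`: `z_map` (thresholded Z
#'   [stat_map()]), `clusters` (cluster table with `cluster_p` and
#'   `significant` columns; only surviving clusters keep nonzero voxels in
#'   `z_map`), `null_max_sizes`, `ale_threshold`.
#' @export
cluster_fwe_threshold <- function(p_map, db, spec = kernel_spec(),
                                  voxel_p = 0.001, cluster_alpha = 0.05,
                                  n_mc = 1000, seed = NULL,
                                  connectivity = 26, null = NULL) {
  stopifnot(inherits(p_map, "stat_map"), inherits(db, "coordinate_database"))
  if (n_mc < 100) stop("n_mc must be >= 100")
  grid <- p_map$grid
  if (is.null(null))
    null <- build_histogram_null(.ma_sparse_list(db, spec), grid,
                                 bin_width = 1e-5)
  S <- .null_survival(null)
  pfloor <- min(S[S > 0])
  supra <- grid$mask & p_map$values > 0 & p_map$values < voxel_p
  zvals <- numeric(prod(grid$shape))
  act <- which(supra)
  empty <- function() {
    tab <- label_clusters(stat_map(grid, numeric(prod(grid$shape))),
                          connectivity)
    tab$cluster_p <- numeric(0)
    tab$significant <- logical(0)
    structure(list(z_map = stat_map(grid, zvals, kind = "z"),
                   clusters = tab, null_max_sizes = integer(0),
                   ale_threshold = NA_real_),
              class = "cluster_fwe_result")
  }
  if (length(act) == 0L) return(empty())
  zvals[act] <- stats::qnorm(pmax(p_map$values[act], pfloor),
                             lower.tail = FALSE)
  zmap <- stat_map(grid, zvals, kind = "z")
  tab <- label_clusters(zmap, connectivity)
  labarr <- attr(tab, "labels")

  thr_bin <- .ale_threshold_bin(null, voxel_p)
  thr_val <- thr_bin * null$bin_width
  sigmas <- vapply(db$experiments, function(e) kernel_sigma(e$n_subjects, spec), 0)
  nf <- vapply(db$experiments, function(e) nrow(e$foci), 0L)
  mask_flat <- which(grid$mask)
  if (!is.null(seed)) set.seed(seed)
  null_max <- integer(n_mc)
  L <- numeric(prod(grid$shape))
  for (it in seq_len(n_mc)) {
    L[] <- 0
    for (e in seq_along(sigmas)) {
      vox <- arrayInd(sample(mask_flat, nf[e], replace = TRUE),
                      grid$shape) - 1L
      sp <- .stamp_max(vox, sigmas[e], grid, spec$truncation_sigma)
      L[sp$idx] <- L[sp$idx] + log1p(-sp$values)
    }
    hot <- mask_flat[-expm1(L[mask_flat]) >= thr_val]
    null_max[it] <- .max_cluster_size(hot, grid$shape, connectivity)
  }
  tab$cluster_p <- (1 + vapply(tab$size_voxels,
                               function(s) sum(null_max >= s), 0L)) /
    (1 + n_mc)
  tab$significant <- tab$cluster_p <= cluster_alpha
  keep_lab <- tab$cluster_id[tab$significant]
  zvals[!(labarr %in% keep_lab)] <- 0
  structure(list(z_map = stat_map(grid, zvals, kind = "z"),
                 clusters = tab, null_max_sizes = null_max,
                 ale_threshold = thr_val),
            class = "cluster_fwe_result")
}

#' @export
print.cluster_fwe_result <- function(x, ...) {
  cat(sprintf("<cluster_fwe_result> %d cluster(s), %d significant\n",
              nrow(x$clusters), sum(x$clusters$significant)))
  invisible(x)
}
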