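#' Specification of a synthetic foci database with planted structure
#'
#' Emulates a large coordinate database: experiments fall into classes;
#' each class co-activates a set of spherical regions with stated
#' probabilities (one focus sampled near each co-activating region centre),
#' on top of uniformly distributed background foci, and draws taxonomy
#' labels with class-specific inclusion probabilities. Everything planted
#' is recorded in a manifest so that downstream recovery can be scored
#' against ground truth.
#'
#' Subject counts default to the 8-30 range typical of fMRI group studies,
#' which exercises the sample-size dependence of the uncertainty kernel.
#'
#' @param regions named list of length-3 mm centres.
#' @param region_radius_mm planted region radius; foci are drawn from an
#'   isotropic Gaussian with sd `region_radius_mm / 2` around the centre,
#'   truncated to the brain mask.
#' @param classes named list; each element a list with fields `n`
#'   (experiment count), `coactivation` (named numeric vector of per-region
#'   co-activation probabilities), `labels` (named numeric vector of label
#'   inclusion probabilities).
#' @param n_background_foci length-2 integer range of uniform background
#'   foci per experiment.
#' @param n_subjects length-2 integer range of subject counts.
#' @param rng_seed RNG seed.
#' @return A list of class `planted_network_spec`.
#' @export
planted_network_spec <- function(regions, region_radius_mm = 6,
                                 classes, n_background_foci = c(5, 12),
                                 n_subjects = c(8, 30), rng_seed = 1) {
  stopifnot(is.list(regions), length(regions) >= 1L,
            !is.null(names(regions)), all(nzchar(names(regions))))
  if (region_radius_mm <= 0) stop("region_radius_mm must be > 0")
  stopifnot(is.list(classes), length(classes) >= 1L,
            !is.null(names(classes)))
  for (cl in classes) {
    if (is.null(cl$n) || cl$n < 0) stop("class counts must be >= 0")
    co <- cl$coactivation
    if (length(co)) {
      if (any(co < 0 | co > 1)) stop("co-activation probabilities in [0,1]")
      if (!all(names(co) %in% names(regions)))
        stop("co-activation names must be region names")
    }
    lb <- cl$labels
    if (length(lb) && any(lb < 0 | lb > 1))
      stop("label probabilities in [0,1]")
  }
  if (any(n_background_foci < 0) || n_background_foci[2] < n_background_foci[1])
    stop("invalid background foci range")
  if (any(n_subjects < 1) || n_subjects[2] < n_subjects[1])
    stop("invalid subject count range")
  structure(list(regions = regions, region_radius_mm = region_radius_mm,
                 classes = classes, n_background_foci = n_background_foci,
                 n_subjects = n_subjects, rng_seed = rng_seed),
            class = "planted_network_spec")
}

#' Generate a synthetic coordinate database
#'
#' @param spec a [planted_network_spec()].
#' @param grid a [brain_grid()]; every planted region centre must fall
#'   inside its brain mask.
#' @return A list with `db` (a [coordinate_database()]) and `manifest`
#'   (data frame: experiment id, class, subject count, one logical
#'   `hit_<region>` column per region, background focus count, drawn
#'   labels as a `;`-joined string).
#' @export
generate_database <- function(spec, grid) {
  stopifnot(inherits(spec, "planted_network_spec"),
            inherits(grid, "brain_grid"))
  for (rn in names(spec$regions)) {
    v <- nearest_voxel(grid, spec$regions[[rn]])
    if (!in_grid(grid, v) || !grid$mask[flat_index(grid, v)])
      stop("region '", rn, "' lies outside the brain mask")
  }
  set.seed(spec$rng_seed)
  mask_flat <- which(grid$mask)
  mask_mm <- vox2mm(grid, arrayInd(mask_flat, grid$shape) - 1L)
  sd_foci <- spec$region_radius_mm / 2
  draw_region_focus <- function(center) {
    for (k in 1:100) {
      f <- center + stats::rnorm(3, 0, sd_foci)
      v <- nearest_voxel(grid, f)
      if (in_grid(grid, v) && grid$mask[flat_index(grid, v)])
        return(f)
    }
    as.numeric(center)   # mask-truncation fallback: snap to the centre
  }
  exps <- list()
  rows <- list()
  for (cn in names(spec$classes)) {
    cl <- spec$classes[[cn]]
    for (i in seq_len(cl$n)) {
      id <- sprintf("%s_%03d", cn, i)
      nsub <- sample(spec$n_subjects[1]:spec$n_subjects[2], 1)
      hits <- stats::setNames(logical(length(spec$regions)),
                              names(spec$regions))
      foci <- NULL
      for (rn in names(cl$coactivation)) {
        if (stats::runif(1) < cl$coactivation[[rn]]) {
          hits[rn] <- TRUE
          foci <- rbind(foci, draw_region_focus(spec$regions[[rn]]))
        }
      }
      nbg <- sample(spec$n_background_foci[1]:spec$n_background_foci[2], 1)
      if (nbg > 0) {
        bg <- mask_mm[sample(length(mask_flat), nbg, replace = TRUE), ,
                      drop = FALSE]
        foci <- rbind(foci, bg)
      }
      if (is.null(foci))   # degenerate spec: ensure at least one focus
        foci <- mask_mm[sample(length(mask_flat), 1), , drop = FALSE]
      labs <- names(cl$labels)[stats::runif(length(cl$labels)) < cl$labels]
      exps[[length(exps) + 1L]] <- experiment(id, nsub, foci, labs)
      row <- data.frame(id = id, class = cn, n_subjects = nsub,
                        n_background = nbg,
                        labels = paste(labs, collapse = ";"))
      for (rn in names(spec$regions))
        row[[paste0("hit_", rn)]] <- hits[[rn]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(db = coordinate_database(exps, grid), manifest = manifest)
}

#' Specification of synthetic resting-state data with planted networks
#'
#' Each participant receives, per planted network, a shared band-limited
#' time course mixed into the network's voxels at an amplitude chosen so
#' that the expected within-network voxel-pairwise correlation matches the
#' target; motion- and tissue-coupled nuisance signal and white noise are
#' added on top. The first volumes are marked as pre-saturation dummies in
#' the manifest and carry a decaying signal offset.
#'
#' @param networks named list of planted-network centres: a length-3 mm
#'   coordinate per network, or a matrix with one centre per row for a
#'   multi-blob network sharing one time course.
#' @param network_radius_mm sphere radius of each network.
#' @param course_band_hz length-2 frequency band (Hz) of the shared
#'   network courses.
#' @param target_correlation desired expected within-network pairwise
#'   correlation, in (0,1).
#' @param motion_amp,tissue_amp per-voxel coupling amplitude scales of the
#'   nuisance signals.
#' @param noise_sd white noise standard deviation.
#' @param n_participants,n_timepoints,tr_seconds acquisition layout
#'   (`n_timepoints` includes the `n_dummies` initial dummy volumes).
#' @param n_dummies initial dummy volumes.
#' @param rng_seed RNG seed.
#' @return A list of class `planted_rs_spec`.
#' @export
planted_rs_spec <- function(networks, network_radius_mm = 8,
                            course_band_hz = c(0.01, 0.08),
                            target_correlation = 0.5, motion_amp = 0.5,
                            tissue_amp = 0.5, noise_sd = 1,
                            n_participants = 10, n_timepoints = 132,
                            tr_seconds = 2.5, n_dummies = 4, rng_seed = 1) {
  stopifnot(is.list(networks), length(networks) >= 1L,
            !is.null(names(networks)))
  nyq <- 1 / (2 * tr_seconds)
  if (course_band_hz[1] <= 0 || course_band_hz[2] <= course_band_hz[1] ||
      course_band_hz[2] >= nyq)
    stop("course band must lie within (0, Nyquist)")
  if (target_correlation <= 0 || target_correlation >= 1)
    stop("target_correlation must be in (0,1); a target of 1 requires ",
         "zero noise, the feasible bound")
  if (n_timepoints - n_dummies < 32L) stop("n_timepoints too small")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(networks = networks, network_radius_mm = network_radius_mm,
                 course_band_hz = course_band_hz,
                 target_correlation = target_correlation,
                 motion_amp = motion_amp, tissue_amp = tissue_amp,
                 noise_sd = noise_sd, n_participants = n_participants,
                 n_timepoints = n_timepoints, tr_seconds = tr_seconds,
                 n_dummies = n_dummies, rng_seed = rng_seed),
            class = "planted_rs_spec")
}

# band-limited unit-variance course of length nt
.band_course <- function(nt, tr, band) {
  x <- stats::rnorm(nt)
  fr <- (seq_len(nt) - 1) / (nt * tr)
  fr <- pmin(fr, 1 / tr - fr)
  g <- as.numeric(fr >= band[1] & fr <= band[2])
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / nt
  (y - mean(y)) / stats::sd(y)
}

#' Generate synthetic resting-state datasets
#'
#' @param spec a [planted_rs_spec()].
#' @param grid a [brain_grid()].
#' @return A list with `datasets` (list of [ts_dataset()]), `networks`
#'   (named list of [seed_region()] masks of the planted networks) and
#'   `manifest` (per-participant mixing amplitudes and dummy count).
#' @export
generate_rs_dataset <- function(spec, grid) {
  stopifnot(inherits(spec, "planted_rs_spec"), inherits(grid, "brain_grid"))
  set.seed(spec$rng_seed)
  nets <- lapply(names(spec$networks), function(nm) {
    ctrs <- rbind2mat(spec$networks[[nm]])
    mask <- array(FALSE, dim = grid$shape)
    for (i in seq_len(nrow(ctrs)))
      mask <- mask |
        make_sphere_seed(ctrs[i, ], spec$network_radius_mm, grid, nm)$mask
    seed_region(nm, mask, grid)
  })
  names(nets) <- names(spec$networks)
  rho <- spec$target_correlation
  amp <- spec$noise_sd * sqrt(rho / (1 - rho))
  if (spec$noise_sd == 0) amp <- 1
  nt <- spec$n_timepoints
  mask_flat <- which(grid$mask)
  nv <- length(mask_flat)
  net_cols <- lapply(nets, function(s) which(s$mask[mask_flat]))
  datasets <- vector("list", spec$n_participants)
  rows <- list()
  for (p in seq_len(spec$n_participants)) {
    id <- sprintf("sub%03d", p)
    courses <- lapply(spec$networks, function(...)
      .band_course(nt, spec$tr_seconds, spec$course_band_hz))
    motion <- apply(matrix(stats::rnorm(nt * 6, 0, 0.02), nt, 6), 2, cumsum)
    tissue <- matrix(0, nt, 3)
    for (j in 1:3) {
      ar <- stats::rnorm(nt)
      for (t in 2:nt) ar[t] <- 0.8 * ar[t - 1] + ar[t] * 0.6
      tissue[, j] <- 100 + ar
    }
    motion_sig <- scale(motion)
    tissue_sig <- scale(tissue)
    M <- matrix(stats::rnorm(nt * nv, 0, spec$noise_sd), nt, nv)
    for (k in seq_along(net_cols))
      M[, net_cols[[k]]] <- M[, net_cols[[k]]] + amp * courses[[k]]
    if (spec$motion_amp > 0) {
      beta <- matrix(stats::rnorm(6 * nv, 0, spec$motion_amp), 6, nv)
      M <- M + motion_sig %*% beta
    }
    if (spec$tissue_amp > 0) {
      beta <- matrix(stats::rnorm(3 * nv, 0, spec$tissue_amp), 3, nv)
      M <- M + tissue_sig %*% beta
    }
    if (spec$n_dummies > 0) {
      sat <- 5 * spec$noise_sd * exp(-(seq_len(nt) - 1))
      M <- M + sat
    }
    arr <- array(0, dim = c(grid$shape, nt))
    flat <- matrix(0, prod(grid$shape), nt)
    flat[mask_flat, ] <- t(M)
    arr <- array(flat, dim = c(grid$shape, nt))
    datasets[[p]] <- ts_dataset(arr, spec$tr_seconds, motion, tissue, grid,
                                id = id)
    rows[[p]] <- data.frame(id = id, network_amplitude = amp,
                            noise_sd = spec$noise_sd,
                            n_dummies = spec$n_dummies)
  }
  manifest <- do.call(rbind, rows)
  list(datasets = datasets, networks = nets, manifest = manifest,
       spec = spec)
}

#' Hand-checkable toy study fixture
#'
#' A four-experiment database on an 8x8x8 grid with a single spherical
#' seed, small enough that every downstream quantity (ALE union values,
#' decoding counts) can be verified by direct arithmetic. The expected
#' values shipped alongside are frozen from first-principles computation
#' of the kernel mass and union formula.
#'
#' @return A list: `grid`, `db`, `seed`, `spec` (kernel spec) and
#'   `expected` (named reference quantities: `ale_peak` at the densest
#'   voxel, `selected_ids`, decoding counts for the label `"reward"`).
#' @export
toy_fixture <- function() {
  grid <- brain_grid(c(8, 8, 8), voxel_mm = 2,
                     mask = array(TRUE, dim = c(8, 8, 8)))
  spec <- kernel_spec()
  exps <- list(
    experiment("e1", 20, rbind(c(0, 0, 0), c(4, 0, 0)), c("reward")),
    experiment("e2", 10, rbind(c(0, 0, 0)), c("reward", "memory")),
    experiment("e3", 15, rbind(c(0, 2, 0)), c("memory")),
    experiment("e4", 12, rbind(c(-6, -6, -6)), c("motor")))
  db <- coordinate_database(exps, grid)
  seed <- make_sphere_seed(c(0, 0, 0), 2.5, grid, "toy_seed")
  # frozen from first-principles arithmetic: per experiment the normalized
  # Gaussian mass at the densest voxel, combined by the union formula
  list(grid = grid, db = db, seed = seed, spec = spec,
       expected = list(
         ale_peak_mm = c(-1, -1, -1),
         ale_peak = 0.06682993103834,
         selected_ids = c("e1", "e2", "e3"),
         reward = list(n_total = 4L, n_seed = 3L, n_label = 2L,
                       n_both = 2L)))
}
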