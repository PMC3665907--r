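# small synthetic participant with controllable voxel time courses
toy_ts <- function(grid, nt = 64, tr = 2.5, fill = function(nv, nt)
  matrix(stats::rnorm(nt * nv), nt, nv)) {
  nv <- sum(grid$mask)
  M <- fill(nv, nt)
  flat <- matrix(0, prod(grid$shape), nt)
  flat[which(grid$mask), ] <- t(M)
  ts_dataset(array(flat, dim = c(grid$shape, nt)), tr,
             matrix(stats::rnorm(nt * 6, 0, 0.05), nt, 6),
             matrix(100 + stats::rnorm(nt * 3), nt, 3), grid)
}

make_cmap <- function(grid, zflat, id, seed_name = "s") {
  z <- numeric(prod(grid$shape))
  z[which(grid$mask)] <- zflat
  structure(list(participant_id = id, seed_name = seed_name,
                 r = stat_map(grid, tanh(z), kind = "r"),
                 z = stat_map(grid, z, kind = "z")),
            class = "connectivity_map")
}

test_that("nuisance matrix has the documented structure", {
  g <- small_grid(8)
  set.seed(1)
  ds <- toy_ts(g, nt = 40)
  nm <- build_nuisance_matrix(ds)
  expect_equal(ncol(nm$x), 31L)                 # 2*(6+6+3) + intercept
  expect_equal(nm$labels[31], "intercept")
  # all non-intercept columns are centered
  expect_lt(max(abs(colMeans(nm$x[, 1:30]))), 1e-10)
  # linear motion drift: derivative constant after t=1, square quadratic
  ds2 <- ds
  ds2$motion[, 1] <- seq_len(40)
  nm2 <- build_nuisance_matrix(ds2)
  d1 <- nm2$x[, nm2$labels == "dmotion1"] # centered backward difference
  expect_lt(max(abs(d1[-1] - d1[2])), 1e-12)
  # constant motion column: derivative dropped with a warning
  ds3 <- ds
  ds3$motion[, 2] <- 5
  expect_warning(nm3 <- build_nuisance_matrix(ds3), "dmotion2")
  expect_false("dmotion2" %in% nm3$labels)
  # projecting the matrix out of its own columns annihilates them
  res <- qr.resid(qr(nm$x), nm$x)
  expect_lt(max(abs(res)), 1e-8)
  # row-count mismatch errors
  expect_error(ts_dataset(ds$data, 2.5, ds$motion[-1, ], ds$tissue_means,
                          g), "one 6-column row")
})

test_that("nuisance regression removes regressors and spares orthogonal signal", {
  g <- small_grid(8)
  set.seed(2)
  ds <- toy_ts(g, nt = 48)
  nm <- build_nuisance_matrix(ds)
  nv <- sum(g$mask)
  # voxel 1: a motion regressor; voxel 2: orthogonal to all regressors
  M <- coactmeta:::.ts_matrix(ds)
  M[, 1] <- ds$motion[, 3]
  ortho <- qr.resid(qr(nm$x), stats::rnorm(48))
  M[, 2] <- ortho + 7               # constant offsets live in the intercept
  ds <- coactmeta:::.ts_set_matrix(ds, M)
  out <- regress_nuisance(ds, nm)
  Mo <- coactmeta:::.ts_matrix(out)
  expect_lt(sqrt(sum(Mo[, 1]^2)), 1e-8)
  expect_lt(max(abs(Mo[, 2] - ortho)), 1e-8)
})

test_that("planted signal survives regression while nuisance is annihilated", {
  g <- small_grid(8)
  set.seed(3)
  nt <- 96
  ds0 <- toy_ts(g, nt = nt)
  nm0 <- build_nuisance_matrix(ds0)
  # a planted signal not confounded with the nuisance space
  sig <- as.numeric(scale(qr.resid(qr(nm0$x), stats::rnorm(nt))))
  ds <- toy_ts(g, nt = nt, fill = function(nv, nt)
    matrix(stats::rnorm(nt * nv, 0, 0.3), nt, nv) + outer(sig, rep(1, nv)))
  ds$motion <- ds0$motion
  ds$tissue_means <- ds0$tissue_means
  # couple motion into all voxels
  M <- coactmeta:::.ts_matrix(ds) + outer(ds$motion[, 1] * 5, rep(1, sum(g$mask)))
  ds <- coactmeta:::.ts_set_matrix(ds, M)
  out <- regress_nuisance(ds)
  Mo <- coactmeta:::.ts_matrix(out)
  cm <- as.numeric(scale(ds$motion[, 1]))
  corr_nuis <- abs(crossprod(Mo, cm)) / (sqrt(colSums(Mo^2)) * sqrt(nt - 1))
  expect_lt(max(corr_nuis), 1e-10)
  corr_sig <- cor(rowMeans(Mo), sig)
  expect_gt(corr_sig, 0.95)
})

test_that("band-pass meets pass- and stop-band contracts", {
  g <- cube_grid(4)
  nt <- 256
  tr <- 2.5
  tt <- (seq_len(nt) - 1) * tr
  amp_after <- function(freq) {
    ds <- toy_ts(g, nt = nt, tr = tr, fill = function(nv, nt)
      outer(sin(2 * pi * freq * tt), rep(1, nv)))
    out <- bandpass_filter(ds)
    M <- coactmeta:::.ts_matrix(out)
    # discard edge effects of the finite window
    core <- 20:(nt - 20)
    max(abs(M[core, 1]))
  }
  df <- 1 / (nt * tr)
  expect_gt(amp_after(25 * df), 0.95)    # ~0.039 Hz, mid-passband
  expect_lt(amp_after(114 * df), 0.10)   # ~0.178 Hz, > 2x upper edge
  expect_lt(amp_after(3 * df), 0.10)     # ~0.0047 Hz, < half lower edge

  # white noise: spectral mass outside the (tapered) band is small
  set.seed(4)
  ds <- toy_ts(g, nt = nt, tr = tr)
  out <- bandpass_filter(ds)
  x <- coactmeta:::.ts_matrix(out)[, 1]
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_len(nt) - 1) / (nt * tr)
  fr <- pmin(fr, 1 / tr - fr)
  inband <- fr >= 0.005 & fr <= 0.085
  expect_lt(sum(sp[!inband]) / sum(sp), 0.10)

  expect_error(bandpass_filter(ds, 0.01, 0.3), "Nyquist")
})

test_that("seed eigenvariate recovers shared structure with the sign rule", {
  g <- small_grid(9)
  seed <- make_sphere_seed(c(0, 0, 0), 4, g)
  nt <- 64
  set.seed(5)
  course <- as.numeric(scale(stats::rnorm(nt)))
  # all seed voxels share one time course
  ds <- toy_ts(g, nt = nt, fill = function(nv, nt) {
    M <- matrix(stats::rnorm(nt * nv, 0, 1), nt, nv)
    sel <- which(seed$mask[which(g$mask)])
    M[, sel] <- outer(course, rep(2, length(sel)))
    M
  })
  ev <- seed_eigenvariate(ds, seed)
  expect_gt(abs(cor(ev, course)), 1 - 1e-10)
  expect_equal(stats::sd(ev), 1)
  # rank-1 plus small noise
  ds2 <- toy_ts(g, nt = nt, fill = function(nv, nt) {
    M <- matrix(stats::rnorm(nt * nv, 0, 0.05), nt, nv)
    sel <- which(seed$mask[which(g$mask)])
    M[, sel] <- M[, sel] + outer(course, stats::runif(length(sel), 0.5, 2))
    M
  })
  expect_gt(cor(seed_eigenvariate(ds2, seed), course), 0.99)
  # two anti-correlated halves: output correlates non-negatively with mean
  ds3 <- toy_ts(g, nt = nt, fill = function(nv, nt) {
    M <- matrix(stats::rnorm(nt * nv, 0, 0.01), nt, nv)
    sel <- which(seed$mask[which(g$mask)])
    h1 <- sel[seq_len(floor(length(sel) / 2))]
    h2 <- setdiff(sel, h1)
    M[, h1] <- M[, h1] + outer(course, rep(1, length(h1)))
    M[, h2] <- M[, h2] - outer(course, rep(0.9, length(h2)))
    M
  })
  ev3 <- seed_eigenvariate(ds3, seed)
  mcourse <- rowMeans(coactmeta:::.ts_matrix(ds3)[, seed$mask[which(g$mask)]])
  expect_gte(cor(ev3, mcourse), 0)
})

test_that("correlation maps use clipped Fisher z with flags", {
  expect_lt(abs(atanh(0.5) - 0.5493), 1e-4)
  rr <- seq(-0.999, 0.999, length.out = 101)
  expect_lt(max(abs(tanh(atanh(rr)) - rr)), 1e-12)

  g <- small_grid(9)
  seed <- make_sphere_seed(c(0, 0, 0), 2.1, g)
  nt <- 256
  set.seed(6)
  course <- as.numeric(scale(stats::rnorm(nt)))
  ds <- toy_ts(g, nt = nt, fill = function(nv, nt) {
    M <- matrix(stats::rnorm(nt * nv), nt, nv)
    sel <- which(seed$mask[which(g$mask)])
    M[, sel] <- outer(course, rep(1, length(sel)))
    M[, 1] <- 0                       # zero-variance voxel
    M
  })
  cm <- seed_correlation_map(ds, seed)
  mask_flat <- which(g$mask)
  sel <- which(seed$mask[mask_flat])
  # voxel equal to the eigenvariate: r clipped below 1, z finite
  expect_equal(cm$r$values[mask_flat[sel[1]]], 1 - 1e-7)
  expect_true(all(is.finite(cm$z$values)))
  # zero-variance voxel flagged with r = 0
  expect_equal(cm$r$values[mask_flat[1]], 0)
  expect_true(cm$flag_zero_variance[mask_flat[1]])
  # independent-noise voxels rarely exceed |r| = 0.2 at T = 256
  noise_r <- cm$r$values[mask_flat[-c(1, sel)]]
  expect_gt(mean(abs(noise_r) < 0.2), 0.95)
})

test_that("group inference detects planted effects and respects nulls", {
  g <- small_grid(12)
  nv <- sum(g$mask)
  region <- which(make_sphere_seed(c(0, 0, 0), 6, g)$mask[which(g$mask)])
  # all-zero maps: nothing significant
  maps0 <- lapply(1:10, function(i) make_cmap(g, numeric(nv), paste0("s", i)))
  r0 <- group_inference(maps0, n_perm = 150, rng_seed = 1)
  expect_equal(sum(r0$clusters$significant), 0L)

  # planted mean 0.3, sd 0.3, n = 30 in a ~100-voxel region
  set.seed(7)
  hits <- vapply(1:10, function(rep) {
    maps <- lapply(1:30, function(i) {
      z <- stats::rnorm(nv, 0, 0.3)
      z[region] <- z[region] + 0.3
      make_cmap(g, z, sprintf("s%02d", i))
    })
    res <- group_inference(maps, n_perm = 150, rng_seed = rep)
    sig <- res$z_map$values[which(g$mask)[region]]
    any(sig > 0)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("paired seed contrast is directional and swap-antisymmetric", {
  g <- small_grid(12)
  nv <- sum(g$mask)
  region <- which(make_sphere_seed(c(5, 5, 0), 5, g)$mask[which(g$mask)])
  set.seed(8)
  maps_a <- list(); maps_b <- list()
  for (i in 1:20) {
    za <- stats::rnorm(nv, 0, 0.25)
    za[region] <- za[region] + 0.35
    zb <- stats::rnorm(nv, 0, 0.25)
    maps_a[[i]] <- make_cmap(g, za, sprintf("s%02d", i), "A")
    maps_b[[i]] <- make_cmap(g, zb, sprintf("s%02d", i), "B")
  }
  ct <- rs_seed_contrast(maps_a, maps_b, n_perm = 150, rng_seed = 2)
  in_region <- which(g$mask)[region]
  expect_gt(sum(ct$a_gt_b$z_map$values[in_region] > 0), 0)
  expect_equal(sum(ct$b_gt_a$z_map$values != 0), 0)
  # swapping inputs swaps the directions exactly
  ct2 <- rs_seed_contrast(maps_b, maps_a, n_perm = 150, rng_seed = 2)
  expect_identical(ct2$b_gt_a$z_map$values, ct$a_gt_b$z_map$values)
  expect_identical(ct2$a_gt_b$z_map$values, ct$b_gt_a$z_map$values)
  # identical inputs: empty both ways
  ct3 <- rs_seed_contrast(maps_a, maps_a, n_perm = 150, rng_seed = 3)
  expect_equal(sum(ct3$a_gt_b$z_map$values != 0), 0)
  # unpaired inputs refused
  expect_error(rs_seed_contrast(maps_a, rev(maps_b)), "paired")
})

test_that("spatial smoothing has the stated FWHM and composes", {
  g <- cube_grid(17)
  ctr <- c(9, 9, 9)
  delta <- array(0, dim = g$shape)
  delta[ctr[1], ctr[2], ctr[3]] <- 1
  sm <- smooth_volume(stat_map(g, delta), fwhm_mm = 5)
  # mass conservation for an interior blob
  expect_lt(abs(sum(sm$values) - 1), 0.01)
  # measured FWHM within half a voxel of 5 mm
  prof <- sm$values[, ctr[2], ctr[3]]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  width_mm <- (diff(above)) * 2       # voxel size 2 mm
  expect_lt(abs(width_mm - 5), 2)
  # constant field unchanged away from the mask edge
  cst <- smooth_volume(stat_map(g, array(3, dim = g$shape)), 5)
  interior <- array(FALSE, dim = g$shape)
  interior[5:13, 5:13, 5:13] <- TRUE
  expect_lt(max(abs(cst$values[interior] - 3)), 1e-10)
  # smoothing twice with f matches once with f*sqrt(2)
  twice <- smooth_volume(sm, 5)
  once <- smooth_volume(stat_map(g, delta), 5 * sqrt(2))
  expect_lt(max(abs(twice$values - once$values)), 0.02 * max(once$values))
})

test_that("the regress-then-filter order is a real contract", {
  g <- cube_grid(5)
  set.seed(9)
  ds <- toy_ts(g, nt = 64)
  a <- bandpass_filter(regress_nuisance(ds))
  b <- regress_nuisance(bandpass_filter(ds))
  expect_gt(max(abs(a$data - b$data)), 1e-6)
})
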