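# Shared fixtures: small centred grids and planted databases built in code.

small_grid <- function(n = 16, voxel_mm = 2) {
  brain_grid(rep(n, 3), voxel_mm = voxel_mm)
}

cube_grid <- function(n = 8, voxel_mm = 2) {
  brain_grid(rep(n, 3), voxel_mm = voxel_mm,
             mask = array(TRUE, dim = rep(n, 3)))
}

# database of experiments with uniformly random in-mask foci (no structure)
uniform_db <- function(grid, n_exp = 6, n_foci = c(5, 12),
                       n_subjects = c(8, 30)) {
  mask_flat <- which(grid$mask)
  mm <- vox2mm(grid, arrayInd(mask_flat, grid$shape) - 1L)
  exps <- lapply(seq_len(n_exp), function(i) {
    nf <- sample(n_foci[1]:n_foci[2], 1)
    experiment(sprintf("u%03d", i), sample(n_subjects[1]:n_subjects[2], 1),
               mm[sample(length(mask_flat), nf, replace = TRUE), ,
                  drop = FALSE])
  })
  coordinate_database(exps, grid)
}

# spec with a seed region and a seed-linked target region planted on a
# centred grid; seed-class experiments co-activate seed and target
planted_macm_spec <- function(grid, n_seed_class = 40, n_background = 60,
                              coact = 1.0, rng_seed = 1,
                              target_b = FALSE) {
  half <- max(vox2mm(grid, grid$shape - 1L)) / 2
  regions <- list(seed = c(0, 0, 0),
                  target = c(-half, -half / 2, 0),
                  target_b = c(half, half / 2, 0))
  classes <- list(
    seedlinked = list(n = n_seed_class,
                      coactivation = c(seed = 1, target = coact),
                      labels = c(reward = 0.8, memory = 0.1)),
    background = list(n = n_background, coactivation = c(),
                      labels = c(reward = 0.05, memory = 0.3)))
  if (target_b)
    classes$blinked <- list(n = n_seed_class,
                            coactivation = c(target_b = 1),
                            labels = c(memory = 0.1))
  planted_network_spec(regions = regions, region_radius_mm = 4,
                       classes = classes, n_background_foci = c(3, 6),
                       rng_seed = rng_seed)
}

expect_same_values <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a$values - b$values)), tol)
}

# compact planted two-seed study: seed A co-activates (and co-fluctuates
# with) target X, seed B with target Y; target Z is planted in the foci
# database only, never in the resting-state covariance
study_layout <- list(seedA = c(-9, 5, 0), seedB = c(9, 5, 0),
                     targetX = c(-6, -11, 0), targetY = c(6, -11, 0),
                     targetZ = c(0, 13, 0))

study_config <- function(rng_seed = 1, out_dir = NULL, with_rs = TRUE,
                         n_participants = 10) {
  g <- brain_grid(rep(20, 3), voxel_mm = 2)
  L <- study_layout
  dbspec <- planted_network_spec(
    regions = L, region_radius_mm = 4,
    classes = list(
      alinked = list(n = 30, coactivation = c(seedA = 1, targetX = 1),
                     labels = c(reward = 0.8, common = 0.5)),
      azlinked = list(n = 15, coactivation = c(seedA = 1, targetZ = 1),
                      labels = c(reward = 0.6, common = 0.5)),
      blinked = list(n = 30, coactivation = c(seedB = 1, targetY = 1),
                     labels = c(memory = 0.8, common = 0.5)),
      background = list(n = 40, coactivation = c(),
                        labels = c(reward = 0.05, memory = 0.05,
                                   common = 0.5, other = 0.3))),
    n_background_foci = c(2, 4), rng_seed = rng_seed)
  rsspec <- NULL
  if (with_rs)
    rsspec <- planted_rs_spec(
      networks = list(netA = rbind(L$seedA, L$targetX),
                      netB = rbind(L$seedB, L$targetY)),
      network_radius_mm = 5, target_correlation = 0.5,
      n_participants = n_participants, n_timepoints = 68,
      rng_seed = rng_seed + 500)
  analysis_config(
    db = dbspec,
    seeds = list(list(center = L$seedA, radius = 5, name = "A"),
                 list(center = L$seedB, radius = 5, name = "B")),
    rs = rsspec, grid = g, n_mc = 100, n_perm = 150, rs_n_perm = 150,
    rng_seed = rng_seed, out_dir = out_dir)
}
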