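# Shared layout of the synthetic two-seed study driven by the numbered
# analysis scripts. Everything is generated from fixed seeds, so each
# script can rebuild exactly the inputs it needs.

suppressPackageStartupMessages(library(coactmeta))

RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

STUDY_SEED <- 2026
study_grid <- function() brain_grid(rep(20, 3), voxel_mm = 2)

# two seeds; seed A co-activates and co-fluctuates with target X, seed B
# with target Y; target Z co-activates seed A in the foci database only
LAYOUT <- list(seedA = c(-9, 5, 0), seedB = c(9, 5, 0),
               targetX = c(-6, -11, 0), targetY = c(6, -11, 0),
               targetZ = c(0, 13, 0))

db_spec <- function(seed = STUDY_SEED) planted_network_spec(
  regions = LAYOUT, region_radius_mm = 4,
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
  n_background_foci = c(2, 4), rng_seed = seed)

rs_spec <- function(seed = STUDY_SEED + 500) planted_rs_spec(
  networks = list(netA = rbind(LAYOUT$seedA, LAYOUT$targetX),
                  netB = rbind(LAYOUT$seedB, LAYOUT$targetY)),
  network_radius_mm = 5, target_correlation = 0.5,
  n_participants = 10, n_timepoints = 68, rng_seed = seed)

study_seeds <- function(grid) list(
  A = make_sphere_seed(LAYOUT$seedA, 5, grid, "A"),
  B = make_sphere_seed(LAYOUT$seedB, 5, grid, "B"))

write_tsv <- function(tab, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("  wrote ", path)
  invisible(path)
}
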