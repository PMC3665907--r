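#' Meta-analytic connectivity modeling for one seed
#'
#' Composition of the MACM stages: select the experiments with at least one
#' focus inside the seed, compute their ALE map, derive voxel p-values from
#' the random-spatial-association histogram null, and apply cluster-level
#' family-wise error thresholding. All intermediates are retained in the
#' result.
#'
#' @param db the full [coordinate_database()].
#' @param seed a [seed_region()] on the database grid.
#' @param spec a [kernel_spec()].
#' @param voxel_p cluster-forming voxel-level threshold.
#' @param cluster_alpha cluster-level familywise alpha.
#' @param n_mc Monte Carlo iterations for the cluster-size null.
#' @param rng_seed RNG seed for the Monte Carlo null.
#' @param bin_width ALE histogram resolution.
#' @param connectivity cluster connectivity (6, 18, 26).
#' @return A list of class `macm_result`: `seed_name`, `experiment_ids`,
#'   `ale`, `p`, `null`, `fwe` (a `cluster_fwe_result`), plus the
#'   thresholds used.
#' @export
run_macm <- function(db, seed, spec = kernel_spec(), voxel_p = 0.001,
                     cluster_alpha = 0.05, n_mc = 1000, rng_seed = NULL,
                     bin_width = 1e-5, connectivity = 26) {
  sel <- suppressWarnings(select_experiments_by_seed(db, seed))
  if (length(sel) == 0L)
    stop("no experiments activate seed '", seed$name, "'")
  sps <- .ma_sparse_list(sel, spec)
  ale <- .ale_from_sparse(sps, sel$grid)
  null <- build_histogram_null(sps, sel$grid, bin_width = bin_width)
  p <- ale_p_map(ale, null)
  fwe <- cluster_fwe_threshold(p, sel, spec, voxel_p = voxel_p,
                               cluster_alpha = cluster_alpha, n_mc = n_mc,
                               seed = rng_seed, connectivity = connectivity,
                               null = null)
  structure(list(seed_name = seed$name, experiment_ids = db_ids(sel),
                 selection = sel, ale = ale, p = p, null = null, fwe = fwe,
                 voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 n_mc = n_mc, rng_seed = rng_seed),
            class = "macm_result")
}

#' @export
print.macm_result <- function(x, ...) {
  cat(sprintf("<macm_result> seed '%s': %d experiments, %d significant cluster(s)\n",
              x$seed_name, length(x$experiment_ids),
              sum(x$fwe$clusters$significant)))
  invisible(x)
}

#' Random partition of a pooled experiment list
#'
#' Uniformly random split of `pool` into two groups of exactly `n_a` and
#' `n_b` elements (the sizes of the two original selections), drawing from
#' the caller's RNG stream.
#'
#' @param n_a,n_b group sizes; must satisfy `n_a + n_b = length(pool)`.
#' @param pool list of experiments (or any list).
#' @return list with elements `a` and `b`.
#' @export
split_pool <- function(n_a, n_b, pool) {
  if (n_a + n_b != length(pool))
    stop("n_a + n_b must equal the pool size (", length(pool), ")")
  if (n_a < 0 || n_b < 0) stop("group sizes must be non-negative")
  take <- if (n_a > 0) sample(length(pool), n_a) else integer()
  list(a = pool[take], b = if (length(take)) pool[-take] else pool)
}

#' Permutation difference analysis between two seeds' co-activation maps
#'
#' The observed statistic is the voxel-wise difference of the two seeds'
#' ALE maps. Experiments contributing to either selection are pooled and
#' repeatedly re-divided at random, preserving the counts of A-only,
#' B-only and shared experiments (a shared experiment enters both permuted
#' groups), and the ALE difference of each random division is recorded.
#' The per-voxel empirical probability that the observed difference exceeds
#' the permuted ones, `(1 + #{perm < obs}) / (1 + n_perm)`, is thresholded
#' at `prob_threshold` and inclusively masked by the corresponding seed's
#' thresholded main effect.
#'
#' Swapping the two seeds exactly swaps the directional outputs: the
#' permutation stream is generated in a canonical seed order internally.
#'
#' @param db the full [coordinate_database()].
#' @param seed_a,seed_b the two [seed_region()]s.
#' @param n_perm number of random divisions (>= 100; 10000 reproduces the
#'   conventional setting, smaller values are for scaled-down studies).
#' @param rng_seed RNG seed for the permutation stream.
#' @param spec a [kernel_spec()].
#' @param prob_threshold posterior-probability cut-off for a direction.
#' @param macm_a,macm_b optional precomputed [run_macm()] results for the
#'   two seeds (recomputed when absent; the main-effect masks come from
#'   them).
#' @param ... further arguments passed to [run_macm()] when recomputing.
#' @return A list of class `macm_difference_result`: observed difference
#'   map `diff`, per-direction probability maps `prob_a_gt_b`,
#'   `prob_b_gt_a`, thresholded directional maps `a_gt_b`, `b_gt_a`
#'   (observed difference masked by threshold and main effect),
#'   `n_permutations`, `rng_seed`.
#' @export
macm_difference <- function(db, seed_a, seed_b, n_perm = 1000,
                            rng_seed = NULL, spec = kernel_spec(),
                            prob_threshold = 0.95, macm_a = NULL,
                            macm_b = NULL, ...) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.null(macm_a))
    macm_a <- run_macm(db, seed_a, spec = spec, rng_seed = rng_seed, ...)
  if (is.null(macm_b))
    macm_b <- run_macm(db, seed_b, spec = spec, rng_seed = rng_seed, ...)
  grid <- db$grid
  ids_a <- macm_a$experiment_ids
  ids_b <- macm_b$experiment_ids
  if (setequal(ids_a, ids_b))
    warning("the two seeds select identical experiment sets; ",
            "the difference analysis is empty by construction")

  # canonical internal order so that swapping arguments mirrors exactly
  swapped <- seed_b$name < seed_a$name ||
    (seed_b$name == seed_a$name && length(ids_b) < length(ids_a))
  if (swapped) {
    tmp <- macm_a; macm_a <- macm_b; macm_b <- tmp
    tmp <- ids_a; ids_a <- ids_b; ids_b <- tmp
  }

  pool_ids <- union(ids_a, ids_b)
  pool <- db$experiments[match(pool_ids, db_ids(db))]
  sps <- .ma_sparse_list(coordinate_database(pool, grid), spec)
  only_a <- setdiff(ids_a, ids_b)
  only_b <- setdiff(ids_b, ids_a)
  both <- intersect(ids_a, ids_b)
  n_oa <- length(only_a); n_ob <- length(only_b); n_bo <- length(both)

  mask_flat <- which(grid$mask)
  np <- length(pool)
  logs <- lapply(sps, function(sp) {
    keep <- match(sp$idx, mask_flat)       # mask-restricted positions
    list(pos = keep[!is.na(keep)], lv = log1p(-sp$values[!is.na(keep)]))
  })
  ale_of <- function(members) {
    L <- numeric(length(mask_flat))
    for (k in members) L[logs[[k]]$pos] <- L[logs[[k]]$pos] + logs[[k]]$lv
    -expm1(L)
  }
  idx_a <- match(ids_a, pool_ids)
  idx_b <- match(ids_b, pool_ids)
  obs <- ale_of(idx_a) - ale_of(idx_b)

  if (!is.null(rng_seed)) set.seed(rng_seed)
  cnt_lt <- integer(length(mask_flat))
  cnt_gt <- integer(length(mask_flat))
  for (it in seq_len(n_perm)) {
    perm <- sample.int(np)
    g_both <- perm[seq_len(n_bo)]
    g_a <- c(g_both, perm[n_bo + seq_len(n_oa)])
    g_b <- c(g_both, perm[n_bo + n_oa + seq_len(n_ob)])
    d <- ale_of(g_a) - ale_of(g_b)
    cnt_lt <- cnt_lt + (d < obs)
    cnt_gt <- cnt_gt + (d > obs)
  }
  prob_a <- (1 + cnt_lt) / (1 + n_perm)
  prob_b <- (1 + cnt_gt) / (1 + n_perm)

  full <- function(v) {
    out <- numeric(prod(grid$shape))
    out[mask_flat] <- v
    out
  }
  diff_map <- stat_map(grid, full(obs), kind = "diff")
  pa_map <- stat_map(grid, full(prob_a), kind = "prob")
  pb_map <- stat_map(grid, full(prob_b), kind = "prob")
  main_a <- macm_a$fwe$z_map$values != 0
  main_b <- macm_b$fwe$z_map$values != 0
  a_vals <- full(obs * (prob_a > prob_threshold))
  a_vals[!main_a] <- 0
  b_vals <- full(-obs * (prob_b > prob_threshold))
  b_vals[!main_b] <- 0
  a_map <- stat_map(grid, a_vals, kind = "diff")
  b_map <- stat_map(grid, b_vals, kind = "diff")

  res <- list(seed_a = macm_a$seed_name, seed_b = macm_b$seed_name,
              diff = diff_map, prob_a_gt_b = pa_map, prob_b_gt_a = pb_map,
              a_gt_b = a_map, b_gt_a = b_map,
              macm_a = macm_a, macm_b = macm_b,
              n_permutations = n_perm, prob_threshold = prob_threshold,
              rng_seed = rng_seed)
  if (swapped) {
    res <- list(seed_a = res$seed_b, seed_b = res$seed_a,
                diff = stat_map(grid, -res$diff$values, kind = "diff"),
                prob_a_gt_b = res$prob_b_gt_a, prob_b_gt_a = res$prob_a_gt_b,
                a_gt_b = res$b_gt_a, b_gt_a = res$a_gt_b,
                macm_a = res$macm_b, macm_b = res$macm_a,
                n_permutations = n_perm, prob_threshold = prob_threshold,
                rng_seed = rng_seed)
  }
  structure(res, class = "macm_difference_result")
}

#' @export
print.macm_difference_result <- function(x, ...) {
  cat(sprintf("<macm_difference_result> %s vs %s: %d / %d voxels per direction (%d permutations)\n",
              x$seed_a, x$seed_b, sum(x$a_gt_b$values != 0),
              sum(x$b_gt_a$values != 0), x$n_permutations))
  invisible(x)
}

#' Minimum-statistic conjunction of thresholded maps
#'
#' Voxel-wise minimum across two or more thresholded, non-negative maps
#' (zero meaning nonsignificant): the result is nonzero exactly where every
#' input is nonzero. Commutative, associative and idempotent.
#'
#' @param ... two or more thresholded [stat_map()]s on the same grid, or a
#'   single list of them.
#' @return A [stat_map()] holding the voxel-wise minimum.
#' @export
conjunction_min <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && is.list(maps[[1]]) &&
      !inherits(maps[[1]], "stat_map"))
    maps <- maps[[1]]
  if (length(maps) < 2L) stop("conjunction requires at least 2 maps")
  stopifnot(all(vapply(maps, inherits, TRUE, "stat_map")))
  grid <- maps[[1]]$grid
  for (m in maps[-1]) if (!same_grid(grid, m$grid))
    stop("conjunction inputs live on different grids")
  for (m in maps) if (any(m$values < 0))
    stop("conjunction inputs must be thresholded non-negative maps")
  vals <- Reduce(pmin, lapply(maps, `[[`, "values"))
  stat_map(grid, vals, kind = maps[[1]]$kind)
}
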