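#' Configuration of a full two-seed connectivity study
#'
#' Collects every input and threshold of the four-stage analysis in one
#' serializable object: the coordinate database (or a generator spec), the
#' two seeds, the resting-state datasets (or a generator spec), the engine
#' parameters, and per-stage RNG seeds. The documented defaults are the
#' conventional thresholds of coordinate-based connectivity studies
#' (voxel p < 0.001, cluster alpha 0.05, decoding alpha 0.001, FDR q
#' 0.05, 0.01-0.08 Hz band, 5 mm FWHM).
#'
#' @param db a [coordinate_database()] or a [planted_network_spec()].
#' @param seeds list of exactly two [seed_region()]s (or lists
#'   `list(center=, radius=, name=)` to build spheres).
#' @param rs a list of [ts_dataset()] lists per participant, a
#'   [planted_rs_spec()], or `NULL` to skip the resting-state arm.
#' @param grid the study [brain_grid()].
#' @param kernel a [kernel_spec()].
#' @param voxel_p,cluster_alpha,n_mc,n_perm ALE/MACM thresholds and
#'   permutation counts.
#' @param rs_band_hz,rs_fwhm_mm,rs_n_perm resting-state band, smoothing
#'   and sign-flip count.
#' @param alpha_decoding,fdr_q decoding thresholds.
#' @param rng_seed master RNG seed; per-stage seeds derive from it.
#' @param out_dir optional output directory for maps, tables and
#'   provenance.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(db, seeds, rs = NULL, grid,
                            kernel = kernel_spec(), voxel_p = 0.001,
                            cluster_alpha = 0.05, n_mc = 1000,
                            n_perm = 10000, rs_band_hz = c(0.01, 0.08),
                            rs_fwhm_mm = 5, rs_n_perm = 1000,
                            alpha_decoding = 0.001, fdr_q = 0.05,
                            rng_seed = 1, out_dir = NULL) {
  stopifnot(inherits(grid, "brain_grid"), length(seeds) == 2L)
  structure(list(db = db, seeds = seeds, rs = rs, grid = grid,
                 kernel = kernel, voxel_p = voxel_p,
                 cluster_alpha = cluster_alpha, n_mc = n_mc,
                 n_perm = n_perm, rs_band_hz = rs_band_hz,
                 rs_fwhm_mm = rs_fwhm_mm, rs_n_perm = rs_n_perm,
                 alpha_decoding = alpha_decoding, fdr_q = fdr_q,
                 rng_seed = rng_seed, out_dir = out_dir),
            class = "analysis_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full two-seed connectivity study
#'
#' Executes, per seed, co-activation mapping (MACM) and resting-state
#' group inference; the seed-vs-seed difference analyses in both
#' modalities; the cross-modality minimum-statistic conjunctions (per
#' seed, and of the two directional differences); and the functional
#' decoding stage (individual profiles, FDR-corrected contrast with
#' main-effect masking, and the both-seed conjunction). Identical
#' configuration and seeds give bit-identical results.
#'
#' @param config an [analysis_config()].
#' @return A list of class `study_bundle` with elements `macm` (per seed),
#'   `macm_diff`, `rs` (per seed), `rs_contrast`, `conjunction` (per-seed
#'   cross-modality maps, difference conjunctions, across-seed map),
#'   `decoding`, `provenance`. Maps and tables are also written under
#'   `config$out_dir` when set.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  grid <- config$grid
  seed_offset <- function(k) (config$rng_seed * 1000L + k) %% 2147483647L

  db <- .stage("database", {
    if (inherits(config$db, "planted_network_spec"))
      generate_database(config$db, grid)$db
    else config$db
  })
  seeds <- .stage("seeds", lapply(config$seeds, function(s) {
    if (inherits(s, "seed_region")) s
    else make_sphere_seed(s$center, s$radius, grid,
                          name = if (is.null(s$name)) "seed" else s$name)
  }))
  sa <- seeds[[1]]; sb <- seeds[[2]]

  macm <- .stage("macm", lapply(seq_along(seeds), function(k)
    run_macm(db, seeds[[k]], spec = config$kernel,
             voxel_p = config$voxel_p, cluster_alpha = config$cluster_alpha,
             n_mc = config$n_mc, rng_seed = seed_offset(k))))
  names(macm) <- c(sa$name, sb$name)

  macm_diff <- .stage("macm_difference",
    macm_difference(db, sa, sb, n_perm = config$n_perm,
                    rng_seed = seed_offset(3), spec = config$kernel,
                    macm_a = macm[[1]], macm_b = macm[[2]]))

  rs_res <- NULL; rs_contrast <- NULL; rs_maps <- NULL
  if (!is.null(config$rs)) {
    rs_maps <- .stage("rs_preprocess", {
      dsets <- if (inherits(config$rs, "planted_rs_spec"))
        generate_rs_dataset(config$rs, grid)$datasets
      else config$rs
      lapply(dsets, function(ds) {
        ds <- drop_dummies(ds)
        ds <- smooth_volume(ds, config$rs_fwhm_mm)
        ds <- regress_nuisance(ds)
        ds <- bandpass_filter(ds, config$rs_band_hz[1], config$rs_band_hz[2])
        lapply(seeds, function(s) seed_correlation_map(ds, s))
      })
    })
    rs_res <- .stage("rs_group", lapply(seq_along(seeds), function(k)
      group_inference(lapply(rs_maps, `[[`, k), voxel_p = config$voxel_p,
                      cluster_alpha = config$cluster_alpha,
                      n_perm = config$rs_n_perm,
                      rng_seed = seed_offset(10 + k))))
    names(rs_res) <- c(sa$name, sb$name)
    rs_contrast <- .stage("rs_contrast",
      rs_seed_contrast(lapply(rs_maps, `[[`, 1), lapply(rs_maps, `[[`, 2),
                       voxel_p = config$voxel_p,
                       cluster_alpha = config$cluster_alpha,
                       n_perm = config$rs_n_perm,
                       rng_seed = seed_offset(13)))
  }

  conjunction <- .stage("conjunction", {
    out <- list()
    if (!is.null(rs_res)) {
      out$per_seed <- lapply(seq_along(seeds), function(k)
        cross_modality_conjunction(macm[[k]], rs_res[[k]]))
      names(out$per_seed) <- c(sa$name, sb$name)
      out$diff_a_gt_b <- conjunction_min(
        .abs_map(macm_diff$a_gt_b), rs_contrast$a_gt_b$z_map)
      out$diff_b_gt_a <- conjunction_min(
        .abs_map(macm_diff$b_gt_a), rs_contrast$b_gt_a$z_map)
      out$across_seeds <- conjunction_min(out$per_seed[[1]],
                                          out$per_seed[[2]])
    } else {
      out$across_seeds <- conjunction_min(macm[[1]]$fwe$z_map,
                                          macm[[2]]$fwe$z_map)
    }
    out
  })

  decoding <- .stage("decoding", {
    ta <- decode_seed(db, sa, alpha_forward = config$alpha_decoding,
                      alpha_reverse = config$alpha_decoding)
    tb <- decode_seed(db, sb, alpha_forward = config$alpha_decoding,
                      alpha_reverse = config$alpha_decoding)
    ct <- contrast_decoding(db, sa, sb, q = config$fdr_q, decode_a = ta,
                            decode_b = tb)
    list(a = ta, b = tb, contrast = ct,
         conjunction = conjunction_decoding(ta, tb))
  })

  provenance <- list(
    package = "coactmeta",
    version = as.character(utils::packageVersion("coactmeta")),
    rng_seed = config$rng_seed,
    n_experiments = length(db),
    seeds = vapply(seeds, `[[`, "", "name"),
    thresholds = list(voxel_p = config$voxel_p,
                      cluster_alpha = config$cluster_alpha,
                      n_mc = config$n_mc, n_perm = config$n_perm,
                      rs_band_hz = config$rs_band_hz,
                      rs_fwhm_mm = config$rs_fwhm_mm,
                      rs_n_perm = config$rs_n_perm,
                      alpha_decoding = config$alpha_decoding,
                      fdr_q = config$fdr_q),
    kernel = unclass(config$kernel))

  bundle <- structure(list(macm = macm, macm_diff = macm_diff, rs = rs_res,
                           rs_contrast = rs_contrast,
                           conjunction = conjunction, decoding = decoding,
                           provenance = provenance, db = db, seeds = seeds),
                      class = "study_bundle")
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

.abs_map <- function(m) stat_map(m$grid, abs(m$values), kind = m$kind)

#' Cross-modality conjunction for one seed
#'
#' Minimum-statistic conjunction of a seed's thresholded co-activation
#' (MACM) Z map and its thresholded resting-state group Z map: voxels
#' connected to the seed in both task-constrained and task-free states.
#'
#' @param macm_result a [run_macm()] result.
#' @param rs_result a [group_inference()] result on the same grid.
#' @return A [stat_map()].
#' @export
cross_modality_conjunction <- function(macm_result, rs_result) {
  stopifnot(inherits(macm_result, "macm_result"),
            inherits(rs_result, "group_inference_result"))
  conjunction_min(macm_result$fwe$z_map, rs_result$z_map)
}

.write_bundle <- function(bundle, out_dir) {
  for (d in c("macm", "rs", "conj", "decoding"))
    dir.create(file.path(out_dir, d), recursive = TRUE,
               showWarnings = FALSE)
  wt <- function(tab, path)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  for (nm in names(bundle$macm)) {
    m <- bundle$macm[[nm]]
    write_stat_map(m$ale, file.path(out_dir, "macm",
                                    sprintf("ale_%s.nii.gz", nm)))
    write_stat_map(m$fwe$z_map,
                   file.path(out_dir, "macm",
                             sprintf("threshZ_%s.nii.gz", nm)))
    wt(m$fwe$clusters, file.path(out_dir, "macm",
                                 sprintf("clusters_%s.tsv", nm)))
  }
  d <- bundle$macm_diff
  write_stat_map(d$a_gt_b, file.path(out_dir, "macm",
      sprintf("diff_%s_gt_%s.nii.gz", d$seed_a, d$seed_b)))
  write_stat_map(d$b_gt_a, file.path(out_dir, "macm",
      sprintf("diff_%s_gt_%s.nii.gz", d$seed_b, d$seed_a)))
  if (!is.null(bundle$rs)) {
    for (nm in names(bundle$rs)) {
      write_stat_map(bundle$rs[[nm]]$z_map,
                     file.path(out_dir, "rs",
                               sprintf("threshZ_%s.nii.gz", nm)))
      wt(bundle$rs[[nm]]$clusters,
         file.path(out_dir, "rs", sprintf("clusters_%s.tsv", nm)))
    }
    for (nm in names(bundle$conjunction$per_seed))
      write_stat_map(bundle$conjunction$per_seed[[nm]],
                     file.path(out_dir, "conj",
                               sprintf("conj_%s.nii.gz", nm)))
  }
  write_stat_map(bundle$conjunction$across_seeds,
                 file.path(out_dir, "conj", "conj_across_seeds.nii.gz"))
  wt(bundle$decoding$a, file.path(out_dir, "decoding", "decode_a.tsv"))
  wt(bundle$decoding$b, file.path(out_dir, "decoding", "decode_b.tsv"))
  wt(bundle$decoding$contrast$a,
     file.path(out_dir, "decoding", "contrast_a.tsv"))
  wt(bundle$decoding$contrast$b,
     file.path(out_dir, "decoding", "contrast_b.tsv"))
  jsonlite::write_json(bundle$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  for (nm in names(x$macm))
    cat(sprintf("  macm '%s': %d experiments, %d significant cluster(s)\n",
                nm, length(x$macm[[nm]]$experiment_ids),
                sum(x$macm[[nm]]$fwe$clusters$significant)))
  if (!is.null(x$rs))
    for (nm in names(x$rs))
      cat(sprintf("  rs '%s': %d significant cluster(s)\n", nm,
                  sum(x$rs[[nm]]$clusters$significant)))
  cat(sprintf("  decoding conjunction: %s\n",
              if (length(x$decoding$conjunction))
                paste(x$decoding$conjunction, collapse = ", ")
              else "(none)"))
  invisible(x)
}
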