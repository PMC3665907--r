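#' Seed region: a named binary mask on a grid
#'
#' Seeds condition experiment selection (co-activation mapping) and
#' time-course extraction (resting-state correlation). The mask must be
#' non-empty and is restricted to the grid's brain mask.
#'
#' @param name seed name.
#' @param mask logical array of the grid's shape.
#' @param grid a [brain_grid()].
#' @return An object of class `seed_region`.
#' @export
seed_region <- function(name, mask, grid) {
  stopifnot(inherits(grid, "brain_grid"))
  if (!is.logical(mask) || !all(dim(mask) == grid$shape))
    stop("mask must be a logical array of the grid's shape")
  mask <- mask & grid$mask
  if (!any(mask)) stop("seed mask is empty (after brain-mask restriction)")
  structure(list(name = as.character(name), mask = mask, grid = grid),
            class = "seed_region")
}

#' @export
print.seed_region <- function(x, ...) {
  com <- center_of_mass(x)
  cat(sprintf("<seed_region> '%s': %d voxels, center of mass %.1f/%.1f/%.1f mm\n",
              x$name, sum(x$mask), com[1], com[2], com[3]))
  invisible(x)
}

#' Spherical seed around a mm centre
#'
#' The mask holds exactly the in-brain voxels whose centre lies within
#' `radius_mm` of `center_mm`. Spheres around published centres of mass
#' stand in for cluster masks that are not distributed with a paper.
#'
#' @param center_mm length-3 mm coordinate; must lie inside the grid's
#'   bounding box.
#' @param radius_mm sphere radius in mm (> 0).
#' @param grid a [brain_grid()].
#' @param name seed name.
#' @return A [seed_region()].
#' @export
make_sphere_seed <- function(center_mm, radius_mm, grid, name = "seed") {
  stopifnot(inherits(grid, "brain_grid"))
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  v <- mm2vox(grid, center_mm)
  if (any(v < -0.5) || any(v >= grid$shape - 0.5))
    stop("sphere centre lies outside the grid bounding box")
  ijk <- as.matrix(expand.grid(0:(grid$shape[1] - 1), 0:(grid$shape[2] - 1),
                               0:(grid$shape[3] - 1)))
  mm <- vox2mm(grid, ijk)
  d2 <- rowSums(sweep(mm, 2, as.numeric(center_mm))^2)
  mask <- array(d2 <= radius_mm^2, dim = grid$shape) & grid$mask
  if (!any(mask))
    stop("sphere at ", paste(center_mm, collapse = "/"),
         " (r=", radius_mm, " mm) intersects no in-brain voxel")
  seed_region(name, mask, grid)
}

#' Seed covering the whole brain mask
#' @param grid a [brain_grid()].
#' @param name seed name.
#' @export
whole_brain_seed <- function(grid, name = "whole_brain") {
  seed_region(name, grid$mask, grid)
}

#' Fuse a seed with its sagittal mirror
#'
#' Returns the union of the seed mask and its reflection x -> -x in mm
#' space, the standard robustness construction for asymmetric meta-analytic
#' seeds. Requires the x axis of the affine to be axis-aligned.
#'
#' @param seed a [seed_region()].
#' @return A [seed_region()] named `<name>+mirror` (idempotent: mirroring a
#'   fused seed returns it unchanged).
#' @export
mirror_seed <- function(seed) {
  stopifnot(inherits(seed, "seed_region"))
  g <- seed$grid
  if (any(abs(g$affine[1, 2:3]) > 1e-9) || any(abs(g$affine[2:3, 1]) > 1e-9))
    stop("mirror_seed requires an x-axis-aligned affine")
  idx <- which(seed$mask)
  ijk <- arrayInd(idx, g$shape) - 1L
  mm <- vox2mm(g, ijk)
  mm[, 1] <- -mm[, 1]
  v <- nearest_voxel(g, mm)
  ok <- in_grid(g, v)
  mask <- seed$mask
  mask[flat_index(g, v[ok, , drop = FALSE])] <- TRUE
  nm <- if (grepl("\\+mirror$", seed$name)) seed$name else
    paste0(seed$name, "+mirror")
  seed_region(nm, mask, g)
}

#' Unweighted centre of mass of a seed (mm)
#'
#' @param seed a [seed_region()].
#' @return length-3 mm coordinate: the mean of the mask voxel centres.
#' @export
center_of_mass <- function(seed) {
  stopifnot(inherits(seed, "seed_region"))
  ijk <- arrayInd(which(seed$mask), seed$grid$shape) - 1L
  colMeans(vox2mm(seed$grid, ijk))
}
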