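# Independent brute-force oracle for a modeled-activation map: dense
# evaluation of the truncated, mass-normalized Gaussian around each focus's
# assigned voxel, combined per voxel by the maximum. Deliberately written
# as plain loops over voxels, separate from the package's sparse stamping.
brute_ma <- function(exp, grid, spec = kernel_spec()) {
  sigma <- sqrt(spec$sigma_template_mm^2 +
                  spec$sigma_subject_mm^2 / exp$n_subjects)
  rad <- spec$truncation_sigma * sigma
  vs <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  # normalization constant over the full truncated offset ball
  rv <- ceiling(rad / vs)
  offs <- as.matrix(expand.grid(-rv[1]:rv[1], -rv[2]:rv[2], -rv[3]:rv[3]))
  dmm2 <- rowSums((offs %*% t(grid$affine[1:3, 1:3]))^2)
  norm_c <- sum(exp(-dmm2[dmm2 <= rad^2] / (2 * sigma^2)))
  fvox <- nearest_voxel(grid, exp$foci)
  fmm <- vox2mm(grid, fvox)
  out <- array(0, dim = grid$shape)
  ijk <- arrayInd(seq_len(prod(grid$shape)), grid$shape) - 1L
  mm <- vox2mm(grid, ijk)
  for (f in seq_len(nrow(fmm))) {
    d2 <- rowSums(sweep(mm, 2, fmm[f, ])^2)
    w <- ifelse(d2 <= rad^2, exp(-d2 / (2 * sigma^2)) / norm_c, 0)
    out <- pmax(out, array(w, dim = grid$shape))
  }
  out[!grid$mask] <- 0
  out
}

# independent enumeration oracle for the exact binomial upper tail
enum_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), 0))
}
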