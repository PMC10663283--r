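# Two-sample energy-distance permutation test (independent of the sampler
# code paths it is used to validate).  x, y: numeric vectors or matrices
# with observations in rows.  Returns a permutation p-value.

energy_statistic <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  nx <- nrow(x); ny <- nrow(y)
  dall <- as.matrix(stats::dist(rbind(x, y)))
  dxy <- dall[seq_len(nx), nx + seq_len(ny), drop = FALSE]
  dxx <- dall[seq_len(nx), seq_len(nx), drop = FALSE]
  dyy <- dall[nx + seq_len(ny), nx + seq_len(ny), drop = FALSE]
  2 * mean(dxy) - mean(dxx) - mean(dyy)
}

energy_perm_test <- function(x, y, n_perm = 199, seed = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  nx <- nrow(x); ny <- nrow(y)
  pooled <- rbind(x, y)
  dall <- as.matrix(stats::dist(pooled))
  stat_from_idx <- function(ix) {
    iy <- setdiff(seq_len(nx + ny), ix)
    2 * mean(dall[ix, iy]) - mean(dall[ix, ix]) - mean(dall[iy, iy])
  }
  obs <- stat_from_idx(seq_len(nx))
  perm <- withr::with_seed(seed, {
    replicate(n_perm, stat_from_idx(sample.int(nx + ny, nx)))
  })
  (1 + sum(perm >= obs)) / (n_perm + 1)
}
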