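# Shared fixtures: everything is generated in code at test time.

# a small quantized volume with a bright box on a dark background
two_level_volume <- function(d = c(24L, 24L, 24L), lo = 0L, hi = 255L) {
  v <- array(lo, d)
  v[8:16, 8:16, 8:16] <- hi
  structure(list(values = array(as.integer(v), d), voxel_mm = 4.42,
                 offset = 0, gain = 1),
            class = "quantized_volume")
}

# wrap a bare array as a quantized_volume
as_quantized <- function(v, voxel_mm = 4.42) {
  structure(list(values = array(as.integer(round(v)), dim(v)),
                 voxel_mm = voxel_mm, offset = 0, gain = 1),
            class = "quantized_volume")
}

# wrap a bare array as a recon_volume
as_recon <- function(v, voxel_mm = 4.42, provenance = "surrogate") {
  structure(list(values = v, voxel_mm = voxel_mm, provenance = provenance),
            class = "recon_volume")
}

# random normalized 256-bin histogram
random_histogram <- function(n_occupied = 40) {
  p <- numeric(256)
  idx <- sample.int(256, n_occupied)
  p[idx] <- stats::rexp(n_occupied)
  p <- p / sum(p)
  structure(list(p = p, n_voxels = 1000L), class = "intensity_histogram")
}

# independent brute-force Otsu oracle: maximizes the between-class
# variance by direct enumeration (a different formulation than the
# package's within-class minimization)
otsu_bruteforce <- function(p) {
  lev <- 0:255
  mu_tot <- sum(p * lev)
  best_t <- NA_integer_; best_b <- -Inf
  for (t in 1:255) {
    wb <- sum(p[1:t])
    wf <- 1 - wb
    if (wb <= 0 || wf <= 0) {
      b <- 0
    } else {
      mu_b <- sum(p[1:t] * lev[1:t]) / wb
      mu_f <- (mu_tot - wb * mu_b) / wf
      b <- wb * wf * (mu_b - mu_f)^2
    }
    if (b > best_b + 1e-12) { best_b <- b; best_t <- t }
  }
  best_t
}

# small phantom-free benchmark config for pipeline tests: the surrogate
# noise scale is pinned so no reference reconstruction is triggered
quick_config <- function(...) {
  benchmark_config(noise_scale = 25, ...)
}

# an activity map with all activity removed (same phantom/grid)
zero_activity <- function(am) {
  am$values[] <- 0
  am
}
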