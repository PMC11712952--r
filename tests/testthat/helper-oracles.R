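# Shared oracles and small fixtures, independent of the implementation
# paths they check.

# closed-form Bethe evaluation (duplicated here on purpose)
oracle_bethe <- function(energy, i_ev, z_over_a) {
  mp <- 938.272
  me <- 0.510999
  k <- 0.307075
  g <- 1 + energy / mp
  b2 <- 1 - 1 / g^2
  wmax <- 2 * me * b2 * g^2 / (1 + 2 * g * me / mp + (me / mp)^2)
  k * z_over_a / b2 * (0.5 * log(2 * me * b2 * g^2 * wmax / (i_ev * 1e-6)^2) - b2)
}

# brute-force per-step LET accumulators for a set of (eps, l) steps
oracle_let <- function(eps, l) {
  list(
    lett = sum(eps) / sum(l),
    letd = sum(eps^2 / l) / sum(eps)
  )
}

# tiny 4x4x4 grid centered at the origin, 1 mm voxels
tiny_grid <- function(n = 4, spacing = 0.1) {
  voxel_grid(rep(-n * spacing / 2, 3), spacing, rep(n, 3))
}

# direct (non-separable) 3D Gaussian convolution for filter oracles
oracle_gauss3 <- function(arr, sigma) {
  d <- dim(arr)
  r <- max(1L, ceiling(4 * sigma))
  ker <- array(0, rep(2 * r + 1, 3))
  for (i in -r:r) for (j in -r:r) for (k in -r:r) {
    ker[i + r + 1, j + r + 1, k + r + 1] <-
      exp(-(i^2 + j^2 + k^2) / (2 * sigma^2))
  }
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    s <- 0
    wsum <- 0
    for (i in -r:r) for (j in -r:r) for (k in -r:r) {
      xi <- x + i
      yj <- y + j
      zk <- z + k
      if (xi < 1 || xi > d[1] || yj < 1 || yj > d[2] || zk < 1 || zk > d[3]) next
      w <- ker[i + r + 1, j + r + 1, k + r + 1]
      s <- s + w * arr[xi, yj, zk]
      wsum <- wsum + w
    }
    out[x, y, z] <- s / wsum
  }
  out
}

# small deterministic transport run shared across tests
cached_sim <- local({
  cache <- list()
  function(energy = 90, n = 4000, scenario = "uncollimated", offset = 0,
           seed = 42, config = transport_config()) {
    key <- paste(energy, n, scenario, offset, seed,
      config$nuclear_model, config$straggling, config$scattering,
      sep = "|"
    )
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_beamlet(
        energy,
        n = n, scenario = scenario, offset = offset, seed = seed,
        config = config
      )
    }
    cache[[key]]
  }
})
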