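# Independent oracles, deliberately coded apart from the package paths
# they check.

# Piecewise single-compartment PCASL difference signal, scalar form.
oracle_delta_m <- function(f, delta, ld, pld, t1b, alpha_lab, alpha_bs,
                           lambda, m0) {
  t <- ld + pld
  eps <- alpha_lab * alpha_bs
  if (t <= delta) return(0)
  base <- 2 * eps * m0 * (f / lambda) * (t1b / 60000) * exp(-delta / t1b)
  if (t <= delta + ld) base * (1 - exp(-(t - delta) / t1b))
  else base * (1 - exp(-ld / t1b)) * exp(-(t - delta - ld) / t1b)
}

# Naive per-prefix recomputation of the one-tailed paired t statistic.
oracle_prefix_t <- function(d, grid) {
  vapply(grid, function(k) {
    x <- d[seq_len(k)]
    u <- sum(x) / k
    s <- sqrt(sum((x - u)^2) / (k - 1))
    if (s == 0) { if (u > 0) Inf else if (u < 0) -Inf else 0 }
    else u * sqrt(k) / s
  }, numeric(1))
}

# Exhaustive neighbor-scan dilation.
oracle_dilate <- function(mask, offs) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (mask[x, y, z]) { out[x, y, z] <- TRUE; next }
    for (i in seq_len(nrow(offs))) {
      nx <- x - offs[i, 1]; ny <- y - offs[i, 2]; nz <- z - offs[i, 3]
      if (nx >= 1 && nx <= d[1] && ny >= 1 && ny <= d[2] &&
          nz >= 1 && nz <= d[3] && mask[nx, ny, nz]) {
        out[x, y, z] <- TRUE; break
      }
    }
  }
  out
}

# Exhaustive scan: voxels of a with a neighbor in b.
oracle_border <- function(a, b, offs) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!a[x, y, z]) next
    for (i in seq_len(nrow(offs))) {
      nx <- x + offs[i, 1]; ny <- y + offs[i, 2]; nz <- z + offs[i, 3]
      if (nx >= 1 && nx <= d[1] && ny >= 1 && ny <= d[2] &&
          nz >= 1 && nz <= d[3] && b[nx, ny, nz]) {
        out[x, y, z] <- TRUE; break
      }
    }
  }
  out
}

# Textbook adjusted Fisher-Pearson skewness.
oracle_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  (m3 / m2^(3 / 2)) * sqrt(n * (n - 1)) / (n - 2)
}

# Small phantom + simulation shared by several tests.
small_sim <- function(n_pairs = 40, seed = 11, noise = noise_config(),
                      tissue = tissue_config()) {
  tm <- sample_tissue_map(shape = c(24, 24, 4), config = tissue,
                          seed = seed)
  sim <- simulate_series(tm, protocol_preset("exp3", n_pairs = n_pairs),
                         noise = noise, seed = seed + 1)
  list(tmap = tm, sim = sim, diff = split_and_subtract(sim$series))
}
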