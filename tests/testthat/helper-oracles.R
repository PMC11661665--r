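# Shared fixtures and tiny independent oracles used across the suite.

# equilibrated tail of a trajectory (drop the first fraction of frames)
traj_tail <- function(traj, drop_frac = 0.3) {
  k0 <- max(1L, floor(length(traj$frames) * drop_frac))
  structure(list(frames = traj$frames[k0:length(traj$frames)],
                 times = traj$times[k0:length(traj$times)], n = traj$n),
            class = "cg_trajectory")
}

all_bead_radii <- function(traj) {
  unlist(lapply(traj$frames, function(f) sqrt(rowSums(f^2))))
}

# brute-force crossing enumeration, independent of crossing_pairs()
crossings_brute <- function(pairs) {
  m <- nrow(pairs)
  count <- 0L
  if (m >= 2L) for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    i1 <- min(pairs[a, ]); j1 <- max(pairs[a, ])
    i2 <- min(pairs[b, ]); j2 <- max(pairs[b, ])
    if ((i1 < i2 && i2 < j1 && j1 < j2) || (i2 < i1 && i1 < j2 && j2 < j1))
      count <- count + 1L
  }
  count
}

# per-pair frame counting, independent of persistence()
count_pair_frames <- function(series, i, j) {
  sum(vapply(series$maps, function(m) {
    any(m$contacts[, 1] == i & m$contacts[, 2] == j)
  }, logical(1)))
}

random_contact_map <- function(n, m, seed) {
  capsidfield:::with_seed(seed, {
    pool <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
    pick <- pool[sample(nrow(pool), min(m, nrow(pool))), , drop = FALSE]
    contact_map(pick, n)
  })
}

# chi-square GoF of sampled radii against r^2 exp(-U(r)) inside a half-
# harmonic wall, expected counts by quadrature
wall_boltzmann_pvalue <- function(rs, R0, omega, bin = 0.4) {
  dens <- function(r) r^2 * exp(-ifelse(r > R0, 0.5 * omega * (r - R0)^2, 0))
  edges <- seq(0, max(rs) + bin, by = bin)
  Z <- stats::integrate(dens, 0, Inf)$value
  p <- vapply(seq_len(length(edges) - 1L), function(k) {
    stats::integrate(dens, edges[k], edges[k + 1])$value / Z
  }, numeric(1))
  obs <- as.numeric(table(cut(rs, edges)))
  keep <- p * length(rs) >= 5
  chi <- sum((obs[keep] - length(rs) * p[keep])^2 / (length(rs) * p[keep]))
  stats::pchisq(chi, df = sum(keep) - 1L, lower.tail = FALSE)
}
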