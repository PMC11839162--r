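# Independent brute-force oracles used across the suite. These are written
# against the definitions only and share no code with the package internals.

# polygon area by the shoelace formula (absolute value)
oracle_polygon_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# clip a polygon by the half-plane of points at least as close to p as to q
oracle_halfplane_clip <- function(poly, p, q) {
  # keep points z with (q - p) . z <= (|q|^2 - |p|^2) / 2
  a <- q[1] - p[1]
  b <- q[2] - p[2]
  c0 <- (q[1]^2 + q[2]^2 - p[1]^2 - p[2]^2) / 2
  n <- nrow(poly)
  if (n == 0) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - c0
  out <- matrix(numeric(), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (d[i] <= 0) out <- rbind(out, poly[i, ])
    if ((d[i] <= 0) != (d[j] <= 0)) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# O(n^2) clipped Voronoi cell areas: each cell is the clip region cut by the
# nearer half-plane of every other site
oracle_voronoi_areas <- function(xy, region) {
  vapply(seq_len(nrow(xy)), function(i) {
    cell <- region
    for (j in seq_len(nrow(xy))) {
      if (j == i) next
      cell <- oracle_halfplane_clip(cell, xy[i, ], xy[j, ])
      if (nrow(cell) < 3) return(0)
    }
    oracle_polygon_area(cell)
  }, numeric(1))
}

# two-sided Fisher exact p for a 2x2 table by full hypergeometric enumeration
oracle_fisher_p <- function(m) {
  rs <- rowSums(m)
  cs <- colSums(m)
  probs <- vapply(max(0, cs[1] - rs[2]):min(rs[1], cs[1]), function(k) {
    stats::dhyper(k, rs[1], rs[2], cs[1])
  }, numeric(1))
  p_obs <- stats::dhyper(m[1, 1], rs[1], rs[2], cs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# permutation p-value for the one-way ANOVA F statistic
oracle_anova_perm_p <- function(value, group, n_perm, seed = 1L) {
  grp <- as.integer(factor(group))
  k <- max(grp)
  n <- length(value)
  grand <- mean(value)
  sst <- sum((value - grand)^2)
  f_of <- function(v) {
    s <- rowsum(v, grp)
    cnt <- tabulate(grp, k)
    ssb <- sum(s^2 / cnt) - n * grand^2
    (ssb / (k - 1)) / ((sst - ssb) / (n - k))
  }
  f_obs <- f_of(value)
  withr::with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (f_of(value[sample.int(n)]) >= f_obs) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}

# equal-area quadrats of a disk (rings x sectors) for a chi-square CSR test
oracle_quadrat_csr_p <- function(x, y, radius, n_rings = 4, n_sectors = 6) {
  r <- sqrt(x^2 + y^2)
  ring <- pmin(floor(n_rings * pmin(r / radius, 1 - 1e-12)^2), n_rings - 1)
  th <- atan2(y, x) + pi
  sector <- pmin(floor(n_sectors * th / (2 * pi)), n_sectors - 1)
  counts <- table(factor(ring * n_sectors + sector,
    levels = 0:(n_rings * n_sectors - 1)
  ))
  stats::chisq.test(as.numeric(counts))$p.value
}

# default chromatome simulation used by the spike-recovery checks:
# 40 proteins spiked 8x in Luc and 2Cneg only, among 500
spiked_chromatome_spec <- function() {
  chromatome_sim_spec(
    n_proteins = 500L,
    spike_sets = list(
      luc_2cneg = list(
        proteins = sprintf("P%04d", 1:40),
        folds = c(Luc = 8, `2Cneg` = 8, `2Cpos` = 1)
      )
    )
  )
}
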