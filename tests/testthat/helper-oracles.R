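# Independent oracles, kept deliberately separate from the package's own
# code paths.

# Brute-force dipolar tensor: explicit elementwise double loop over site
# pairs and Cartesian components, no vectorized outer products.
brute_dipolar_tensor <- function(sites_a, sites_b, g = 2.0023) {
  cc <- 1.299 / 6
  t <- matrix(0, 3, 3)
  for (sa in sites_a) {
    for (sb in sites_b) {
      d <- sb$position - sa$position
      r <- sqrt(d[1]^2 + d[2]^2 + d[3]^2)
      u <- d / r
      for (p in 1:3) {
        for (q in 1:3) {
          t[p, q] <- t[p, q] + sa$population * sb$population *
            ((p == q) - 3 * u[p] * u[q]) / r^3
        }
      }
    }
  }
  cc * g^2 * t
}

# Brute-force D/E: try all 6 orderings of the principal values and keep the
# one satisfying |t_zz| >= |t_yy| >= |t_xx|.
brute_DE <- function(tensor) {
  ev <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)$values
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    v <- ev[p]  # (t_xx, t_yy, t_zz)
    if (abs(v[3]) >= abs(v[2]) - 1e-15 && abs(v[2]) >= abs(v[1]) - 1e-15) {
      return(list(d = 1.5 * v[3], e = (v[1] - v[2]) / 2))
    }
  }
  stop("no ordering satisfied the convention")
}

random_sites <- function(n, scale = 10) {
  lapply(seq_len(n), function(i) {
    point_spin_site(stats::runif(3, -scale, scale), stats::runif(1, 0, 1 / n))
  })
}

# Aitken-style closed form for the limit of an exact exponential series on
# an equally spaced grid.
aitken_limit <- function(y) {
  n <- length(y)
  d1 <- y[n - 1] - y[n - 2]
  d2 <- y[n] - y[n - 1]
  y[n] + d2^2 / (d1 - d2)
}
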