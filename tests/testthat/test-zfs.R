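test_that("pair_dipolar_constant follows 1.299 g^2 / r^3", {
  expect_equal(pair_dipolar_constant(1, g = 1), 1.299)
  expect_equal(pair_dipolar_constant(10.28), 4.793890e-3, tolerance = 1e-6)
  expect_equal(pair_dipolar_constant(4) / pair_dipolar_constant(8), 8)
  expect_error(pair_dipolar_constant(0), "positive")
})

test_that("two-point |D| matches the published long-range values", {
  # r_oo = 9: model 2.397e-3 vs printed 2.40e-3 (Config 1) / 2.42e-3 (Config 2)
  d9 <- point_dipole_D(9, point_dipole_model("two_point"))
  expect_equal(d9, 0.5 * 1.299 * 2.0023^2 / 10.28^3, tolerance = 1e-12)
  expect_equal(d9, 2.40e-3, tolerance = 0.02)
  # r_oo = 8: 3.258e-3, within ~3% of the printed 3.34e-3
  d8 <- point_dipole_D(8, point_dipole_model("two_point"))
  expect_equal(d8, 3.258318e-3, tolerance = 1e-6)
  expect_equal(d8, 3.34e-3, tolerance = 0.03)
  # decay limit
  expect_lt(point_dipole_D(1e6), 1e-17)
})

test_that("dipolar tensor obeys the axial anchor contract", {
  for (r in c(3, 7.5, 10.28)) {
    for (g in c(2, 2.0023)) {
      a <- list(point_spin_site(c(0, 0, 0), 1))
      b <- list(point_spin_site(c(0, 0, r), 1))
      z <- extract_DE(dipolar_tensor(a, b, g = g))
      expect_equal(abs(z$d), 0.5 * 1.299 * g^2 / r^3, tolerance = 1e-12)
      expect_equal(z$e, 0)
      expect_true(z$axial)
    }
  }
})

test_that("tensor invariants hold and assembly matches the brute-force oracle", {
  set.seed(11)
  for (i in 1:12) {
    na <- sample(1:10, 1); nb <- sample(1:10, 1)
    a <- random_sites(na); b <- random_sites(nb)
    t <- dipolar_tensor(a, b)
    m <- unclass(t)
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_lt(abs(sum(diag(m))), 1e-10)
    oracle <- brute_dipolar_tensor(a, b)
    expect_lt(max(abs(m - oracle)) / max(abs(oracle)), 1e-12)
  }
  expect_error(
    dipolar_tensor(list(point_spin_site(c(0, 0, 0), 1)),
                   list(point_spin_site(c(0, 0, 0), 1))),
    "coincident")
  expect_error(dipolar_tensor(list(), list(point_spin_site(c(0, 0, 1), 1))),
               "non-empty")
})

test_that("extract_DE implements the |t_zz| >= |t_yy| >= |t_xx| convention", {
  # axial tensor diag(-d/3, -d/3, 2d/3) -> D = d, E = 0
  for (d in c(1, -0.4, 3e-3)) {
    t <- structure(diag(c(-d / 3, -d / 3, 2 * d / 3)),
                   class = c("dipolar_tensor", "matrix"))
    z <- extract_DE(t)
    expect_equal(z$d, d)
    expect_equal(z$e, 0)
  }
  # generic traceless tensors: compare against the all-orderings oracle
  set.seed(5)
  for (i in 1:25) {
    ab <- stats::rnorm(2)
    t <- diag(c(ab, -sum(ab)))
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))   # random rotation
    t <- q %*% t %*% t(q)
    t <- (t + t(t)) / 2
    t <- t - diag(rep(sum(diag(t)) / 3, 3))     # re-symmetrize exactly
    z <- extract_DE(structure(t, class = c("dipolar_tensor", "matrix")))
    o <- brute_DE(t)
    expect_equal(z$d, o$d, tolerance = 1e-10)
    expect_equal(abs(z$e), abs(o$e), tolerance = 1e-10)
    expect_lte(abs(z$e), abs(z$d) / 3 + 1e-10)
    expect_lt(abs(sum(z$principal_values)), 1e-10)
  }
  # null tensor
  z0 <- extract_DE(structure(matrix(0, 3, 3),
                             class = c("dipolar_tensor", "matrix")))
  expect_equal(z0$d, 0)
  expect_equal(z0$e, 0)
  # malformed tensors rejected
  bad <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)
  expect_error(extract_DE(structure(bad, class = c("dipolar_tensor",
                                                   "matrix"))),
               "symmetric")
  expect_error(extract_DE(structure(diag(3), class = c("dipolar_tensor",
                                                       "matrix"))),
               "traceless")
})

test_that("four-point model reproduces the published Config 2 long-range D", {
  z <- dimer_zfs(9, alpha = 0, point_dipole_model("four_point"))
  expect_equal(abs(z$d), 2.42e-3, tolerance = 0.05)
  # cross-check the full pipeline against the brute-force oracle
  frames <- build_dimer(dimer_configuration(9, alpha = 0))
  sa <- place_point_spins(frames[[1]], "four_point")
  sb <- place_point_spins(frames[[2]], "four_point")
  o <- brute_DE(brute_dipolar_tensor(sa, sb))
  expect_equal(z$d, o$d, tolerance = 1e-12)
})

test_that("four-point tensor collapses to the nuclei-site tensor as offsets shrink to zero", {
  frames <- build_dimer(dimer_configuration(8, alpha = 0))
  s0 <- lapply(frames, place_point_spins, model = "four_point",
               l_pi_n = 0, l_pi_o = 0)
  nuclei <- lapply(frames, function(f) list(
    point_spin_site(f$n_position, 0.45),
    point_spin_site(f$o_position, 0.51)))
  t0 <- dipolar_tensor(s0[[1]], s0[[2]])
  tn <- dipolar_tensor(nuclei[[1]], nuclei[[2]])
  expect_equal(unclass(t0), unclass(tn), tolerance = 1e-12)
})

test_that("E vanishes identically for the orthogonal-lobe configuration", {
  for (r in c(5, 6, 8, 11)) {
    z <- dimer_zfs(r, alpha = 90, point_dipole_model("four_point"))
    expect_lt(abs(z$e), 1e-12)
  }
  # parallel lobes with finite offsets do develop rhombicity
  z0 <- dimer_zfs(5, alpha = 0, point_dipole_model("four_point"))
  expect_gt(abs(z0$e), 1e-8)
})

test_that("log|D| vs log r approaches slope -3 at long range for every model", {
  r <- seq(8, 20, by = 1)
  for (m in list(point_dipole_model("two_point"),
                 point_dipole_model("four_point"))) {
    d <- abs(gen_reference_zfs_curves(m, r, alpha = 0)$d)
    slope <- stats::coef(stats::lm(log(d) ~ log(r + m$d_no)))[2]
    expect_equal(unname(slope), -3, tolerance = 0.02)
  }
})

test_that("the tensor is bilinear in the site populations", {
  frames <- build_dimer(dimer_configuration(7, alpha = 20))
  sa <- place_point_spins(frames[[1]], "four_point")
  sb <- place_point_spins(frames[[2]], "four_point")
  scale_sites <- function(sites, c) lapply(sites, function(s)
    point_spin_site(s$position, c * s$population))
  z1 <- extract_DE(dipolar_tensor(sa, sb))
  z2 <- extract_DE(dipolar_tensor(scale_sites(sa, 0.37), sb))
  expect_equal(z2$d, 0.37 * z1$d, tolerance = 1e-12)
  expect_equal(z2$e, 0.37 * z1$e, tolerance = 1e-12)
})

test_that("fit_lobe_offsets recovers the generating offsets exactly on model data", {
  truth <- point_dipole_model("four_point")   # 0.574 / 0.461
  ref <- gen_reference_zfs_curves(truth, r_grid = c(5, 5.5, 6, 7, 8, 9),
                                  alpha = 0)
  fit <- fit_lobe_offsets(ref, template = point_dipole_model(
    "four_point", l_pi_n = 0.3, l_pi_o = 0.3), alpha = 0)
  expect_equal(fit$l_pi_n, 0.574, tolerance = 1e-4)
  expect_equal(fit$l_pi_o, 0.461, tolerance = 1e-4)
})

test_that("fit_lobe_offsets degenerate limit reproduces a two-point reference curve", {
  ref <- gen_reference_zfs_curves(point_dipole_model("two_point"),
                                  r_grid = c(5, 5.5, 6, 7, 8, 9))
  fit <- fit_lobe_offsets(ref, alpha = 0)
  cur <- gen_reference_zfs_curves(fit$model, r_grid = ref$r_oo, alpha = 0)
  expect_equal(abs(cur$d), abs(ref$d), tolerance = 0.02)
  expect_lt(max(abs(cur$e)), 5e-4)
})

test_that("fit_lobe_offsets recovers offsets within 3 standard errors under noise", {
  truth <- point_dipole_model("four_point")
  ref <- gen_reference_zfs_curves(truth, r_grid = c(5, 5.5, 6, 7, 8, 9),
                                  alpha = 0)
  noisy <- withr::with_seed(21, {
    transform(ref, d = d * (1 + stats::rnorm(nrow(ref), sd = 0.02)),
              e = e * (1 + stats::rnorm(nrow(ref), sd = 0.02)))
  })
  fit <- fit_lobe_offsets(noisy, template = point_dipole_model(
    "four_point", l_pi_n = 0.4, l_pi_o = 0.4), alpha = 0)
  expect_lt(abs(fit$l_pi_n - 0.574), 3 * fit$l_pi_n_err + 0.05)
  expect_lt(abs(fit$l_pi_o - 0.461), 3 * fit$l_pi_o_err + 0.05)
})
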