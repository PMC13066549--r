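test_that("Gaussian overlap closed form matches numeric quadrature", {
  # identical centers, sigma 100: J = 1/sqrt(2*pi*20000)
  em <- lineshape(15000, 100 * 2 * sqrt(2 * log(2)), "emission")
  ab <- lineshape(15000, 100 * 2 * sqrt(2 * log(2)), "absorption")
  expect_rel_equal(spectral_overlap(em, ab), 1 / sqrt(2 * pi * 2e4), 1e-12)
  expect_equal(spectral_overlap(em, ab), 2.82e-3, tolerance = 1e-2)

  gauss <- function(x, c0, s) exp(-(x - c0)^2 / (2 * s^2)) /
    (s * sqrt(2 * pi))
  set.seed(123)
  for (trial in 1:50) {
    cd <- runif(1, 14000, 16000); ca <- runif(1, 14000, 16000)
    sd_ <- runif(1, 50, 400); sa <- runif(1, 50, 400)
    d <- lineshape(cd, sd_ * 2 * sqrt(2 * log(2)), "emission")
    a <- lineshape(ca, sa * 2 * sqrt(2 * log(2)), "absorption")
    # trapezoid oracle on a wide 1e5-point grid
    lo <- min(cd, ca) - 8 * max(sd_, sa)
    hi <- max(cd, ca) + 8 * max(sd_, sa)
    x <- seq(lo, hi, length.out = 1e5)
    f <- gauss(x, cd, sd_) * gauss(x, ca, sa)
    quad <- sum((f[-1] + f[-length(f)]) / 2) * (x[2] - x[1])
    expect_rel_equal(spectral_overlap(d, a), quad, 1e-8)
  }
  # monotone decay with detuning
  J <- vapply(seq(0, 3000, by = 300), function(delta) {
    spectral_overlap(lineshape(15000 - delta, 350, "emission"),
                     lineshape(15000, 350, "absorption"))
  }, 0)
  expect_true(all(diff(J) < 0))
  expect_error(lineshape(15000, -1), "positive")
})

test_that("golden-rule prefactor agrees with the hbar/unit-conversion oracle", {
  # k = 2*pi/hbar * V^2 * J with V = h*c*Vtilde and J in cm:
  # k[s^-1] = 4*pi^2*c[cm/s] * Vtilde^2 * J -> x1e-12 for ps^-1
  C_oracle <- 4 * pi^2 * 2.99792458e10 * 1e-12
  expect_rel_equal(eet_constants$forster_cm_ps, C_oracle, 1e-12)
  k <- forster_rate(10.08, 2.0e-3)
  expect_rel_equal(k, C_oracle * 10.08^2 * 2e-3, 1e-12)
  expect_equal(k, 0.240, tolerance = 0.01)
  expect_equal(1 / k, 4.2, tolerance = 0.05)
  expect_equal(forster_rate(0, 1e-3), 0)
  expect_rel_equal(forster_rate(3 * 4, 1e-3), 9 * forster_rate(4, 1e-3),
                   1e-12)
})

test_that("pairwise matrix: degenerate dimer symmetric, detuned asymmetric", {
  fix <- make_dimer_fixture(15, "parallel")
  ss <- extract_pigment_sites(fix$model, classify_cofactors(fix$model))
  p <- site_params()
  H <- build_hamiltonian(ss, p, "dipole")
  rm_ <- pairwise_rate_matrix(ss, H, p)
  expect_equal(rm_$k[1, 2], rm_$k[2, 1], tolerance = 1e-12)
  expect_true(all(rm_$k >= 0) && all(diag(rm_$k) == 0))
  # mixed-class dimer: downhill (b -> a) faster than uphill
  fix2 <- make_dimer_fixture(15, "parallel",
                             classes = c("chl_b", "chl_a"))
  ss2 <- extract_pigment_sites(fix2$model, classify_cofactors(fix2$model))
  H2 <- build_hamiltonian(ss2, p, "dipole")
  rm2 <- pairwise_rate_matrix(ss2, H2, p)
  expect_gt(rm2$k[1, 2], rm2$k[2, 1])
})

test_that("point-dipole rate follows the R^-6 law (slope -6.00 +/- 0.02)", {
  p <- site_params()
  Rs <- seq(15, 60, by = 5)
  ks <- vapply(Rs, function(R) {
    fix <- make_dimer_fixture(R, "parallel")
    ss <- extract_pigment_sites(fix$model, classify_cofactors(fix$model))
    H <- build_hamiltonian(ss, p, "dipole")
    pairwise_rate_matrix(ss, H, p)$k[1, 2]
  }, 0)
  slope <- coef(lm(log(ks) ~ log(Rs)))[[2]]
  expect_equal(slope, -6, tolerance = 0.02 / 6)
  expect_true(all(diff(1 / ks) > 0))  # tau monotone in R
})

test_that("exciton states: closed forms, sign fix, reconstruction", {
  E <- 15000; V <- 120
  ex <- exciton_states(matrix(c(E, V, V, E), 2))
  expect_equal(ex$energies, c(E - V, E + V))
  d <- exciton_states(diag(c(3, 1, 2)))
  expect_equal(d$energies, c(1, 2, 3))
  expect_equal(abs(d$coefficients), diag(3)[, c(2, 3, 1)])
  set.seed(99)
  M <- matrix(rnorm(64), 8); M <- (M + t(M)) / 2
  e8 <- exciton_states(M)
  expect_lt(max(abs(e8$coefficients %*% diag(e8$energies) %*%
                      t(e8$coefficients) - M)), 1e-8)
  # largest-magnitude coefficient of every state is positive
  expect_true(all(apply(e8$coefficients, 2, function(v) {
    v[which.max(abs(v))] > 0
  })))
})

test_that("Boltzmann populations: degenerate, kT-spaced, limits", {
  expect_equal(boltzmann_populations(c(10, 10), 300), c(0.5, 0.5))
  kT <- eet_constants$kB_cm1_K * 300
  P <- boltzmann_populations(c(0, kT), 300)
  expect_rel_equal(P[1], 1 / (1 + exp(-1)), 1e-12)
  expect_equal(boltzmann_populations(c(0, 208.5), 300)[1], 0.731,
               tolerance = 1e-3)
  expect_equal(boltzmann_populations(c(0, 500, 900), 1e9),
               rep(1 / 3, 3), tolerance = 1e-6)
  set.seed(5)
  for (i in 1:10) {
    expect_equal(sum(boltzmann_populations(rnorm(6, 15000, 200),
                                           runif(1, 10, 600))), 1)
  }
  expect_error(boltzmann_populations(c(1, 2), 0), "positive")
})

test_that("generalized Forster reduces to pairwise for singleton domains", {
  cloud <- random_site_cloud(6, seed = 44)
  ss <- extract_pigment_sites(cloud, classify_cofactors(cloud))
  p <- site_params()
  H <- build_hamiltonian(ss, p, "dipole")
  rm_ <- pairwise_rate_matrix(ss, H, p)
  ids <- names(ss$sites)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      kgf <- gf_rate(ids[i], ids[j], H, p)
      if (rm_$k[i, j] > 0) {
        expect_rel_equal(kgf, rm_$k[i, j], 1e-10)
      } else {
        expect_lt(kgf, 1e-15)
      }
    }
  }
})

test_that("GF rate equals explicit M,N enumeration on 3+3 and 5+5 clusters", {
  p <- site_params()
  for (nn in c(3, 5)) {
    fix <- make_two_domain_cluster(nn, nn, intra_spacing = 9,
                                   inter_gap = 24, seed = 42)
    ss <- extract_pigment_sites(fix$model, classify_cofactors(fix$model))
    H <- build_hamiltonian(ss, p, "dipole")
    grp <- partition_site_ids(ss, fix$partition)
    k_fwd <- gf_rate(grp$D, grp$A, H, p)
    expect_rel_equal(k_fwd, gf_oracle(grp$D, grp$A, H, p), 1e-9)
    k_bwd <- gf_rate(grp$A, grp$D, H, p)
    expect_rel_equal(k_bwd, gf_oracle(grp$A, grp$D, H, p), 1e-9)
    expect_true(k_fwd >= 0 && k_bwd >= 0)
  }
})

test_that("GF guards: overlapping or empty domains, zero inter-block", {
  fix <- make_two_domain_cluster(2, 2, seed = 2)
  ss <- extract_pigment_sites(fix$model, classify_cofactors(fix$model))
  H <- build_hamiltonian(ss, site_params(), "dipole")
  ids <- names(ss$sites)
  expect_error(gf_rate(ids[1:2], ids[2:3], H), "overlap")
  expect_error(gf_rate(character(), ids[1:2], H), "non-empty")
  H0 <- H
  H0$matrix[1:2, 3:4] <- 0; H0$matrix[3:4, 1:2] <- 0
  expect_equal(gf_rate(ids[1:2], ids[3:4], H0, site_params()), 0)
})

test_that("full rate matrix is rigid-motion invariant", {
  fix <- make_two_domain_cluster(3, 2, seed = 77)
  p <- site_params()
  build <- function(model) {
    ss <- extract_pigment_sites(model, classify_cofactors(model))
    H <- build_hamiltonian(ss, p, "tresp")
    list(pair = pairwise_rate_matrix(ss, H, p),
         gf = gf_rate_matrix(ss, H, fix$partition, p))
  }
  a <- build(fix$model)
  b <- build(rigid_transform_model(fix$model, rand_rotation(55),
                                   c(3, 3, -8)))
  expect_equal(b$pair$k, a$pair$k, tolerance = 1e-9)
  expect_equal(b$gf$k, a$gf$k, tolerance = 1e-9)
})
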