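# shared fixture helpers: every test works from generated structures, never
# from stored data

sites_of <- function(model, table = default_cofactor_table()) {
  extract_pigment_sites(model, classify_cofactors(model, table))$sites
}

# random proper rotation matrix (Gram-Schmidt on a seeded Gaussian draw)
rand_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform_model <- function(model, R, t = c(0, 0, 0)) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]
  a$y <- xyz[, 2] + t[2]
  a$z <- xyz[, 3] + t[3]
  structure_model(a)
}

# a cloud of synthetic chlorins at seeded random positions/orientations,
# spaced widely enough that no two rings collide
random_site_cloud <- function(n, seed, box = 40 + 10 * n) {
  set.seed(seed)
  atoms <- list()
  repeat {
    centers <- matrix(runif(3 * n, 0, box), ncol = 3)
    if (n < 2 || min(dist(centers)) > 9) break
  }
  for (i in seq_len(n)) {
    phi <- runif(1, 0, 2 * pi); u <- runif(1, -1, 1)
    # random orthonormal in-plane frame
    ez <- c(sqrt(1 - u^2) * cos(phi), sqrt(1 - u^2) * sin(phi), u)
    ref <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ex <- ref - sum(ref * ez) * ez; ex <- ex / sqrt(sum(ex^2))
    ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
            ez[3] * ex[1] - ez[1] * ex[3],
            ez[1] * ex[2] - ez[2] * ex[1])
    atoms[[i]] <- eetnet:::chlorin_atoms(centers[i, ], ex, ey, "A", i,
                                         "chl_a")
  }
  structure_model(do.call(rbind, atoms))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected),
            rel_tol * max(abs(expected), .Machine$double.eps))
}

# independent generalized-Forster oracle: explicit M,N enumeration built
# from base R primitives only (own eigen call, own Gaussian overlap, own
# Boltzmann weights and rate constant)
gf_oracle <- function(donor_ids, acceptor_ids, H, p) {
  di <- match(donor_ids, H$site_ids); ai <- match(acceptor_ids, H$site_ids)
  ed <- eigen(H$matrix[di, di, drop = FALSE], symmetric = TRUE)
  ea <- eigen(H$matrix[ai, ai, drop = FALSE], symmetric = TRUE)
  kB <- 0.6950348004
  w <- exp(-(ed$values - min(ed$values)) / (kB * p$temperature))
  Pm <- w / sum(w)
  fw_d <- mean(p$lineshape_fwhm[H$classes[di]])
  fw_a <- mean(p$lineshape_fwhm[H$classes[ai]])
  cls <- H$classes[di]
  tb <- sort(table(cls), decreasing = TRUE)
  mc <- names(tb)[tb == max(tb)]
  mc <- if ("chl_a" %in% mc) "chl_a" else sort(mc)[1]
  st <- p$stokes_shift[[mc]]
  s_d <- fw_d / (2 * sqrt(2 * log(2))); s_a <- fw_a / (2 * sqrt(2 * log(2)))
  ktot <- 0
  for (M in seq_along(ed$values)) {
    for (N in seq_along(ea$values)) {
      V_MN <- sum(outer(ed$vectors[, M], ea$vectors[, N]) *
                    H$matrix[di, ai, drop = FALSE])
      delta <- (ed$values[M] - st) - ea$values[N]
      J <- exp(-delta^2 / (2 * (s_d^2 + s_a^2))) /
        sqrt(2 * pi * (s_d^2 + s_a^2))
      ktot <- ktot + Pm[M] * (4 * pi^2 * 2.99792458e-2) * V_MN^2 * J
    }
  }
  ktot
}
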