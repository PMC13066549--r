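#' Gaussian lineshape descriptor
#'
#' Area-normalized Gaussian on the wavenumber axis. Emission lineshapes are
#' red-shifted by the Stokes shift relative to the 0-0 energy.
#'
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1).
#' @param role `"absorption"` or `"emission"`.
#' @return A `Lineshape` list with `center`, `sigma`, `role`.
#' @export
lineshape <- function(center, fwhm, role = c("absorption", "emission")) {
  role <- match.arg(role)
  if (fwhm <= 0) stop("lineshape fwhm must be positive")
  structure(list(center = center,
                 sigma = fwhm / (2 * sqrt(2 * log(2))),
                 role = role),
            class = "Lineshape")
}

#' Donor-emission / acceptor-absorption spectral overlap (cm)
#'
#' For unit-area Gaussians the overlap integral has the closed form
#' J = exp(-Delta^2 / (2 (s_D^2 + s_A^2))) / sqrt(2 pi (s_D^2 + s_A^2)),
#' Delta = center_D - center_A.
#'
#' @param donor A `Lineshape` (emission).
#' @param acceptor A `Lineshape` (absorption).
#' @return Overlap in cm (inverse wavenumber).
#' @export
spectral_overlap <- function(donor, acceptor) {
  s2 <- donor$sigma^2 + acceptor$sigma^2
  if (s2 <= 0) stop("non-positive lineshape widths")
  delta <- donor$center - acceptor$center
  exp(-delta^2 / (2 * s2)) / sqrt(2 * pi * s2)
}

#' Golden-rule Forster rate from coupling and overlap
#'
#' k = (2 pi / hbar) V^2 J in practical units:
#' k[ps^-1] = 4 pi^2 c * V[cm^-1]^2 * J[cm], c in cm/ps (prefactor ~1.184).
#'
#' @param V Electronic coupling (cm^-1).
#' @param J Spectral overlap (cm).
#' @return Rate in ps^-1.
#' @export
forster_rate <- function(V, J) {
  if (any(J < 0)) stop("negative spectral overlap")
  eet_constants$forster_cm_ps * V^2 * J
}

class_lineshapes <- function(class, params) {
  e0 <- params$site_energy[[class]]
  fw <- params$lineshape_fwhm[[class]]
  st <- params$stokes_shift[[class]]
  list(abs = lineshape(e0, fw, "absorption"),
       em  = lineshape(e0 - st, fw, "emission"))
}

#' Pairwise Forster rate matrix over all site pairs
#'
#' For every ordered (donor, acceptor) pair the donor emission lineshape
#' (class 0-0 energy minus Stokes shift) is overlapped with the acceptor
#' absorption lineshape and combined with the coupling from the Hamiltonian.
#' Forward and backward rates are both stored; the matrix is generally
#' asymmetric through the spectral factors.
#'
#' @param siteset `PigmentSiteSet` or site list (for classes/ids).
#' @param H A `Hamiltonian` consistent with `siteset`.
#' @param params A `SiteParams`.
#' @return A `RateMatrix` (level `"pairwise"`): list with `nodes`, `k`
#'   (ps^-1 matrix, rows = donor), `tau` (ps), `level`.
#' @export
pairwise_rate_matrix <- function(siteset, H, params = site_params()) {
  sites <- as_site_list(siteset)
  ids <- vapply(sites, `[[`, "", "site_id")
  if (!identical(ids, H$site_ids)) {
    stop("Hamiltonian site order does not match site set")
  }
  classes <- vapply(sites, `[[`, "", "class")
  ls <- lapply(unique(classes), class_lineshapes, params = params)
  names(ls) <- unique(classes)
  n <- length(ids)
  k <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      J <- spectral_overlap(ls[[classes[i]]]$em, ls[[classes[j]]]$abs)
      k[i, j] <- forster_rate(H$matrix[i, j], J)
    }
  }
  new_rate_matrix(ids, k, "pairwise")
}

new_rate_matrix <- function(nodes, k, level) {
  tau <- ifelse(k > 0, 1 / k, Inf)
  diag(tau) <- 0
  structure(list(nodes = nodes, k = k, tau = tau, level = level),
            class = "RateMatrix")
}

#' @export
print.RateMatrix <- function(x, ...) {
  cat(sprintf("RateMatrix (%s): %d nodes\n", x$level, length(x$nodes)))
  invisible(x)
}

#' Exciton states of a domain Hamiltonian block
#'
#' Eigen-decomposition of the symmetric intra-domain block. Eigenvalues are
#' returned ascending; each eigenvector's sign is fixed by making its
#' largest-magnitude coefficient positive.
#'
#' @param H_block Symmetric numeric matrix (cm^-1).
#' @return List with `energies` (ascending, cm^-1) and `coefficients`
#'   (columns = states, orthonormal).
#' @export
exciton_states <- function(H_block) {
  H_block <- as.matrix(H_block)
  if (max(abs(H_block - t(H_block))) > 1e-9) {
    stop("Hamiltonian block is not symmetric")
  }
  e <- eigen((H_block + t(H_block)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (m in seq_len(ncol(vecs))) {
    piv <- which.max(abs(vecs[, m]))
    if (vecs[piv, m] < 0) vecs[, m] <- -vecs[, m]
  }
  list(energies = vals, coefficients = vecs)
}

#' Boltzmann populations of exciton states
#'
#' P_M = exp(-(e_M - e_min) / kB T) / Z with kB = 0.695 cm^-1/K.
#'
#' @param energies Energies (cm^-1).
#' @param T Temperature (K), > 0.
#' @return Probability vector summing to 1.
#' @export
boltzmann_populations <- function(energies, T = 300) {
  if (T <= 0) stop("temperature must be positive")
  w <- exp(-(energies - min(energies)) / (eet_constants$kB_cm1_K * T))
  w / sum(w)
}

majority_class <- function(classes) {
  tb <- sort(table(classes), decreasing = TRUE)
  nm <- names(tb)[tb == max(tb)]
  if ("chl_a" %in% nm) "chl_a" else sort(nm)[1]
}

#' Generalized-Forster rate between two pigment domains (ps^-1)
#'
#' Diagonalizes the intra-domain blocks of the Hamiltonian, couples donor
#' exciton M to acceptor exciton N through
#' V_MN = sum_m sum_n c^M_m c^N_n V_mn (inter-domain block), computes each
#' exciton-to-exciton Forster rate with lineshapes centered at the exciton
#' energies (class-average widths; donor emission shifted by the donor
#' domain's majority-class Stokes shift), and thermally averages over donor
#' excitons: k = sum_M P_M(T) sum_N k_MN.
#'
#' @param donor_ids,acceptor_ids Site ids of the two (disjoint) domains.
#' @param H A `Hamiltonian` containing all those sites.
#' @param params A `SiteParams`.
#' @return Rate in ps^-1.
#' @export
gf_rate <- function(donor_ids, acceptor_ids, H, params = site_params()) {
  if (length(intersect(donor_ids, acceptor_ids))) {
    stop("donor and acceptor domains overlap")
  }
  if (!length(donor_ids) || !length(acceptor_ids)) {
    stop("domains must be non-empty")
  }
  di <- match(donor_ids, H$site_ids)
  ai <- match(acceptor_ids, H$site_ids)
  if (anyNA(di) || anyNA(ai)) stop("domain site id absent from Hamiltonian")
  ex_d <- exciton_states(H$matrix[di, di, drop = FALSE])
  ex_a <- exciton_states(H$matrix[ai, ai, drop = FALSE])
  V_inter <- H$matrix[di, ai, drop = FALSE]
  V_MN <- t(ex_d$coefficients) %*% V_inter %*% ex_a$coefficients
  cls_d <- H$classes[di]; cls_a <- H$classes[ai]
  fw_d <- mean(params$lineshape_fwhm[cls_d])
  fw_a <- mean(params$lineshape_fwhm[cls_a])
  stokes_d <- params$stokes_shift[[majority_class(cls_d)]]
  P <- boltzmann_populations(ex_d$energies, params$temperature)
  k <- 0
  for (M in seq_along(ex_d$energies)) {
    em <- lineshape(ex_d$energies[M] - stokes_d, fw_d, "emission")
    for (N in seq_along(ex_a$energies)) {
      ab <- lineshape(ex_a$energies[N], fw_a, "absorption")
      k <- k + P[M] * forster_rate(V_MN[M, N], spectral_overlap(em, ab))
    }
  }
  k
}

#' Domain-level generalized-Forster rate matrix
#'
#' @param siteset `PigmentSiteSet` or site list.
#' @param H A `Hamiltonian` over the same sites.
#' @param partition A `DomainPartition` covering every site.
#' @param params A `SiteParams`.
#' @return A `RateMatrix` (level `"domain"`) over the domain labels, rows =
#'   donor domain.
#' @export
gf_rate_matrix <- function(siteset, H, partition, params = site_params()) {
  groups <- partition_site_ids(siteset, partition)
  labs <- names(groups)
  n <- length(labs)
  k <- matrix(0, n, n, dimnames = list(labs, labs))
  for (d in seq_len(n)) {
    for (a in seq_len(n)) {
      if (d == a) next
      k[d, a] <- gf_rate(groups[[d]], groups[[a]], H, params)
    }
  }
  new_rate_matrix(labs, k, "domain")
}
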