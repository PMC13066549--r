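#' Orientation factor of the dipole-dipole coupling
#'
#' kappa = d_i . d_j - 3 (d_i . r_hat)(d_j . r_hat), with r the separation
#' vector between the two dipole centers. Collinear head-to-tail dipoles give
#' -2, parallel side-by-side +1.
#'
#' @param d_i,d_j Dipole direction vectors (normalized internally).
#' @param r Separation vector (any units, must be non-zero).
#' @return Dimensionless scalar in [-2, 2].
#' @export
kappa <- function(d_i, d_j, r) {
  rn <- sqrt(sum(r^2))
  if (rn < 1e-12) stop("zero separation vector")
  di <- d_i / sqrt(sum(d_i^2))
  dj <- d_j / sqrt(sum(d_j^2))
  rh <- r / rn
  sum(di * dj) - 3 * sum(di * rh) * sum(dj * rh)
}

#' Point-dipole excitonic coupling (cm^-1)
#'
#' V = f * C * kappa * mu_i mu_j / R^3 with mu in Debye, R the Mg-Mg
#' distance in nm and C = e^2/(4 pi eps0) expressed in cm^-1 nm^3 D^-2
#' (~5.03). The screening factor f is taken from `params`.
#'
#' @param site_i,site_j `PigmentSite` objects.
#' @param params A `SiteParams`.
#' @return Coupling in cm^-1 (signed).
#' @export
dipole_coupling <- function(site_i, site_j, params = site_params()) {
  r <- site_j$mg - site_i$mg
  R_nm <- sqrt(sum(r^2)) / 10
  if (R_nm < 1e-9) stop("zero Mg-Mg distance between ", site_i$site_id,
                        " and ", site_j$site_id)
  di <- assign_transition_dipole(site_i, params)
  dj <- assign_transition_dipole(site_j, params)
  k <- kappa(di$direction, dj$direction, r)
  params$screening * eet_constants$dipole_cm1_nm3 * k *
    di$magnitude_D * dj$magnitude_D / R_nm^3
}

# Resolve template atoms on a residue; missing atoms are dropped and the
# remaining charges re-neutralized (deposited models commonly truncate
# tails). Fails if more than `max_missing_frac` of the template is absent.
resolve_template_charges <- function(site, templates, params,
                                     max_missing_frac = 0.2,
                                     rescale = TRUE) {
  tpl <- templates[[site$class]]
  if (is.null(tpl)) stop("no transition-charge template for class ",
                         site$class)
  hit <- match(tpl$atom, site$atoms$atom)
  missing <- is.na(hit)
  if (mean(missing) > max_missing_frac) {
    stop(sprintf("%.0f%% of template atoms missing on %s",
                 100 * mean(missing), site$site_id))
  }
  q <- tpl$charge_e[!missing]
  if (any(missing)) {
    warning(sum(missing), " template atom(s) missing on ", site$site_id,
            "; dropped and re-neutralized")
    q <- q - mean(q)
  }
  pos <- as.matrix(site$atoms[hit[!missing], c("x", "y", "z")])
  if (rescale) {
    # rescale so the realized transition dipole equals the class dipole
    mu_vec_eA <- colSums(q * pos)
    mu_D <- sqrt(sum(mu_vec_eA^2)) * eet_constants$debye_per_eA
    if (mu_D < 1e-9) stop("template dipole vanishes on ", site$site_id)
    target <- params$dipole_strength[[site$class]]
    q <- q * target / mu_D
  }
  list(pos = pos, q = q)
}

#' Transition-charge (TrEsp) excitonic coupling (cm^-1)
#'
#' Coulomb sum over atomic transition charges,
#' V = f * K * sum_ab q_a q_b / r_ab with q in e, r in Angstrom and
#' K = e^2/(4 pi eps0) ~ 116141 cm^-1 A. Template charges are rescaled per
#' residue so the realized transition-dipole magnitude equals the class
#' dipole strength, which makes the method converge to [dipole_coupling()]
#' at large separation.
#'
#' @param site_i,site_j `PigmentSite` objects.
#' @param templates A `TrespTemplate`.
#' @param params A `SiteParams`.
#' @param rescale If `FALSE`, use the template charges as shipped without
#'   rescaling to the class dipole strength (raw Coulomb sum).
#' @return Coupling in cm^-1 (signed).
#' @export
tresp_coupling <- function(site_i, site_j,
                           templates = default_tresp_template(),
                           params = site_params(), rescale = TRUE) {
  a <- resolve_template_charges(site_i, templates, params,
                                rescale = rescale)
  b <- resolve_template_charges(site_j, templates, params,
                                rescale = rescale)
  d2 <- outer(rowSums(a$pos^2), rowSums(b$pos^2), "+") -
    2 * a$pos %*% t(b$pos)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-6)) stop("superposed atoms between ", site_i$site_id,
                          " and ", site_j$site_id)
  params$screening * eet_constants$coulomb_cm1_A *
    sum(outer(a$q, b$q) / d)
}

#' Site-basis excitonic Hamiltonian (cm^-1)
#'
#' Diagonal entries are the class site energies; off-diagonal entries the
#' pairwise couplings under the chosen method. Site order is deterministic:
#' (chain, resnum), i.e. the order produced by [extract_pigment_sites()].
#'
#' @param siteset A `PigmentSiteSet` or site list.
#' @param params A `SiteParams`.
#' @param method `"tresp"` or `"dipole"`.
#' @param templates `TrespTemplate` (used by the tresp method).
#' @return A `Hamiltonian`: list with `site_ids`, `classes`, symmetric
#'   `matrix` (cm^-1).
#' @export
build_hamiltonian <- function(siteset, params = site_params(),
                              method = c("tresp", "dipole"),
                              templates = default_tresp_template()) {
  method <- match.arg(method)
  sites <- as_site_list(siteset)
  if (!length(sites)) stop("need at least one pigment site")
  ids <- vapply(sites, `[[`, "", "site_id")
  classes <- vapply(sites, `[[`, "", "class")
  n <- length(sites)
  H <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(H) <- params$site_energy[classes]
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- tryCatch(
          switch(method,
                 dipole = dipole_coupling(sites[[i]], sites[[j]], params),
                 tresp  = tresp_coupling(sites[[i]], sites[[j]],
                                         templates, params)),
          error = function(e) {
            stop("coupling failed for pair ", ids[i], " / ", ids[j], ": ",
                 conditionMessage(e))
          })
        H[i, j] <- H[j, i] <- v
      }
    }
  }
  structure(list(site_ids = ids, classes = classes, matrix = H,
                 method = method),
            class = "Hamiltonian")
}

#' @export
print.Hamiltonian <- function(x, ...) {
  cat(sprintf("Hamiltonian: %d sites (%s method)\n", length(x$site_ids),
              x$method))
  invisible(x)
}
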