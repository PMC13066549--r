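#' Physical constants used throughout the package
#'
#' All energies are wavenumbers (cm^-1), distances Angstrom unless stated,
#' dipoles Debye, time picoseconds. Constants are derived from CODATA values
#' rather than quoted rounded numbers so that unit-analysis tests can check
#' them independently.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{coulomb_cm1_A}{e^2/(4 pi eps0) expressed in cm^-1 * Angstrom per
#'     e^2: the Coulomb prefactor for transition-charge sums (~116141).}
#'   \item{dipole_cm1_nm3}{Coulomb prefactor for the point-dipole coupling,
#'     cm^-1 * nm^3 / Debye^2 (~5.034).}
#'   \item{forster_cm_ps}{Prefactor of the Forster golden-rule rate,
#'     k[ps^-1] = forster_cm_ps * V[cm^-1]^2 * J[cm] (= 4 pi^2 c, ~1.184).}
#'   \item{kB_cm1_K}{Boltzmann constant in cm^-1/K (~0.695).}
#'   \item{debye_per_eA}{Debye per e*Angstrom (~4.803).}
#' }
#' @export
eet_constants <- local({
  c_cm_ps <- 2.99792458e10 * 1e-12               # speed of light, cm per ps
  hartree_cm1 <- 219474.6313632
  bohr_A <- 0.529177210903
  coulomb_cm1_A <- hartree_cm1 * bohr_A          # e^2/(4 pi eps0) in cm^-1 * A
  debye_per_eA <- 1 / 0.208194342                # 1 e*A in Debye
  list(
    coulomb_cm1_A  = coulomb_cm1_A,
    dipole_cm1_nm3 = coulomb_cm1_A / debye_per_eA^2 / 1e3,
    forster_cm_ps  = 4 * pi^2 * c_cm_ps,
    kB_cm1_K       = 0.6950348004,
    debye_per_eA   = debye_per_eA
  )
})
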