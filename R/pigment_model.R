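#' Spectral parameters per pigment class
#'
#' Site energies, dipole strengths and lineshape parameters stand in for the
#' per-pigment excited-state calculations that a full quantum-chemical
#' treatment would supply; they are literature-typical values and every one
#' of them is configurable. Energies in cm^-1, dipoles in Debye,
#' temperature in K.
#'
#' @param site_energy Named numeric, 0-0 transition energy per class.
#' @param dipole_strength Named numeric, Qy transition dipole per class (D).
#' @param lineshape_fwhm Named numeric, Gaussian FWHM per class (cm^-1).
#' @param stokes_shift Named numeric, emission red-shift per class (cm^-1).
#' @param temperature Kelvin.
#' @param screening Dimensionless dielectric screening factor applied to all
#'   couplings, in (0, 1.5].
#' @return A `SiteParams` list.
#' @export
site_params <- function(site_energy = c(chl_a = 14900, chl_b = 15385),
                        dipole_strength = c(chl_a = 4.0, chl_b = 3.4),
                        lineshape_fwhm = c(chl_a = 350, chl_b = 350),
                        stokes_shift = c(chl_a = 120, chl_b = 120),
                        temperature = 300,
                        screening = 0.8) {
  stopifnot(all(site_energy > 0), all(dipole_strength > 0),
            all(lineshape_fwhm > 0), all(stokes_shift >= 0),
            temperature > 0)
  if (!(screening > 0 && screening <= 1.5)) {
    stop("screening factor must lie in (0, 1.5]")
  }
  structure(list(site_energy = site_energy,
                 dipole_strength = dipole_strength,
                 lineshape_fwhm = lineshape_fwhm,
                 stokes_shift = stokes_shift,
                 temperature = temperature,
                 screening = screening),
            class = "SiteParams")
}

#' Read SiteParams from flat `key: value` text
#'
#' Recognized keys: `<class>.site_energy`, `<class>.dipole_strength`,
#' `<class>.lineshape_fwhm`, `<class>.stokes_shift`, `temperature`,
#' `screening`. Unspecified values keep their defaults.
#'
#' @param path File path.
#' @return A `SiteParams` list.
#' @export
read_site_params <- function(path) {
  kv <- read_flat_config(path)
  p <- site_params()
  for (key in names(kv)) {
    val <- as.numeric(kv[[key]])
    if (key == "temperature") { p$temperature <- val; next }
    if (key == "screening")   { p$screening <- val; next }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[2] %in% names(p)) {
      stop("unrecognized site-params key: ", key)
    }
    p[[parts[2]]][[parts[1]]] <- val
  }
  do.call(site_params, unclass(p))
}

read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  m <- regmatches(lines, regexec("^(\\S+)\\s*:\\s*(.+?)\\s*$", lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  stats::setNames(lapply(m, `[[`, 3L), vapply(m, `[[`, "", 2L))
}

#' Default transition-charge template for chlorin rings
#'
#' A synthetic stand-in for a fitted transition-charge set (the published
#' quantum-chemically derived charge sets are not shipped): four point
#' charges on the NB->ND axis of the chlorin — an inner +/- pair on the ring
#' nitrogens and an outer counter-pair on the B/D ring carbons whose
#' magnitude q' = q (a/b)^3 cancels the octupole of the inner pair, so the
#' Coulomb sum converges to the point-dipole limit as (extent/R)^4. Charges
#' sum to zero and give a transition dipole along NB->ND (the Qy
#' convention); they are rescaled at coupling time so the realized dipole
#' magnitude on each residue equals the class dipole strength, so only the
#' spatial distribution (not the absolute scale) of this set matters.
#'
#' @return A `TrespTemplate`: list per class of data.frame (atom, charge_e).
#' @export
default_tresp_template <- function() {
  q <- 0.28
  qo <- q * (2.05 / 3.40)^3  # octupole-cancelling outer charge
  chlorin <- data.frame(
    atom = c("NB", "ND", "C3B", "C3D"),
    charge_e = c(-q, q, qo, -qo),
    stringsAsFactors = FALSE
  )
  structure(list(chl_a = chlorin, chl_b = chlorin), class = "TrespTemplate")
}

#' Read a transition-charge template from CSV
#'
#' CSV columns: `class`, `atom`, `charge_e`. Charges per class must sum to
#' zero within 1e-6 e.
#'
#' @param path CSV file path.
#' @return A `TrespTemplate`.
#' @export
read_tresp_template <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "atom", "charge_e") %in% names(df)))
  out <- split(df[c("atom", "charge_e")], df$class)
  for (cl in names(out)) {
    if (abs(sum(out[[cl]]$charge_e)) > 1e-6) {
      stop("template charges for class ", cl, " do not sum to zero")
    }
    rownames(out[[cl]]) <- NULL
  }
  structure(out, class = "TrespTemplate")
}

## ---- pigment sites -------------------------------------------------------

CHL_CLASSES <- c("chl_a", "chl_b")
RING_NITROGENS <- c("NA", "NB", "NC", "ND")
MG_RING_N_MAX <- 2.6  # Angstrom, Mg-N coordination ceiling

#' Extract geometric pigment sites from a classified structure
#'
#' Builds one `PigmentSite` per chlorophyll-class residue that has a
#' resolvable central Mg and at least the NB and ND dipole-anchor nitrogens.
#' Residues failing the geometry checks (missing Mg, missing anchors, ring
#' nitrogens too far from Mg) are collected in a skip report with reasons,
#' never silently dropped.
#'
#' @param model The `StructureModel` the inventory came from.
#' @param inventory A `CofactorInventory` from [classify_cofactors()].
#' @return A `PigmentSiteSet`: list with `sites` (list of `PigmentSite`) and
#'   `skipped` (data.frame site_id, reason).
#' @export
extract_pigment_sites <- function(model, inventory) {
  chl <- inventory$residues[inventory$residues$class %in% CHL_CLASSES, ,
                            drop = FALSE]
  chl <- chl[order(chl$chain, chl$resnum, chl$inscode), , drop = FALSE]
  a <- model$atoms
  sites <- list()
  skipped <- data.frame(site_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(chl))) {
    sel <- a$chain == chl$chain[r] & a$resnum == chl$resnum[r] &
      a$inscode == chl$inscode[r]
    res_atoms <- a[sel, , drop = FALSE]
    sid <- sprintf("%s:%d%s:%s", chl$chain[r], chl$resnum[r],
                   chl$inscode[r], chl$code[r])
    fail <- function(why) {
      skipped[nrow(skipped) + 1L, ] <<- list(sid, why)
    }
    mg <- res_atoms[res_atoms$atom == "MG", , drop = FALSE]
    if (!nrow(mg)) { fail("missing Mg"); next }
    mg_pos <- c(mg$x[1], mg$y[1], mg$z[1])
    ringn <- res_atoms[res_atoms$atom %in% RING_NITROGENS, , drop = FALSE]
    if (!all(c("NB", "ND") %in% ringn$atom)) {
      fail("missing NB/ND dipole anchors"); next
    }
    npos <- as.matrix(ringn[, c("x", "y", "z")])
    rownames(npos) <- ringn$atom
    dn <- sqrt(rowSums(sweep(npos, 2, mg_pos)^2))
    if (any(dn > MG_RING_N_MAX)) {
      fail(sprintf("ring nitrogen %.1f A from Mg",
                   max(dn))); next
    }
    sites[[sid]] <- structure(list(
      site_id = sid,
      chain = chl$chain[r], resnum = chl$resnum[r],
      code = chl$code[r], class = chl$class[r],
      mg = mg_pos,
      nb = unname(npos["NB", ]), nd = unname(npos["ND", ]),
      ring_nitrogens = npos,
      atoms = res_atoms[, c("atom", "element", "x", "y", "z")],
      domain = NA_character_
    ), class = "PigmentSite")
  }
  structure(list(sites = sites, skipped = skipped), class = "PigmentSiteSet")
}

#' @export
print.PigmentSiteSet <- function(x, ...) {
  cat("PigmentSiteSet:", length(x$sites), "sites,",
      nrow(x$skipped), "skipped\n")
  invisible(x)
}

#' Qy transition dipole of a pigment site
#'
#' Direction is the normalized NB->ND ring-nitrogen axis (configurable to the
#' reverse); magnitude is the class dipole strength. Sign conventions cancel
#' in all downstream |V|^2 quantities.
#'
#' @param site A `PigmentSite`.
#' @param params A `SiteParams`.
#' @param convention `"nb_to_nd"` (default) or `"nd_to_nb"`.
#' @return List with `direction` (unit 3-vector) and `magnitude_D`.
#' @export
assign_transition_dipole <- function(site, params = site_params(),
                                     convention = c("nb_to_nd", "nd_to_nb")) {
  convention <- match.arg(convention)
  v <- site$nd - site$nb
  if (convention == "nd_to_nb") v <- -v
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("zero-length NB->ND vector for site ", site$site_id)
  mu <- params$dipole_strength[[site$class]]
  list(direction = v / nv, magnitude_D = mu)
}

#' Least-squares chlorin ring plane normal
#'
#' Unit normal of the best-fit plane through the ring nitrogens (SVD of the
#' centered coordinates). Sign convention: positive z component; if the z
#' component is (numerically) zero, positive x.
#'
#' @param site A `PigmentSite` with >= 3 ring nitrogens.
#' @return Unit 3-vector.
#' @export
ring_plane_normal <- function(site) {
  p <- site$ring_nitrogens
  if (nrow(p) < 3) stop("need >= 3 ring nitrogens for site ", site$site_id)
  centered <- sweep(p, 2, colMeans(p))
  sv <- svd(centered)
  if (sv$d[2] < 1e-8) {
    stop("collinear ring nitrogens for site ", site$site_id)
  }
  n <- sv$v[, 3]
  if (abs(n[3]) > 1e-12) {
    if (n[3] < 0) n <- -n
  } else if (n[1] < 0) n <- -n
  n / sqrt(sum(n^2))
}
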