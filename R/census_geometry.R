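#' Pigment stoichiometry normalized to a reference class
#'
#' Each class count is expressed per 100 molecules of the reference class.
#' The printed value is rounded to the nearest integer, except values below 1
#' which keep one decimal (so trace pigments are not rounded to 0); the
#' unrounded values are always carried alongside.
#'
#' @param inventory A `CofactorInventory` (or a named integer vector of
#'   counts).
#' @param reference Reference class name (default `"chl_a"`).
#' @return A `PigmentRatio`: data.frame with `class`, `count`, `value`
#'   (unrounded) and `printed` (rounded per rule).
#' @export
pigment_ratio <- function(inventory, reference = "chl_a") {
  counts <- if (inherits(inventory, "CofactorInventory")) inventory$counts
            else inventory
  if (is.null(counts[reference]) || is.na(counts[reference]) ||
      counts[[reference]] == 0) {
    stop("reference class ", reference, " has zero count")
  }
  counts <- counts[counts > 0]
  value <- 100 * counts / counts[[reference]]
  printed <- ifelse(value < 1, round(value, 1), round(value))
  out <- data.frame(class = names(counts), count = as.integer(counts),
                    value = as.numeric(value), printed = as.numeric(printed),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("PigmentRatio", "data.frame"))
}

#' Mg-Mg distance between two pigment sites (Angstrom)
#' @param site_i,site_j `PigmentSite` objects.
#' @export
mg_mg_distance <- function(site_i, site_j) {
  if (is.null(site_i$mg) || is.null(site_j$mg)) stop("site lacks Mg position")
  sqrt(sum((site_i$mg - site_j$mg)^2))
}

#' Minimum inter-residue atom distance
#'
#' @param model A `StructureModel`.
#' @param res_i,res_j Residue selectors: list(chain=, resnum=, inscode="")
#' @param atom_filter `"all"`, `"heavy"` (exclude hydrogens) or
#'   `"sidechain"` (heavy atoms beyond the backbone N/CA/C/O).
#' @return Minimum pairwise distance in Angstrom.
#' @export
min_residue_distance <- function(model, res_i, res_j,
                                 atom_filter = c("heavy", "all",
                                                 "sidechain")) {
  atom_filter <- match.arg(atom_filter)
  pick <- function(sel) {
    a <- model$atoms
    ins <- if (is.null(sel$inscode)) "" else sel$inscode
    r <- a[a$chain == sel$chain & a$resnum == sel$resnum &
             a$inscode == ins, , drop = FALSE]
    if (!nrow(r)) {
      stop("residue not found: ", sel$chain, "/", sel$resnum)
    }
    if (atom_filter %in% c("heavy", "sidechain")) {
      r <- r[!(toupper(r$element) %in% c("H", "D")), , drop = FALSE]
    }
    if (atom_filter == "sidechain") {
      r <- r[!(r$atom %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
    }
    if (!nrow(r)) stop("no atoms left after filter for residue ",
                       sel$chain, "/", sel$resnum)
    as.matrix(r[, c("x", "y", "z")])
  }
  pi_ <- pick(res_i); pj <- pick(res_j)
  d2 <- outer(rowSums(pi_^2), rowSums(pj^2), "+") - 2 * pi_ %*% t(pj)
  sqrt(max(0, min(d2)))
}

#' Axial ligand of a chlorophyll's central Mg
#'
#' Finds the nearest candidate donor atom (N, O or S of any residue other
#' than the chlorin itself, including waters and other cofactors) within
#' `cutoff` of the Mg.
#'
#' @param site A `PigmentSite`.
#' @param model The parent `StructureModel`.
#' @param cutoff Angstrom (default 3.0, covering His-NE2 and Asn-OD1
#'   coordination).
#' @return A `LigandCall` list: `site_id`, `ligand` (chain/resnum/resname or
#'   NULL), `donor_atom`, `distance_A`.
#' @export
axial_ligand <- function(site, model, cutoff = 3.0) {
  a <- model$atoms
  own <- a$chain == site$chain & a$resnum == site$resnum
  cand <- a[!own & toupper(a$element) %in% c("N", "O", "S"), , drop = FALSE]
  if (!nrow(cand)) {
    return(list(site_id = site$site_id, ligand = NULL,
                donor_atom = NA_character_, distance_A = NA_real_))
  }
  d <- sqrt((cand$x - site$mg[1])^2 + (cand$y - site$mg[2])^2 +
              (cand$z - site$mg[3])^2)
  k <- which.min(d)
  if (d[k] > cutoff) {
    return(list(site_id = site$site_id, ligand = NULL,
                donor_atom = NA_character_, distance_A = NA_real_))
  }
  list(site_id = site$site_id,
       ligand = list(chain = cand$chain[k], resnum = cand$resnum[k],
                     resname = cand$resname[k]),
       donor_atom = cand$atom[k],
       distance_A = d[k])
}

#' All chlorophyll pairs within an Mg-Mg cutoff
#'
#' @param siteset A `PigmentSiteSet` (or plain list of sites).
#' @param mg_cutoff Angstrom (default 12).
#' @return data.frame (site_i, site_j, distance_A) sorted by distance
#'   ascending, ties by site ids.
#' @export
find_chl_pairs <- function(siteset, mg_cutoff = 12.0) {
  sites <- as_site_list(siteset)
  n <- length(sites)
  empty <- data.frame(site_i = character(), site_j = character(),
                      distance_A = numeric(), stringsAsFactors = FALSE)
  if (n < 2 || mg_cutoff <= 0) return(empty)
  mg <- t(vapply(sites, `[[`, numeric(3), "mg"))
  ids <- vapply(sites, `[[`, "", "site_id")
  d <- as.matrix(stats::dist(mg))
  idx <- which(upper.tri(d) & d <= mg_cutoff, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  out <- data.frame(site_i = ids[idx[, 1]], site_j = ids[idx[, 2]],
                    distance_A = d[idx], stringsAsFactors = FALSE)
  out <- out[order(out$distance_A, out$site_i, out$site_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_site_list <- function(x) {
  if (inherits(x, "PigmentSiteSet")) x$sites else x
}

#' Clusters of near-parallel stacked chlorins
#'
#' Builds the graph whose edges join site pairs with Mg-Mg distance at most
#' `mg_cutoff` and ring-plane normals within `max_angle` degrees (angles
#' folded to [0, 90] so antiparallel normals count as parallel stacking),
#' and returns its connected components of size >= 2.
#'
#' @param siteset A `PigmentSiteSet` or site list.
#' @param mg_cutoff Angstrom.
#' @param max_angle Degrees (default 30).
#' @return List of character vectors of site ids.
#' @export
find_parallel_clusters <- function(siteset, mg_cutoff = 12.0,
                                   max_angle = 30) {
  sites <- as_site_list(siteset)
  if (length(sites) < 2) return(list())
  ids <- vapply(sites, `[[`, "", "site_id")
  normals <- t(vapply(sites, ring_plane_normal, numeric(3)))
  pairs <- find_chl_pairs(sites, mg_cutoff)
  if (!nrow(pairs)) return(list())
  i <- match(pairs$site_i, ids); j <- match(pairs$site_j, ids)
  cosang <- abs(rowSums(normals[i, , drop = FALSE] *
                          normals[j, , drop = FALSE]))
  ang <- acos(pmin(1, cosang)) * 180 / pi
  keep <- ang <= max_angle
  if (!any(keep)) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs$site_i[keep], to = pairs$site_j[keep]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  out <- split(ids, comp$membership)
  out <- out[vapply(out, length, 1L) >= 2]
  unname(lapply(out, sort))
}

#' Per-domain chlorophyll binding counts
#'
#' @param siteset A `PigmentSiteSet` or site list.
#' @param partition A `DomainPartition` (see [domain_partition()]) mapping
#'   every site id — or every chain — to a domain label.
#' @return List with `counts` (named integer per domain), `min_lhc`,
#'   `max_lhc` computed over domains other than `"core"`.
#' @export
binding_site_inventory <- function(siteset, partition) {
  sites <- as_site_list(siteset)
  lab <- vapply(sites, function(s) domain_of(partition, s), "")
  miss <- vapply(sites, `[[`, "", "site_id")[is.na(lab)]
  if (length(miss)) {
    stop("partition does not cover site(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  counts <- table(factor(lab, levels = unique(c(partition$labels, lab))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  lhc <- counts[names(counts) != "core"]
  list(counts = counts,
       min_lhc = if (length(lhc)) min(lhc) else NA_integer_,
       max_lhc = if (length(lhc)) max(lhc) else NA_integer_)
}
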