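## Synthetic pigment-protein fixtures with analytic ground truth.
## Chlorin-like residues carry the standard CLA/CHL atom names (MG, ring
## nitrogens NA/NB/NC/ND, meso carbons CHA-CHD) so the production reader,
## classifier and TrEsp template all resolve on them; geometry is exact by
## construction.

CHLORIN_LOCAL <- local({
  # (u, v) coordinates in the ring plane; Qy axis NB->ND along +u
  m <- rbind(
    MG  = c(0, 0),
    NB  = c(-2.05, 0), ND = c(2.05, 0),
    "NA" = c(0, 2.05), NC = c(0, -2.05),
    C3B = c(-3.40, 0), C3D = c(3.40, 0),
    CHA = c(2.4, 2.4), CHB = c(-2.4, 2.4),
    CHC = c(-2.4, -2.4), CHD = c(2.4, -2.4)
  )
  colnames(m) <- c("u", "v")
  m
})

chlorin_elements <- c(MG = "MG", NB = "N", ND = "N", "NA" = "N", NC = "N",
                      C3B = "C", C3D = "C",
                      CHA = "C", CHB = "C", CHC = "C", CHD = "C")

class_to_code <- c(chl_a = "CLA", chl_b = "CHL")

# one chlorin residue: center = Mg position, ex = Qy (NB->ND) unit vector,
# ey = in-plane unit vector orthogonal to ex
chlorin_atoms <- function(center, ex, ey, chain, resnum, class = "chl_a") {
  ex <- ex / sqrt(sum(ex^2)); ey <- ey / sqrt(sum(ey^2))
  if (abs(sum(ex * ey)) > 1e-8) stop("ex and ey must be orthogonal")
  nm <- rownames(CHLORIN_LOCAL)
  pos <- CHLORIN_LOCAL[, "u"] %o% ex + CHLORIN_LOCAL[, "v"] %o% ey
  pos <- sweep(pos, 2, center, "+")
  data.frame(record = "HETATM", chain = chain, resnum = as.integer(resnum),
             inscode = "", resname = class_to_code[[class]], atom = nm,
             altloc = "", element = unname(chlorin_elements[nm]),
             x = pos[, 1], y = pos[, 2], z = pos[, 3], occupancy = 1,
             stringsAsFactors = FALSE)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

#' Two-chlorophyll fixture with a prescribed orientation factor
#'
#' Places two complete chlorin residues with Mg-Mg separation `R` along x
#' and Qy axes realizing the requested geometry: `"collinear"` (both along
#' the separation, kappa = -2), `"parallel"` (both perpendicular, kappa =
#' +1), `"perpendicular"` (one along the separation, one perpendicular,
#' kappa = 0), or `"angle"` (both perpendicular to the separation, rotated
#' by `angle_deg` about it, kappa = cos(angle)).
#'
#' @param R Mg-Mg distance in Angstrom (> 3).
#' @param kappa_target One of `"collinear"`, `"parallel"`,
#'   `"perpendicular"`, `"angle"`.
#' @param classes Length-2 character, pigment class per residue.
#' @param angle_deg Rotation for `kappa_target = "angle"`.
#' @return List with `model` (`StructureModel`), `truth` (list: `R_A`,
#'   `kappa`, per-site Qy directions).
#' @export
make_dimer_fixture <- function(R, kappa_target = c("collinear", "parallel",
                                                   "perpendicular", "angle"),
                               classes = c("chl_a", "chl_a"),
                               angle_deg = 0) {
  kappa_target <- match.arg(kappa_target)
  if (R <= 3) stop("R must exceed 3 Angstrom")
  ux <- c(1, 0, 0); uy <- c(0, 1, 0); uz <- c(0, 0, 1)
  geom <- switch(kappa_target,
    collinear     = list(e1 = ux, f1 = uy, e2 = ux, f2 = uy, kappa = -2),
    parallel      = list(e1 = uy, f1 = uz, e2 = uy, f2 = uz, kappa = 1),
    perpendicular = list(e1 = ux, f1 = uy, e2 = uy, f2 = uz, kappa = 0),
    angle = {
      th <- angle_deg * pi / 180
      list(e1 = uy, f1 = uz,
           e2 = cos(th) * uy + sin(th) * uz,
           f2 = -sin(th) * uy + cos(th) * uz,
           kappa = cos(th))
    })
  atoms <- rbind(
    chlorin_atoms(c(0, 0, 0), geom$e1, geom$f1, "A", 1, classes[1]),
    chlorin_atoms(c(R, 0, 0), geom$e2, geom$f2, "A", 2, classes[2])
  )
  list(model = new_structure_model(atoms),
       truth = list(R_A = R, kappa = geom$kappa,
                    qy_1 = geom$e1, qy_2 = geom$e2, classes = classes))
}

#' Two spatially separated pigment clusters with a labeled partition
#'
#' Cluster D sits near the origin, cluster A is displaced by `inter_gap`
#' along x; within a cluster, pigments are stacked along y with
#' `intra_spacing`, with small seeded positional jitter and random in-plane
#' Qy orientations.
#'
#' @param n_d,n_a Pigments per cluster (>= 1).
#' @param intra_spacing Angstrom between neighbours within a cluster.
#' @param inter_gap Angstrom between cluster origins; must be >=
#'   `intra_spacing`.
#' @param seed Integer RNG seed (fixture is reproducible byte-for-byte).
#' @param classes Pigment class used for every site.
#' @return List with `model`, `partition` (`DomainPartition`, labels `D` and
#'   `A`), `truth` (Mg positions and Qy axes per site).
#' @export
make_two_domain_cluster <- function(n_d, n_a, intra_spacing = 10,
                                    inter_gap = 30, seed = 1,
                                    classes = "chl_a") {
  stopifnot(n_d >= 1, n_a >= 1)
  if (inter_gap < intra_spacing) {
    stop("inter_gap must be at least intra_spacing (clusters overlap)")
  }
  build <- function(n, chain, x0) {
    lapply(seq_len(n), function(i) {
      center <- c(x0 + stats::runif(1, -1, 1),
                  (i - 1) * intra_spacing + stats::runif(1, -1, 1),
                  stats::runif(1, -1, 1))
      phi <- stats::runif(1, 0, 2 * pi)
      ex <- c(cos(phi), sin(phi), 0)
      ey <- c(-sin(phi), cos(phi), 0)
      list(atoms = chlorin_atoms(center, ex, ey, chain, i, classes),
           center = center, qy = ex)
    })
  }
  parts <- with_seed(seed, {
    list(d = build(n_d, "D", 0), a = build(n_a, "A", inter_gap))
  })
  atoms <- do.call(rbind, lapply(c(parts$d, parts$a), `[[`, "atoms"))
  list(
    model = new_structure_model(atoms),
    partition = domain_partition(c(D = "D", A = "A"), by = "chain"),
    truth = list(
      centers_d = lapply(parts$d, `[[`, "center"),
      centers_a = lapply(parts$a, `[[`, "center"),
      qy_d = lapply(parts$d, `[[`, "qy"),
      qy_a = lapply(parts$a, `[[`, "qy"),
      seed = seed)
  )
}

#' Census scene: known class counts, ligands, pairs and stacks
#'
#' Builds a structure whose census is known exactly: `counts` chlorophylls
#' and carotenoid-like residues on a sparse grid (default spacing 20 A, so
#' no incidental pairs), an optional parallel stack of chlorins, and
#' optional protein residues placing a donor atom at a stated distance from
#' a chosen Mg.
#'
#' @param counts Named integer vector over pigment classes (chl classes get
#'   full chlorin geometry; other classes get simple carbon-chain residues
#'   with their default component codes).
#' @param stack_n If > 0, adds `stack_n` chlorins stacked along z with
#'   `stack_spacing` and parallel ring planes (they count toward no class in
#'   `counts`; they are extra `chl_a`).
#' @param stack_spacing Angstrom (default 9).
#' @param ligands List of lists: `target` (index of the chlorin, in
#'   placement order), `resname` (e.g. "HIS", "ASN"), `donor` (atom name),
#'   `element`, `distance` (A from the Mg).
#' @param seed RNG seed (orientation jitter).
#' @return List with `model` and `truth` (counts, stack ids, ligand calls).
#' @export
make_census_scene <- function(counts = c(chl_a = 3, chl_b = 1),
                              stack_n = 0, stack_spacing = 9,
                              ligands = list(), seed = 1) {
  stopifnot(all(counts >= 0))
  code_of <- function(class) {
    if (class %in% names(class_to_code)) return(class_to_code[[class]])
    tab <- default_cofactor_table()
    hit <- names(tab)[tab == class]
    if (!length(hit)) stop("no component code for class ", class)
    hit[1]
  }
  atoms <- list()
  chl_ids <- character()
  grid_i <- 0
  place <- function() {
    grid_i <<- grid_i + 1
    c(20 * ((grid_i - 1) %% 8), 20 * ((grid_i - 1) %/% 8), 0)
  }
  resnum <- 0
  out <- with_seed(seed, {
    for (class in names(counts)) {
      for (i in seq_len(counts[[class]])) {
        resnum <- resnum + 1
        center <- place()
        if (class %in% c("chl_a", "chl_b")) {
          phi <- stats::runif(1, 0, 2 * pi)
          ex <- c(cos(phi), sin(phi), 0); ey <- c(-sin(phi), cos(phi), 0)
          atoms[[length(atoms) + 1]] <-
            chlorin_atoms(center, ex, ey, "X", resnum, class)
          chl_ids <- c(chl_ids,
                       sprintf("X:%d:%s", resnum, class_to_code[[class]]))
        } else {
          # 5-carbon chain stand-in for carotenoid/quinone/lipid residues
          atoms[[length(atoms) + 1]] <- data.frame(
            record = "HETATM", chain = "X", resnum = as.integer(resnum),
            inscode = "", resname = code_of(class),
            atom = paste0("C", 1:5), altloc = "", element = "C",
            x = center[1] + 1.5 * (0:4), y = center[2], z = center[3],
            occupancy = 1, stringsAsFactors = FALSE)
        }
      }
    }
    stack_ids <- character()
    for (s in seq_len(stack_n)) {
      resnum <- resnum + 1
      atoms[[length(atoms) + 1]] <-
        chlorin_atoms(c(200, 200, (s - 1) * stack_spacing),
                      c(1, 0, 0), c(0, 1, 0), "S", resnum, "chl_a")
      stack_ids <- c(stack_ids, sprintf("S:%d:CLA", resnum))
    }
    ligand_truth <- list()
    for (lg in ligands) {
      resnum <- resnum + 1
      target_id <- chl_ids[lg$target]
      mg <- atoms[[lg$target]][atoms[[lg$target]]$atom == "MG",
                               c("x", "y", "z")]
      el <- if (is.null(lg$element)) substr(lg$donor, 1, 1) else lg$element
      atoms[[length(atoms) + 1]] <- data.frame(
        record = "ATOM", chain = "P", resnum = as.integer(resnum),
        inscode = "", resname = lg$resname,
        atom = c("CB", lg$donor), altloc = "",
        element = c("C", el),
        x = as.numeric(mg$x) + c(0, 0),
        y = as.numeric(mg$y) + c(0, 0),
        z = as.numeric(mg$z) + c(lg$distance + 1.5, lg$distance),
        occupancy = 1, stringsAsFactors = FALSE)
      ligand_truth[[length(ligand_truth) + 1]] <-
        list(site_id = target_id, resname = lg$resname, donor = lg$donor,
             distance = lg$distance)
    }
    list(atoms = atoms, chl_ids = chl_ids, stack_ids = stack_ids,
         ligand_truth = ligand_truth)
  })
  list(model = new_structure_model(do.call(rbind, out$atoms)),
       truth = list(counts = counts, chl_ids = out$chl_ids,
                    stack_ids = out$stack_ids,
                    ligands = out$ligand_truth, seed = seed))
}

#' Write a fixture to disk as mmCIF plus a JSON ground-truth sidecar
#'
#' @param fixture A list with elements `model` and `truth` as returned by
#'   the `make_*` fixture generators.
#' @param path Output mmCIF path; the sidecar is written next to it with
#'   extension `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(fixture, path) {
  write_mmcif(fixture$model, path)
  jsonlite::write_json(fixture$truth,
                       paste0(tools::file_path_sans_ext(path),
                              ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
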