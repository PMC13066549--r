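#' Read an atomic model from an mmCIF or PDB file
#'
#' Parses the `_atom_site` category of a PDBx/mmCIF file, or the fixed-column
#' ATOM/HETATM records of a PDB file, into a flat atom table. All polymer and
#' non-polymer residues are retained. Alternate conformers are resolved
#' deterministically: for each (chain, resnum, inscode, atom name) key the
#' highest-occupancy conformer is kept, ties broken by the alphabetically
#' first alt-loc label.
#'
#' @param path Path to the coordinate file.
#' @param format One of `"auto"`, `"mmcif"`, `"pdb"`. `"auto"` decides from
#'   the file extension (`.cif`/`.mmcif` vs `.pdb`/`.ent`), falling back to
#'   content sniffing.
#' @return A `StructureModel`: a list with element `atoms`, a data.frame with
#'   columns `record` ("ATOM"/"HETATM"), `chain`, `resnum`, `inscode`,
#'   `resname`, `atom`, `altloc`, `element`, `x`, `y`, `z`, `occupancy`.
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        head1 <- readLines(path, n = 1L, warn = FALSE)
        if (length(head1) && grepl("^data_", head1)) "mmcif" else "pdb"
      }
  }
  atoms <- switch(format,
    mmcif = parse_mmcif_atoms(path),
    pdb   = parse_pdb_atoms(path)
  )
  new_structure_model(atoms)
}

#' Build a StructureModel from an atom table
#'
#' Programmatic constructor (the file readers funnel through it): validates
#' coordinates, rejects duplicate atom keys and applies the deterministic
#' alt-loc policy.
#'
#' @param atoms data.frame with the columns documented in
#'   [read_structure()]; missing `record`/`altloc`/`inscode`/`occupancy`
#'   columns are filled with defaults.
#' @return A `StructureModel`.
#' @export
structure_model <- function(atoms) {
  defaults <- list(record = "HETATM", inscode = "", altloc = "",
                   occupancy = 1, element = "")
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  new_structure_model(atoms)
}

new_structure_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms)) {
    bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
    if (any(bad)) stop("non-finite coordinates for ", sum(bad), " atom(s)")
    key <- paste(atoms$chain, atoms$resnum, atoms$inscode,
                 atoms$altloc, atoms$atom, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop("duplicate atom key (chain/resnum/altloc/atom): ",
           gsub("\r", "/", d))
    }
    atoms <- select_altloc(atoms)
    atoms <- atoms[order(atoms$chain, atoms$resnum, atoms$inscode), ,
                   drop = FALSE]
    rownames(atoms) <- NULL
  }
  structure(list(atoms = atoms), class = "StructureModel")
}

# highest occupancy wins; ties broken by first altloc label alphabetically
select_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resnum, atoms$inscode, atoms$atom,
               sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

#' @export
print.StructureModel <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("StructureModel: %d atoms, %d residues, %d chains\n",
              nrow(x$atoms), length(unique(rk)),
              length(unique(x$atoms$chain))))
  invisible(x)
}

residue_keys <- function(model) {
  a <- model$atoms
  if (!nrow(a)) return(character())
  paste(a$chain, a$resnum, a$inscode, sep = "\r")
}

#' List residues of a model
#'
#' @param model A `StructureModel`.
#' @return data.frame with one row per residue: `chain`, `resnum`, `inscode`,
#'   `resname`, `record`, `n_atoms`.
#' @export
structure_residues <- function(model) {
  a <- model$atoms
  if (!nrow(a)) {
    return(data.frame(chain = character(), resnum = integer(),
                      inscode = character(), resname = character(),
                      record = character(), n_atoms = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- residue_keys(model)
  first <- !duplicated(key)
  out <- a[first, c("chain", "resnum", "inscode", "resname", "record")]
  out$n_atoms <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
}

## ---- mmCIF parsing -------------------------------------------------------

# Tokenize one mmCIF data line, honouring single/double quotes.
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character())
  tok <- regmatches(line, list(m))[[1]]
  tok <- sub("^'(.*)'$", "\\1", tok)
  sub('^"(.*)"$', "\\1", tok)
}

parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  fields <- character()
  rows <- list()
  while (i <= n) {
    line <- lines[[i]]
    if (grepl("^\\s*loop_\\s*$", line)) {
      # collect header of this loop
      j <- i + 1L
      hdr <- character()
      while (j <= n && grepl("^\\s*_", lines[[j]])) {
        hdr <- c(hdr, sub("^\\s*(_\\S+).*$", "\\1", lines[[j]]))
        j <- j + 1L
      }
      if (length(hdr) && all(startsWith(hdr, "_atom_site."))) {
        fields <- sub("^_atom_site\\.", "", hdr)
        # collect data lines until next category/loop/comment-only structure
        k <- j
        buf <- character()
        while (k <= n) {
          dl <- lines[[k]]
          if (grepl("^\\s*(loop_|_\\S|#|data_)", dl)) break
          if (startsWith(dl, ";")) {
            # multi-line value blocks are not expected in atom_site; skip block
            k <- k + 1L
            while (k <= n && !startsWith(lines[[k]], ";")) k <- k + 1L
            k <- k + 1L
            next
          }
          if (nzchar(trimws(dl))) buf <- c(buf, dl)
          k <- k + 1L
        }
        rows <- lapply(buf, cif_tokens)
        bad <- which(vapply(rows, length, 1L) != length(fields))
        if (length(bad)) {
          stop("mmCIF parse error in _atom_site: line '", buf[bad[1]],
               "' has ", length(rows[[bad[1]]]), " values, expected ",
               length(fields))
        }
        i <- k
        break
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(fields)) {
    # an empty-but-valid file (data_ block, no atom_site loop)
    if (!any(grepl("^data_", lines))) {
      stop("mmCIF parse error: no data_ block and no _atom_site loop in ",
           path)
    }
    return(empty_atom_table())
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- fields
  get <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% fields) return(mat[, nm])
    if (!is.null(alt) && alt %in% fields) return(mat[, alt])
    rep(default, nrow(mat))
  }
  altloc <- get("label_alt_id")
  altloc[altloc %in% c(".", "?") | is.na(altloc)] <- ""
  inscode <- get("pdbx_PDB_ins_code")
  inscode[inscode %in% c(".", "?") | is.na(inscode)] <- ""
  occ <- suppressWarnings(as.numeric(get("occupancy", default = "1")))
  occ[is.na(occ)] <- 1
  resnum <- suppressWarnings(as.integer(get("auth_seq_id", "label_seq_id")))
  if (anyNA(resnum)) stop("mmCIF parse error: non-integer auth_seq_id")
  data.frame(
    record    = get("group_PDB", default = "HETATM"),
    chain     = get("auth_asym_id", "label_asym_id"),
    resnum    = resnum,
    inscode   = inscode,
    resname   = get("label_comp_id", "auth_comp_id"),
    atom      = get("label_atom_id", "auth_atom_id"),
    altloc    = altloc,
    element   = get("type_symbol"),
    x         = as.numeric(mat[, "Cartn_x"]),
    y         = as.numeric(mat[, "Cartn_y"]),
    z         = as.numeric(mat[, "Cartn_z"]),
    occupancy = occ,
    stringsAsFactors = FALSE
  )
}

empty_atom_table <- function() {
  data.frame(record = character(), chain = character(), resnum = integer(),
             inscode = character(), resname = character(), atom = character(),
             altloc = character(), element = character(), x = numeric(),
             y = numeric(), z = numeric(), occupancy = numeric(),
             stringsAsFactors = FALSE)
}

## ---- PDB parsing ---------------------------------------------------------

parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[sel]
  if (!length(lines)) return(empty_atom_table())
  f <- function(from, to) trimws(substring(lines, from, to))
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("PDB parse error: malformed coordinate field at record ",
         which(is.na(x) | is.na(y) | is.na(z))[1])
  }
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    record    = f(1, 6),
    chain     = f(22, 22),
    resnum    = as.integer(f(23, 26)),
    inscode   = f(27, 27),
    resname   = f(18, 20),
    atom      = f(13, 16),
    altloc    = f(17, 17),
    element   = f(77, 78),
    x = x, y = y, z = z,
    occupancy = occ,
    stringsAsFactors = FALSE
  )
}

## ---- writing -------------------------------------------------------------

#' Write a StructureModel as minimal valid PDBx/mmCIF
#'
#' Emits a `data_` block with an `_atom_site` loop carrying the standard
#' columns; coordinates are written with 3 decimals, so round-trips preserve
#' geometry to 1e-3 Angstrom.
#'
#' @param model A `StructureModel`.
#' @param path Output path.
#' @param block_id Name for the data block.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(model, path, block_id = "eetnet") {
  a <- model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", block_id), "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.auth_asym_id",
               "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy"), con)
  if (nrow(a)) {
    alt <- ifelse(nzchar(a$altloc), a$altloc, ".")
    ins <- ifelse(nzchar(a$inscode), a$inscode, "?")
    writeLines(sprintf("%-6s %d %s %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f",
                       a$record, seq_len(nrow(a)), a$element, a$atom, alt,
                       a$resname, a$chain, a$chain, a$resnum, ins,
                       a$x, a$y, a$z, a$occupancy), con)
  }
  writeLines("#", con)
  invisible(path)
}
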