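#' Pigment / cofactor class vocabulary
#' @export
cofactor_classes <- c("chl_a", "chl_b", "carotenoid:diadinoxanthin",
                      "carotenoid:neoxanthin", "carotenoid:beta_carotene",
                      "quinone", "fes_cluster", "lipid", "other")

#' Default chemical-component -> pigment-class table
#'
#' Maps PDB chemical-component codes to the closed pigment-class vocabulary.
#' CLA (chlorophyll a), CHL (chlorophyll b) and BCR (beta-carotene) are
#' standard; the diadinoxanthin (DD6), neoxanthin (NEX), phylloquinone (PQN),
#' iron-sulfur (SF4) and thylakoid-lipid codes follow the PDB chemical
#' component dictionary but have not been reconciled against any particular
#' deposited entry — the table is config-driven precisely so it can be
#' overridden per structure with [read_cofactor_table()].
#'
#' @return A named character vector (code -> class) of class `CofactorTable`.
#' @export
default_cofactor_table <- function() {
  tab <- c(
    CLA = "chl_a",
    CHL = "chl_b",
    DD6 = "carotenoid:diadinoxanthin",
    NEX = "carotenoid:neoxanthin",
    BCR = "carotenoid:beta_carotene",
    PQN = "quinone",
    SF4 = "fes_cluster",
    LHG = "lipid", LMG = "lipid", SQD = "lipid", DGD = "lipid",
    PG  = "lipid"
  )
  as_cofactor_table(tab)
}

as_cofactor_table <- function(x) {
  stopifnot(is.character(x), !is.null(names(x)))
  if (anyDuplicated(names(x))) stop("duplicate component codes in table")
  bad <- setdiff(unique(x), cofactor_classes)
  if (length(bad)) stop("unknown pigment class(es): ",
                        paste(bad, collapse = ", "))
  structure(x, class = "CofactorTable")
}

#' Read / write a cofactor table as flat `code: class` text
#'
#' The format is one `CODE: class` pair per line; `#` starts a comment.
#'
#' @param path File path.
#' @return A `CofactorTable`.
#' @export
read_cofactor_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  m <- regmatches(lines, regexec("^(\\S+)\\s*:\\s*(\\S+)$", lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed cofactor-table line: ", lines[bad][1])
  tab <- vapply(m, `[[`, "", 3L)
  names(tab) <- vapply(m, `[[`, "", 2L)
  as_cofactor_table(tab)
}

#' @rdname read_cofactor_table
#' @param table A `CofactorTable` to serialize.
#' @export
write_cofactor_table <- function(table, path) {
  writeLines(sprintf("%s: %s", names(table), unname(table)), path)
  invisible(path)
}

#' Classify the cofactor residues of a structure
#'
#' Every residue whose chemical-component code appears in `table` is
#' classified; non-polymer (HETATM) residues with codes absent from the table
#' are reported in `unmapped`, never silently dropped. Standard amino acids
#' and waters are ignored.
#'
#' @param model A `StructureModel`.
#' @param table A `CofactorTable` (default [default_cofactor_table()]).
#' @return A `CofactorInventory`: list with `residues` (chain, resnum, code,
#'   class), `counts` (named integer per class present), `chain_counts`, and
#'   `unmapped` (data.frame of unclassified non-polymer residues).
#' @export
classify_cofactors <- function(model, table = default_cofactor_table()) {
  if (!length(table)) stop("cofactor table is empty")
  res <- structure_residues(model)
  hit <- res$resname %in% names(table)
  classified <- res[hit, c("chain", "resnum", "inscode", "resname")]
  names(classified)[names(classified) == "resname"] <- "code"
  classified$class <- unname(table[classified$code])
  rownames(classified) <- NULL
  amino <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
             "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
  water <- c("HOH", "WAT", "DOD")
  un <- res[!hit & res$record == "HETATM" &
              !(res$resname %in% c(amino, water)), , drop = FALSE]
  rownames(un) <- NULL
  counts <- table(factor(classified$class, levels = cofactor_classes))
  counts <- stats::setNames(as.integer(counts), cofactor_classes)
  chain_counts <- if (nrow(classified)) {
    as.data.frame(table(chain = classified$chain, class = classified$class),
                  stringsAsFactors = FALSE, responseName = "n")
  } else {
    data.frame(chain = character(), class = character(), n = integer())
  }
  chain_counts <- chain_counts[chain_counts$n > 0, , drop = FALSE]
  rownames(chain_counts) <- NULL
  structure(list(residues = classified, counts = counts,
                 chain_counts = chain_counts, unmapped = un),
            class = "CofactorInventory")
}

#' @export
print.CofactorInventory <- function(x, ...) {
  cat("CofactorInventory:", nrow(x$residues), "classified,",
      nrow(x$unmapped), "unmapped non-polymer residues\n")
  if (length(x$counts)) {
    for (cl in names(x$counts)) cat(sprintf("  %-28s %d\n", cl, x$counts[[cl]]))
  }
  invisible(x)
}
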