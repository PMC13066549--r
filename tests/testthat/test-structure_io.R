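test_that("fixture structures round-trip through mmCIF with geometry intact", {
  for (kind in c("dimer", "census")) {
    fix <- if (kind == "dimer") make_dimer_fixture(10, "collinear")
           else make_census_scene(counts = c(chl_a = 2, chl_b = 1),
                                  seed = 7)
    path <- withr::local_tempfile(fileext = ".cif")
    write_mmcif(fix$model, path)
    back <- read_structure(path, "mmcif")
    expect_equal(nrow(back$atoms), nrow(fix$model$atoms))
    expect_equal(nrow(structure_residues(back)),
                 nrow(structure_residues(fix$model)))
    orig <- fix$model$atoms[order(fix$model$atoms$chain,
                                  fix$model$atoms$resnum,
                                  fix$model$atoms$atom), ]
    got <- back$atoms[order(back$atoms$chain, back$atoms$resnum,
                            back$atoms$atom), ]
    expect_equal(got$atom, orig$atom)
    expect_lt(max(abs(got$x - orig$x), abs(got$y - orig$y),
                  abs(got$z - orig$z)), 1e-3)
  }
})

test_that("dimer fixture parses to 2 CLA residues; empty file to 0", {
  fix <- make_dimer_fixture(12, "parallel")
  path <- withr::local_tempfile(fileext = ".cif")
  write_mmcif(fix$model, path)
  m <- read_structure(path)
  res <- structure_residues(m)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$resname == "CLA"))

  empty <- withr::local_tempfile(fileext = ".cif")
  writeLines("data_empty\n#", empty)
  m0 <- read_structure(empty)
  expect_equal(nrow(structure_residues(m0)), 0L)
})

test_that("PDB fixed-column records parse and agree with mmCIF", {
  fix <- make_dimer_fixture(10, "collinear")
  a <- fix$model$atoms
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, seq_len(nrow(a)), a$atom, "", a$resname, a$chain, a$resnum,
    "", a$x, a$y, a$z, a$occupancy, 0, a$element), pdb)
  m <- read_structure(pdb, "pdb")
  expect_equal(nrow(m$atoms), nrow(a))
  s <- sites_of(m)
  expect_equal(mg_mg_distance(s[[1]], s[[2]]), 10, tolerance = 1e-3)
})

test_that("malformed input raises a parse error naming the problem", {
  bad <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site.group_PDB",
               "_atom_site.Cartn_x", "HETATM 1.0 extra_token"), bad)
  expect_error(read_structure(bad), "parse error")
  expect_error(read_structure(withr::local_tempfile(fileext = ".cif")),
               "not found")
})

test_that("alt-loc policy keeps highest occupancy, ties alphabetical", {
  cif <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_x", "loop_", "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy")
  rows <- c("HETATM 1 MG MG A CLA X 1 0.0 0.0 0.0 0.40",
            "HETATM 2 MG MG B CLA X 1 1.0 0.0 0.0 0.60",
            "HETATM 3 N NB A CLA X 1 2.0 0.0 0.0 0.50",
            "HETATM 4 N NB B CLA X 1 3.0 0.0 0.0 0.50")
  writeLines(c(hdr, rows, "#"), cif)
  m <- read_structure(cif)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$atom == "MG"], 1.0)  # occupancy 0.60 wins
  expect_equal(m$atoms$x[m$atoms$atom == "NB"], 2.0)  # tie -> altloc A
  # deterministic: same file, same selection
  expect_identical(read_structure(cif)$atoms, m$atoms)
})

test_that("duplicate atom keys and non-finite coordinates are rejected", {
  a <- make_dimer_fixture(8, "parallel")$model$atoms
  dup <- rbind(a, a[1, ])
  expect_error(structure_model(dup), "duplicate")
  bad <- a; bad$x[3] <- NaN
  expect_error(structure_model(bad), "finite")
})

test_that("classification is partition-complete and reports unmapped codes", {
  scene <- make_census_scene(
    counts = c(chl_a = 3, chl_b = 1,
               `carotenoid:diadinoxanthin` = 2), seed = 3)
  a <- scene$model$atoms
  # add a non-polymer residue with an unknown code
  a <- rbind(a, data.frame(record = "HETATM", chain = "Z", resnum = 1L,
                           inscode = "", resname = "XYZ", atom = "C1",
                           altloc = "", element = "C", x = 500, y = 0,
                           z = 0, occupancy = 1))
  m <- structure_model(a)
  inv <- classify_cofactors(m)
  expect_equal(inv$counts[["chl_a"]], 3L)
  expect_equal(inv$counts[["chl_b"]], 1L)
  expect_equal(inv$counts[["carotenoid:diadinoxanthin"]], 2L)
  expect_equal(inv$unmapped$resname, "XYZ")
  res <- structure_residues(m)
  nonpoly <- sum(res$record == "HETATM")
  expect_equal(nrow(inv$residues) + nrow(inv$unmapped), nonpoly)
  expect_equal(sum(inv$counts), nrow(inv$residues))
})

test_that("zero-cofactor model gives all-zero counts, empty unmapped", {
  m <- structure_model(data.frame(
    record = "ATOM", chain = "A", resnum = 1L, inscode = "",
    resname = "ALA", atom = c("N", "CA", "C"), altloc = "",
    element = c("N", "C", "C"), x = 1:3, y = 0, z = 0, occupancy = 1))
  inv <- classify_cofactors(m)
  expect_true(all(inv$counts == 0L))
  expect_equal(nrow(inv$unmapped), 0L)
})

test_that("cofactor table round-trips and rejects bad vocabulary", {
  tab <- default_cofactor_table()
  path <- withr::local_tempfile(fileext = ".cfg")
  write_cofactor_table(tab, path)
  back <- read_cofactor_table(path)
  expect_equal(unclass(back), unclass(tab))
  expect_error(eetnet:::as_cofactor_table(c(CLA = "nonsense_class")),
               "unknown pigment class")
})

test_that("export round-trips: rate matrix CSV, inventory JSON, graphml", {
  fix <- make_two_domain_cluster(2, 2, seed = 11)
  ss <- extract_pigment_sites(fix$model, classify_cofactors(fix$model))
  H <- build_hamiltonian(ss, method = "dipole")
  rm_ <- pairwise_rate_matrix(ss, H)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_tables(rm_, csv, "csv")
  back <- read_rate_matrix(csv, nodes = rm_$nodes)
  expect_lt(max(abs(back$k - rm_$k)) / max(rm_$k), 1e-9)

  inv <- classify_cofactors(fix$model)
  js <- withr::local_tempfile(fileext = ".json")
  export_tables(inv, js, "json")
  got <- jsonlite::read_json(js)
  expect_equal(got$counts$chl_a, 4L)

  binned <- bin_edges(rm_)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_tables(binned, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_true("bin" %in% igraph::edge_attr_names(g))
  expect_equal(igraph::ecount(g), nrow(binned))

  expect_error(export_tables(list(1), withr::local_tempfile(), "csv"),
               "unsupported")
})
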