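#!/usr/bin/env Rscript
# Census and geometry checks on the deposited supercomplex model.
# The coordinate files are not shipped (size) and cannot be fetched in an
# offline run; download them first:
#   curl -o data-raw/9vjs.cif https://files.rcsb.org/download/9VJS.cif
#   curl -o data-raw/8wgh.cif https://files.rcsb.org/download/8WGH.cif
# Then: Rscript scripts/census_9vjs.R [--model data-raw/9vjs.cif]

suppressPackageStartupMessages(library(eetnet))

args <- commandArgs(trailingOnly = TRUE)
model_path <- "data-raw/9vjs.cif"
i <- 1
while (i <= length(args)) {
  if (args[i] == "--model") { model_path <- args[i + 1]; i <- i + 2 }
  else stop("unknown argument: ", args[i])
}
if (!file.exists(model_path)) {
  stop("coordinate file not found: ", model_path,
       " (see header comment for the download command)")
}

model <- read_structure(model_path)
inv <- classify_cofactors(model)
print(inv)
cat("\nNormalized stoichiometry (per 100 Chl a):\n")
print(as.data.frame(pigment_ratio(inv)))

ss <- extract_pigment_sites(model, inv)
cat(sprintf("\nPigment sites: %d (skipped %d)\n", length(ss$sites),
            nrow(ss$skipped)))

cc <- inv$chain_counts
chl_chain <- tapply(cc$n[grepl("^chl", cc$class)],
                    cc$chain[grepl("^chl", cc$class)], sum)
lhc_chains <- names(chl_chain)[chl_chain >= 11 & chl_chain <= 15]
cat(sprintf("Antenna-sized chains (11-15 Chl): %d\n", length(lhc_chains)))
cat(sprintf("Chl a within those chains: %d\n",
            sum(cc$n[cc$class == "chl_a" & cc$chain %in% lhc_chains])))
cat(sprintf("Carotenoids within those chains: %d\n",
            sum(cc$n[grepl("^carotenoid", cc$class) &
                       cc$chain %in% lhc_chains])))

cat("\nAxial ligands of the first 10 sites:\n")
for (s in head(ss$sites, 10)) {
  lg <- axial_ligand(s, model)
  cat(sprintf("  %s -> %s %s (%.2f A)\n", s$site_id,
              if (is.null(lg$ligand)) "none" else lg$ligand$resname,
              if (is.null(lg$ligand)) "" else lg$donor_atom,
              if (is.null(lg$ligand)) NA else lg$distance_A))
}
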