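#!/usr/bin/env Rscript
# ZPE-corrected reaction profiles on the forsterite surfaces.
#
# Calibrated fixtures reproduce the published Delta H(0 K) landmarks of the
# HCN dimerization on the (120), (101) and (111) facets: the (120)BC
# two-step route (deprotonation then C-C coupling), the single-step (101)
# cases, and the (111)DE case whose product ends up *above* its transition
# state once ZPE corrections are applied — an inversion the profile
# validator flags against the ~4 kJ/mol DFT accuracy.

suppressPackageStartupMessages(library(surfkin))
dir.create("results", showWarnings = FALSE)

specs <- profile_case_specs()
surface_cases <- setdiff(names(specs), "gas")
rows <- list(); flag_rows <- list()
for (nm in surface_cases) {
  prof <- build_profile(generate_reaction_case(specs[[nm]])$path,
                        "bhlyp//pbe")
  cat("\n==", nm, "==\n")
  print(prof$steps, row.names = FALSE)
  fl <- validate_profile(prof, tolerance = 4)
  if (nrow(fl) > 0) {
    fl$case <- nm
    flag_rows[[nm]] <- fl
    for (i in which(fl$type == "inversion"))
      cat(sprintf("  ! TS/product inversion: gap %.1f kJ/mol (%s)\n",
                  fl$gap[i], fl$severity[i]))
  }
  nd <- prof$nodes; nd$case <- nm
  rows[[nm]] <- nd
}

profiles <- do.call(rbind, rows)
write.table(profiles, "results/surface_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
flags <- do.call(rbind, flag_rows)
write.table(flags, "results/profile_flags.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nThe (111)DE inversion sits within DFT accuracy: that step is",
    "effectively barrierless-or-inverted, but strongly endothermic either",
    "way.\nwrote results/surface_profiles.tsv, results/profile_flags.tsv\n")
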