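#!/usr/bin/env Rscript
# The kinetics table: Gibbs barriers, RRKM rate constants and half-lives
# at 150/200/300 K for all six surface cases.
#
# The calibrated fixtures reproduce the published Gibbs energetics; the
# rate constants are then computed by this package's own canonical RRKM
# with the auto tunneling policy (Eckart correction on proton-transfer-like
# steps only). Rates below 1e-19 s^-1 render as 0 in the table, with
# infinite half-life.

suppressPackageStartupMessages(library(surfkin))

res <- run_pipeline(run_config(out_dir = "results/rate_table",
                               temperatures = c(150, 200, 300),
                               cases = "table1", tunnel = "auto",
                               method = "rrkm", grain = 5, seed = 1))
cat("Rendered rate table:\n\n")
writeLines(readLines("results/rate_table/rate_table.tsv"))
cat("\nReading the table: the (120)BC deprotonation is fast at every",
    "temperature; C-C bond formation on (101)BC is the fastest coupling",
    "channel (half-life ~2 minutes at 150 K), while every (111) channel",
    "is frozen below 300 K.\n")
cat("Outputs under results/rate_table/ (profiles, records, table,",
    "report.json).\n")
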