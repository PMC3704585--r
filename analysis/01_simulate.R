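#!/usr/bin/env Rscript
# Generate the default synthetic surveillance scenario: 47 regions on a
# lattice, annual covariates 1965-2010 with declining TFR, case panels
# 1979-2010 from the catalytic force-of-infection model, and the linear
# panel used for estimator validation. Writes the panels under
# results/data/ in the CSV dialects the readers consume.

suppressPackageStartupMessages(library(kdpanel))
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sc <- scenario_config(seed = 1)
covs <- simulate_covariates(sc)
cat <- simulate_catalytic_cases(sc, covs)
lp <- simulate_linear_panel(sc, covs)

write.csv(covs$covariates, file.path(outdir, "covariates.csv"), row.names = FALSE)
write.csv(cat$cases, file.path(outdir, "cases.csv"), row.names = FALSE)
write.csv(cat$pop, file.path(outdir, "population.csv"), row.names = FALSE)
write.csv(cat$standard, file.path(outdir, "standard_structure.csv"), row.names = FALSE)
write.csv(covs$national_tfr, file.path(outdir, "national_tfr.csv"), row.names = FALSE)
edges <- which(covs$adjacency == 1 & upper.tri(covs$adjacency), arr.ind = TRUE)
write.csv(data.frame(from = rownames(covs$adjacency)[edges[, 1]],
                     to = colnames(covs$adjacency)[edges[, 2]]),
          file.path(outdir, "adjacency.csv"), row.names = FALSE)
write.csv(lp$panel, file.path(outdir, "linear_panel.csv"), row.names = FALSE)
jsonlite::write_json(cat$truth$foi, file.path(outdir, "truth_foi.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf("regions: %d, case years: %d-%d, total cases: %d",
                sc$n_regions, min(sc$case_years), max(sc$case_years),
                sum(cat$cases$count)))
message(sprintf("national TFR declines %.2f -> %.2f",
                covs$national_tfr$value[1], tail(covs$national_tfr$value, 1)))
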