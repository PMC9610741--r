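#!/usr/bin/env Rscript
# Boltzmann energetics of the binding modes: convert the AFM population
# weights into an energy diagram (most populated mode at 0) and compute the
# allowed transition path under the mode-region adjacency from the contact
# analysis.

source("analysis/common.R")
suppressPackageStartupMessages(library(jsonlite))

afm <- make_afm_study()
fit <- run_afm_branch(afm$fields, K = 3, seed = afm$seed)$fit
diagram <- boltzmann_energies(fit$weights, temperature_K = 295)

# region adjacency from the planted mode contact sets on the toy globule
protein <- make_toy_protein(134, seed = STUDY_SEED)
sets <- lapply(default_mode_specs(), `[[`, "contact_residues")
adj <- matrix("overlapping", 3, 3)
for (i in 1:2) for (j in (i + 1):3) {
  adj[i, j] <- adj[j, i] <- region_overlap(sets[[i]], sets[[j]], protein)
}
path <- transition_path(diagram, adj)

print(diagram)
cat(sprintf("dE(1->2) = %.3f kJ/mol; dE(2->3) = %.3f kJ/mol; ratio %.2f\n",
            diagram$delta[1, 2], diagram$delta[2, 3],
            diagram$delta[2, 3] / diagram$delta[1, 2]))
cat("adjacency (1,2):", adj[1, 2], " (2,3):", adj[2, 3],
    " (1,3):", adj[1, 3], "\n")
cat("transition path 1 -> 3:", paste(path$path, collapse = " -> "),
    sprintf("(uphill cost %.3f kJ/mol)\n", path$cost_kJmol))

write_json(list(
  temperature_K = diagram$temperature_K,
  populations = diagram$populations,
  energies_kJmol = diagram$energies_kJmol,
  energies_kT = diagram$energies_kT,
  adjacency = adj, transition_path = path$path,
  uphill_cost_kJmol = path$cost_kJmol),
  "results/energy_diagram.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("diagram -> results/energy_diagram.json\n")
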