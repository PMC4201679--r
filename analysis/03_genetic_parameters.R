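#!/usr/bin/env Rscript
# Stage 3 — variance components from the full data.
#
# Fits the conventional animal model y = Xb + Za + e (fixed sex and hatch;
# pedigree relationship matrix A) by AI-REML for each trait on the full
# phenotype data, the analogue of the study's genetic-parameter table.
# Writes results/genetic_parameters.csv.

library(chickgp)

ped <- read_pedigree("results/population/pedigree.csv")
ph_all <- read_phenotypes("results/population/phenotypes.csv")
A <- pedigree_a_matrix(ped)

rows <- lapply(split(ph_all, ph_all$trait), function(ph) {
  des <- design_spec(ph$y, ph$id, ph$sex, ph$hatch, k_ids = rownames(A))
  vc <- ai_reml(des, A)
  data.frame(trait = ph$trait[1],
             sigma_a2 = vc$sigma_a2, sigma_e2 = vc$sigma_e2,
             h2 = vc$h2, h2_se = vc$h2_se,
             converged = vc$converged, iterations = vc$iterations)
})
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
print(tab, digits = 3)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/genetic_parameters.csv", row.names = FALSE)
cat("Variance components written to results/genetic_parameters.csv\n")
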