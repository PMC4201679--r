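#!/usr/bin/env Rscript
# Stage 1 — simulate the study population.
#
# Builds the synthetic analogue of the three-generation intercross: two
# divergent founder lines (10 birds each), 51 F1, and 511 F2 birds in 8
# half-sib sire families, genotyped at a desk-scale panel of 5,000 SNPs on
# 10 chromosomes, with all five traits (BW6, BW12, EP, BMP, LMP) simulated
# at their design heritabilities. Writes the population as plain-text
# files under results/population/.

library(chickgp)

seed <- 20260929
out <- "results/population"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pop <- simulate_population(n_per_line = 10, n_snps = 5000,
                           n_chromosomes = 10, map_length_cm = 100,
                           divergence = 0.3,
                           n_f1 = 51, n_sires_f1 = 8, n_f2 = 511,
                           traits = chicken_traits(n_qtl = 200), seed = seed)
print(pop)

write_pedigree(pop$pedigree, file.path(out, "pedigree.csv"))
write_genotypes(pop$genotypes, file.path(out, "genotypes.tsv"))
write_phenotypes(pop$phenotypes, file.path(out, "phenotypes.csv"))

fam <- table(pop$family)
cat(sprintf("Half-sib family sizes: %s (total F2 = %d)\n",
            paste(sort(fam, decreasing = TRUE), collapse = ", "), sum(fam)))
for (tr in names(pop$phenotypes)) {
  ph <- pop$phenotypes[[tr]]
  cat(sprintf("%-5s mean %8.2f sd %7.2f realized h2 %.3f\n", tr,
              mean(ph$y), sd(ph$y), var(ph$tbv) / var(ph$y)))
}
cat("Population files written to", out, "\n")
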