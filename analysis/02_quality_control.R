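#!/usr/bin/env Rscript
# Stage 2 — SNP quality control.
#
# Applies the study's filters (call rate >= 95%, MAF >= 0.01; the chip
# intensity filter is not computable from dosages) to the simulated panel
# and writes the QC'd genotypes plus a JSON report under results/.

library(chickgp)

geno <- read_genotypes("results/population/genotypes.tsv", format = "tsv")
print(geno)

qc <- filter_snps(geno, min_call_rate = 0.95, min_maf = 0.01)
print(qc$report)
qc_report_json(qc$report, "results/qc_report.json")
write_genotypes(qc$genotypes, "results/genotypes_qc.tsv")
cat("Retained", qc$report$n_retained, "of", qc$report$n_input, "SNPs\n")
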