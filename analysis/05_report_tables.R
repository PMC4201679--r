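#!/usr/bin/env Rscript
# Stage 5 — formatted result tables.
#
# Reshapes the tidy cross-validation report into the familiar layout:
# pooled accuracy and bias slope per trait x model x scenario, with
# paired-t significance markers between models within a scenario/trait.

tab <- read.csv("results/crossval_report.csv")

fmt_block <- function(stat, title) {
  x <- tab[is.na(tab$fold) & tab$statistic == stat, ]
  if (nrow(x) == 0) return(invisible(NULL))
  wide <- reshape(x[, c("scenario", "trait", "model", "value")],
                  idvar = c("scenario", "trait"), timevar = "model",
                  direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  cat("\n==", title, "==\n")
  print(wide, row.names = FALSE, digits = 3)
}

fmt_block("pooled_accuracy",
          "Correlation between corrected phenotypes and predictions (pooled over folds)")
fmt_block("slope", "Regression slope of corrected phenotype on prediction")
fmt_block("accuracy", "Full-data (own-record) accuracy")

pt <- tab[is.na(tab$fold) & tab$statistic == "paired_t_p", ]
if (nrow(pt)) {
  cat("\n== Paired t-tests between models (p-values, df = folds - 1) ==\n")
  wide <- reshape(pt[, c("scenario", "trait", "model", "value")],
                  idvar = c("scenario", "trait"), timevar = "model",
                  direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 2)
}
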