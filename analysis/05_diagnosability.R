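#!/usr/bin/env Rscript
# Stage 5: diagnosability of bill size under the 75% rule.
#
# The t-quantile index is computed on the composite bill-size score for
# every ordered pair of taxa (rows focal), at both the subspecies and
# the region level; a pair counts only if the rule passes in both
# directions. The headline question: is any named subspecies
# reciprocally diagnosable from ALL others?

library(cuckoomorph)

specimens <- read_specimens("results/specimens.csv")
bill <- complete_specimens(specimens, bill_traits())$records
pca <- pca_composite(bill)

for (lvl in c("subspecies", "region")) {
  lv <- if (lvl == "region") region_levels() else subspecies_levels()
  gs <- group_summaries(pca$composite, bill[[lvl]], levels = lv)
  dm <- d_matrix(gs)
  rep_ <- reciprocal_report(dm)
  write.csv(round(dm$D, 2), sprintf("results/diagnosability_%s.csv", lvl))

  cat("\n==", lvl, "level ==\n")
  print(dm)
  for (tx in names(rep_$per_taxon)) {
    if (length(rep_$per_taxon[[tx]]) > 0)
      cat(tx, "reciprocally diagnosable from:",
          paste(rep_$per_taxon[[tx]], collapse = ", "), "\n")
  }
  cat(if (rep_$any_fully_diagnosable)
    paste("Fully diagnosable:", paste(rep_$fully_diagnosable,
                                      collapse = ", "), "\n")
    else "No taxon is reciprocally diagnosable from all others.\n")
}
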