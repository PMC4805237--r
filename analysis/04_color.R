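#!/usr/bin/env Rscript
# Stage 4: ventral color.
#
# The four ordinal color regions vary concordantly (Spearman), so breast
# color stands in for the ventral surface; the 75% rule is applied
# directly to the observed score distributions, in both directions for
# every pair.

library(cuckoomorph)

specimens <- read_specimens("results/specimens.csv")
colr <- complete_specimens(specimens, color_traits())$records

rho <- rank_correlations(colr)
write.csv(round(rho, 2), "results/color_spearman.csv")
cat("Spearman correlations among color regions range",
    sprintf("%.2f-%.2f\n", min(rho[upper.tri(rho)]),
            max(rho[upper.tri(rho)])))

for (lvl in c("subspecies", "region")) {
  lv <- if (lvl == "region") region_levels() else subspecies_levels()
  em <- empirical_75_matrix(colr$color_breast, colr[[lvl]], levels = lv)
  rep_ <- reciprocal_report(em)
  write.csv(round(em$D, 2), sprintf("results/color_rule_%s.csv", lvl))
  cat(sprintf("Breast color, %s level: %d reciprocally diagnosable pairs%s\n",
              lvl, rep_$n_reciprocal_pairs,
              if (rep_$any_fully_diagnosable)
                paste0("; fully diagnosable: ",
                       paste(rep_$fully_diagnosable, collapse = ", "))
              else "; no taxon separable from all others"))
}

# the palest subspecies against the darkest, both directions
m_vs_d <- empirical_75(colr$color_breast[colr$subspecies == "maynardi"],
                       colr$color_breast[colr$subspecies == "dominicae"])
d_vs_m <- empirical_75(colr$color_breast[colr$subspecies == "dominicae"],
                       colr$color_breast[colr$subspecies == "maynardi"])
cat(sprintf("maynardi outside the dominicae range: %.0f%%; reverse: %.0f%%\n",
            100 * m_vs_d$fraction_outside, 100 * d_vs_m$fraction_outside))
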