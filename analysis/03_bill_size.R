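#!/usr/bin/env Rscript
# Stage 3: multivariate structure of bill size.
#
# Sex screen (Pillai's trace, adjusted for subspecies), composite bill
# size (PC1 of the three bill measurements on the correlation scale),
# Mahalanobis outlier screen, complete-linkage clustering with a
# three-index vote on the number of clusters, and discriminant
# classification by region and by named subspecies.

library(cuckoomorph)

specimens <- read_specimens("results/specimens.csv")
bill <- complete_specimens(specimens, bill_traits())$records

sexed <- bill[bill$sex %in% c("male", "female"), ]
scr <- pillai_manova(sexed, bill_traits(), "sex", "subspecies")
cat(sprintf("Sex screen: Pillai = %.3f, F = %.2f, p = %.2f -> %s\n",
            scr$pillai, scr$approx_F, scr$p,
            if (scr$p > 0.05) "sexes pooled" else "dimorphism detected"))

pca <- pca_composite(bill)
cat(sprintf("PC1 carries %.1f%% of the variance; correlations with raw traits: %s\n",
            100 * pca$prop_var[1],
            paste(sprintf("%s %.2f", sub("_mm", "", names(pca$trait_correlations)),
                          pca$trait_correlations), collapse = ", ")))
write.csv(data.frame(specimen_id = names(pca$composite),
                     pc1 = unname(pca$composite)),
          "results/composite_bill_size.csv", row.names = FALSE)

scrn <- mahalanobis_screen(bill)
write.csv(scrn, "results/mahalanobis.csv", row.names = FALSE)
cat(sprintf("Largest squared Mahalanobis distance %.1f vs chi-square bound %.1f\n",
            max(scrn$d2), max(scrn$chi2_quantile)))

hc <- cluster_complete(bill)
ok <- optimal_k(hc, bill)
cat("Cluster votes:", paste(names(ok$votes), ok$votes, sep = "=",
                            collapse = ", "),
    "-> k =", ok$k_best, "\n")
cl <- cutree(hc, ok$k_best)
cc <- as.data.frame.matrix(table(bill$region, cl))
write.csv(cc, "results/cluster_counts.csv")
print(cc)

for (lvl in c("region", "subspecies")) {
  lv <- if (lvl == "region") region_levels() else subspecies_levels()
  fit <- lda_fit(bill, grouping = lvl, group_levels = lv)
  cat(sprintf("\nDFA by %s: axis 1 carries %.0f%% of between-group variance\n",
              lvl, 100 * fit$prop_between[1]))
  write.csv(round(unclass(fit$confusion), 2),
            sprintf("results/confusion_%s.csv", lvl))
}
cat("\nClassification matrices written (rows = actual, cols = predicted).\n")
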