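#!/usr/bin/env Rscript
# Stage 2: measurement repeatability.
#
# Seventeen specimens are measured and scored in two independent
# sessions (the museum protocol); repeatability is the intraclass
# correlation from a one-way ANOVA with specimen as the factor. The
# generator also emits each trait's expected repeatability r* so the
# estimate can be judged against truth — at n = 17 the estimate is
# noisy, which is exactly the small-sample regime of the original
# protocol.

library(cuckoomorph)

cfg <- build_config("clinal_step", seed = 1L)
specimens <- sample_specimens(cfg)
rp <- sample_repeats(specimens, k = 17)

summ <- repeatability_summary(rp)
summ$r_star <- unname(rp$r_star[summ$trait])
write.csv(summ, "results/repeatability.csv", row.names = FALSE)

cat("Repeatability from 17 twice-measured specimens:\n")
print(summ[, c("trait", "r", "r_star", "max_abs_diff", "mean_abs_diff")],
      row.names = FALSE, digits = 3)
cat("\nBill traits land in the moderate-to-high band; color scoring,\n")
cat("with its coarse ordinal scale, is consistently high.\n")
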