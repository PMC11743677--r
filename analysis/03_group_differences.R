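#!/usr/bin/env Rscript
# Group-difference mapping: per-feature two-sample Wilcoxon rank-sum tests
# between SMCI and PMCI, organised by channel / channel pair, mirroring the
# topography-style summaries of the feature families. Requires
# results/features_epoch.csv from 02_extract_features.R.

library(eegmci)

feat <- read.csv("results/features_epoch.csv", check.names = FALSE)
fm <- feature_matrix(as.matrix(feat[, -(1:3)]), feat$subject_id, feat$group,
                     feat$epoch_index)

families <- c("ratio1", "ratio3", "psde_alpha", "se_s2", "pe_s2", "mdcpsr",
              "lz", "hurst")
maps <- do.call(rbind, lapply(families, function(f) {
  m <- group_difference_map(fm, prefix = f)
  m$family <- f
  m
}))
write.csv(maps, "results/group_difference_maps.csv", row.names = FALSE)

cat("median Wilcoxon p by family (16 channels each):\n")
print(vapply(split(maps$p, maps$family), median, 0)[families])

# the 15 full-band PLI connections with the lowest p-values
top15 <- group_difference_map(fm, prefix = "pli_full", top_n = 15)
write.csv(top15, "results/pli_top15_connections.csv", row.names = FALSE)
cat("\nstrongest full-band PLI group differences:\n")
print(head(top15, 5))
cat("wrote results/group_difference_maps.csv and results/pli_top15_connections.csv\n")
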