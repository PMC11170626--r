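# All-pairs structural similarity under the four fingerprints, plus the
# activity-profile similarity - the quantitative backbone of the SAS
# analysis. For n compounds this is n(n-1)/2 comparisons per fingerprint
# (17,391 at n = 187, self-comparisons excluded).

source("analysis/00_common.R")

lib <- study_library()
pc <- count_pairs(length(lib))
message(sprintf("%d compounds: %d pairwise comparisons per fingerprint (%d with self)",
                length(lib), pc$without_self, pc$with_self))

pairs <- pairwise_similarity(lib)
stopifnot(nrow(pairs) == pc$without_self)

for (k in fingerprint_kinds()) {
  message(sprintf("  %-17s mean = %.4f  sd = %.4f", k,
                  mean(pairs[[k]]), sd(pairs[[k]])))
}

utils::write.csv(pairs, file.path(results_dir, "pairwise_similarity.csv"),
                 row.names = FALSE)
message("wrote results/pairwise_similarity.csv")
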