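# SAS maps: per-fingerprint structural thresholds (mean + 2 SD of the
# pairwise distribution), four-region classification of every pair, and
# the cross-fingerprint consensus lists - region II (smooth SAR) and
# region IV (pseudo-activity cliffs).

source("analysis/00_common.R")

lib <- study_library()
pairs <- study_pairs(lib)

thr <- sas_thresholds(pairs, activity_threshold = 0.1)
message("structural thresholds (mean + 2 SD):")
for (k in names(thr$structural)) {
  message(sprintf("  %-17s %.4f", k, thr$structural[[k]]))
}

cls <- classify_sas(pairs, thr)
print(sas_region_counts(cls))

cons2 <- consensus_pairs(cls, "II")
cons4 <- consensus_pairs(cls, "IV")
message(sprintf("consensus region II pairs: %d; region IV (pseudo-cliffs): %d",
                nrow(cons2), nrow(cons4)))
if (nrow(cons4)) {
  message("most structurally similar pseudo-cliff: ",
          cons4$name_i[1], " vs ", cons4$name_j[1],
          sprintf(" (structural %.3f, activity %.3f)",
                  cons4$mean_structural_similarity[1],
                  cons4$activity_similarity[1]))
}

utils::write.csv(cons2, file.path(results_dir, "consensus_region_II.csv"),
                 row.names = FALSE)
utils::write.csv(cons4, file.path(results_dir, "consensus_region_IV.csv"),
                 row.names = FALSE)
for (k in fingerprint_kinds()) {
  pts <- sas_points(cls, k)
  pts$name_i <- cls$name_i
  pts$name_j <- cls$name_j
  write_sas_html(pts, file.path(results_dir, paste0("sas_map_", k, ".html")),
                 title = paste("SAS map -", k))
}
message("wrote consensus CSVs and per-fingerprint SAS HTML maps under results/")
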