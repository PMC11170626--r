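# Activity-profile statistics: which epigenetic targets are hit most
# often, which compounds are single-target, and which compounds act on
# the largest number of targets.

source("analysis/00_common.R")

lib <- study_library()

tf <- target_frequency(lib)
message("15 most frequent targets:")
for (i in 1:15) {
  message(sprintf("  %-12s %d", tf$target[i], tf$n_compounds[i]))
}

st <- single_target_compounds(lib)
message(sprintf("single-target compounds: %d (most frequent: %s)",
                st$total,
                if (nrow(st$breakdown)) st$breakdown$target[1] else "none"))

mt <- multi_target_ranking(lib, k = 10)
message("top multi-target compounds:")
for (i in seq_len(min(5, nrow(mt)))) {
  message(sprintf("  %-18s %d targets", mt$name[i], mt$n_targets[i]))
}

utils::write.csv(tf, file.path(results_dir, "target_frequency.csv"),
                 row.names = FALSE)
utils::write.csv(st$breakdown,
                 file.path(results_dir, "single_target_breakdown.csv"),
                 row.names = FALSE)
utils::write.csv(mt, file.path(results_dir, "multi_target_ranking.csv"),
                 row.names = FALSE)
message("wrote results/target_frequency.csv, results/single_target_breakdown.csv, results/multi_target_ranking.csv")
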