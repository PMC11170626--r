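# Scaffold-diversity analysis: Bemis-Murcko scaffold frequencies, the
# top-10 coverage, and the cyclic-system-recovery curve whose AUC
# summarizes how evenly the library spreads over its scaffolds
# (0.5 = every compound its own scaffold, 1.0 = a single scaffold).

source("analysis/00_common.R")

lib <- study_library()
tab <- scaffold_table(lib, "ring_bearing_only")

message(sprintf("%d unique scaffolds over %d ring-bearing compounds (%d acyclic)",
                attr(tab, "n_unique_scaffolds"),
                sum(tab$count), attr(tab, "n_acyclic")))
message("ten most frequent scaffolds:")
top <- utils::head(as.data.frame(tab), 10)
for (i in seq_len(nrow(top))) {
  message(sprintf("  %5.2f%%  (n=%2d)  %s", 100 * top$fraction[i],
                  top$count[i], top$scaffold[i]))
}
message(sprintf("top-10 coverage: %.2f%%", 100 * top_k_coverage(tab, 10)))

cv <- csr_curve(tab)
message(sprintf("CSR AUC = %.4f", cv$auc))

utils::write.csv(as.data.frame(tab),
                 file.path(results_dir, "scaffold_table.csv"),
                 row.names = FALSE)
utils::write.csv(cv$points, file.path(results_dir, "csr_curve.csv"),
                 row.names = FALSE)
jsonlite::write_json(list(n_unique_scaffolds = attr(tab, "n_unique_scaffolds"),
                          top10_coverage = top_k_coverage(tab, 10),
                          csr_auc = cv$auc),
                     file.path(results_dir, "scaffold_summary.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote results/scaffold_table.csv, results/csr_curve.csv, results/scaffold_summary.json")
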