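# Chemical-space view: physicochemical descriptors, z-scored, embedded
# in 2-D with a seeded t-SNE. Pass a reference SMILES file (one SMILES
# per line, optional tab-separated id) as the first argument to overlay
# the library on a larger collection.

source("analysis/00_common.R")

ref_path <- commandArgs(trailingOnly = TRUE)[1]
ref <- if (!is.na(ref_path) && file.exists(ref_path)) {
  message("overlaying reference set: ", ref_path)
  read_smiles(ref_path)
} else NULL

lib <- study_library()
coords <- chem_space_map(lib, ref, perplexity = 30, max_iter = 1000,
                         seed = 42)
message(sprintf("embedded %d molecules using %d descriptors",
                nrow(coords), attr(coords, "n_descriptors")))

utils::write.csv(coords, file.path(results_dir, "chem_space.csv"),
                 row.names = FALSE)

# quick static view of the same coordinates
png(file.path(results_dir, "chem_space.png"), 800, 800)
plot(coords$x, coords$y,
     col = ifelse(coords$set_label == "library", "#d95f02", "#7570b3"),
     pch = 19, cex = 0.7, xlab = "t-SNE 1", ylab = "t-SNE 2",
     main = "Chemical space")
legend("topright", legend = unique(coords$set_label),
       col = c("#d95f02", "#7570b3")[seq_along(unique(coords$set_label))],
       pch = 19)
dev.off()
message("wrote results/chem_space.csv and results/chem_space.png")
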