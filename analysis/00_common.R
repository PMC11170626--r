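# Shared setup for the analysis scripts. Each numbered script can be run
# on its own from the repository root: Rscript analysis/0X_*.R
#
# The study library is the curated food-chemical database when its CSV is
# present under inst/extdata/; otherwise a synthetic stand-in at the same
# scale (187 compounds over 90 scaffolds, Zipf-distributed scaffold sizes)
# so every analysis runs end to end out of the box.

suppressMessages(library(epichem))

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

study_library <- function(seed = 2025) {
  csv <- file.path("inst", "extdata", "epi_food_chemical_database.csv")
  if (file.exists(csv)) {
    message("using curated database: ", csv)
    return(read_compound_db(csv))
  }
  message("curated database CSV not found; using the synthetic stand-in ",
          "(187 compounds, 90 scaffolds, seed ", seed, ")")
  generate_library(synthetic_spec(n_compounds = 187, n_scaffolds = 90,
                                  scaffold_concentration = 1, seed = seed))
}

study_pairs <- function(lib) {
  cache <- file.path(results_dir, "pairwise_similarity.csv")
  if (file.exists(cache)) {
    tab <- utils::read.csv(cache, check.names = FALSE,
                           colClasses = c(id_i = "character",
                                          id_j = "character"))
    if (nrow(tab) == length(lib) * (length(lib) - 1) / 2) return(tab)
  }
  pairwise_similarity(lib)
}
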