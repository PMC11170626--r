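# Build (or load) the study library, validate it, and record the basic
# activity-population census: how many compounds carry protein-resolved
# activity, how many only family-level flags, and how many are
# profile-incomplete.

source("analysis/00_common.R")

lib <- study_library()
print(lib)

s <- activity_summary(lib)
message(sprintf("specific activity: %d/%d compounds; general-only: %d; incomplete: %d",
                s$n_specific, s$n_compounds, s$n_general_only,
                s$n_profile_incomplete))

write_compound_db(lib, file.path(results_dir, "library.csv"))
jsonlite::write_json(s, file.path(results_dir, "library_summary.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote results/library.csv and results/library_summary.json")
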