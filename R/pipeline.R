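# End-to-end orchestration: validate -> fingerprints -> scaffolds/CSR ->
# profiles -> SAS -> embedding -> report, under one declarative config,
# with a machine-readable manifest (content hashes) for reproducibility.

#' Pipeline configuration
#'
#' Either \code{input} (a database CSV path) or \code{synthetic} (a
#' [synthetic_spec()]) must be supplied. The whole configuration is
#' serialized into the run manifest.
#'
#' @param input path to a database CSV, or \code{NULL}.
#' @param synthetic a [synthetic_spec()], or \code{NULL}.
#' @param out_dir output directory.
#' @param column_map see [default_column_map()].
#' @param kinds fingerprint kinds to compute.
#' @param denominator scaffold-fraction convention, see [scaffold_table()].
#' @param activity_threshold SAS activity cut.
#' @param reference optional reference SMILES file for the chemical-space
#'   overlay.
#' @param perplexity,max_iter t-SNE parameters.
#' @param seed global seed (drives the embedding; synthetic input
#'   carries its own seed).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            out_dir = "epichem_out",
                            column_map = default_column_map(),
                            kinds = fingerprint_kinds(),
                            denominator = "ring_bearing_only",
                            activity_threshold = 0.1,
                            reference = NULL,
                            perplexity = 30, max_iter = 500, seed = 42) {
  if (is.null(input) && is.null(synthetic)) {
    stop("config invalid: supply either 'input' or 'synthetic'")
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("config invalid: input file not found: ", input)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  if (!is.null(reference) && !file.exists(reference)) {
    stop("config invalid: reference file not found: ", reference)
  }
  structure(list(input = input, synthetic = synthetic, out_dir = out_dir,
                 column_map = column_map, kinds = kinds,
                 denominator = denominator,
                 activity_threshold = activity_threshold,
                 reference = reference, perplexity = perplexity,
                 max_iter = max_iter, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage, writes each stage's tables (CSV), the SAS HTML
#' maps, a \code{summary.json} and a \code{manifest.json} listing every
#' output with an MD5 content hash. A stage failure aborts the run with
#' the stage name; outputs written so far are kept next to a
#' \code{FAILED} marker file.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly; the summary is attached as the
#'   \code{summary} attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "validate"
  res <- tryCatch({
    lib <- if (!is.null(config$input)) {
      read_compound_db(config$input, config$column_map)
    } else {
      generate_library(config$synthetic)
    }

    stage <- "fingerprints"
    pairs <- pairwise_similarity(lib, config$kinds)

    stage <- "scaffolds"
    stab <- scaffold_table(lib, config$denominator)
    csr <- csr_curve(stab)

    stage <- "profiles"
    freq <- target_frequency(lib)
    singles <- single_target_compounds(lib)
    multi <- multi_target_ranking(lib, k = 10)
    asum <- activity_summary(lib)

    stage <- "sas"
    thr <- sas_thresholds(pairs, config$kinds,
                          activity_threshold = config$activity_threshold)
    cls <- classify_sas(pairs, thr)
    cons2 <- consensus_pairs(cls, "II")
    cons4 <- consensus_pairs(cls, "IV")
    counts <- sas_region_counts(cls)

    stage <- "embed"
    ref <- if (!is.null(config$reference)) read_smiles(config$reference)
    coords <- chem_space_map(lib, ref,
                             perplexity = config$perplexity,
                             max_iter = config$max_iter, seed = config$seed)

    stage <- "report"
    tables <- list(
      pairwise_similarity = pairs,
      scaffold_table = as.data.frame(stab),
      csr_points = csr$points,
      target_frequency = freq,
      single_target_breakdown = singles$breakdown,
      multi_target_ranking = multi,
      consensus_region_II = cons2,
      consensus_region_IV = cons4,
      embedding = coords)
    manifest <- write_report(tables, config$out_dir, formats = "csv")
    for (k in config$kinds) {
      p <- file.path(config$out_dir, paste0("sas_map_", k, ".html"))
      pts <- sas_points(cls, k)
      pts$name_i <- cls$name_i
      pts$name_j <- cls$name_j
      write_sas_html(pts, p, title = paste("SAS map -", k))
      manifest[nrow(manifest) + 1L, ] <- list(paste0("sas_map_", k), "html",
                                              p, nrow(pts))
    }
    summary <- list(
      n_compounds = asum$n_compounds,
      n_specific = asum$n_specific,
      n_general_only = asum$n_general_only,
      n_profile_incomplete = asum$n_profile_incomplete,
      n_unique_scaffolds = attr(stab, "n_unique_scaffolds"),
      n_acyclic = attr(stab, "n_acyclic"),
      csr_auc = csr$auc,
      top10_scaffold_coverage = top_k_coverage(stab, 10),
      structural_thresholds = as.list(thr$structural),
      region_counts = apply(counts, 1, as.list),
      n_consensus_region_II = nrow(cons2),
      n_consensus_region_IV = nrow(cons4),
      n_descriptors = attr(coords, "n_descriptors"),
      provenance = lib$provenance,
      seed = config$seed)
    sp <- file.path(config$out_dir, "summary.json")
    jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA)
    manifest[nrow(manifest) + 1L, ] <- list("summary", "json", sp, NA_integer_)
    manifest$md5 <- unname(tools::md5sum(manifest$path))
    mp <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(list(config = .serialize_config(config),
                              files = manifest),
                         mp, auto_unbox = TRUE, digits = NA)
    attr(manifest, "summary") <- summary
    manifest
  }, error = function(e) {
    writeLines(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

.serialize_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) out$synthetic <- unclass(out$synthetic)
  out$column_map <- NULL
  out
}
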