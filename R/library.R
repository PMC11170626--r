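#' Compound libraries
#'
#' The central container: a validated set of compound records, each with a
#' canonical SMILES, provenance metadata, a binary activity profile over
#' the panel's specific targets, and binary family-level ("general")
#' activity flags for compounds annotated without protein resolution.
#'
#' @param compounds data.frame with one row per compound and columns
#'   \code{compound_id} (unique integers), \code{name}, \code{smiles}
#'   (canonical), and optionally \code{inchi}, \code{inchikey},
#'   \code{food_sources}, \code{foodb_id}, \code{coconut_id}, \code{doi}.
#'   Missing cross-reference IDs are \code{NA}.
#' @param profile integer/numeric matrix, \code{nrow(compounds)} by
#'   \code{length(panel)}, entries in \{0, 1\}; columns named by target.
#' @param general binary matrix of family-level flags (may have 0 columns).
#' @param panel a [target_panel()].
#' @param provenance character scalar describing the source (file path or
#'   a \code{"synthetic(seed=...)"} tag).
#' @return An object of class \code{compound_library}.
#' @export
compound_library <- function(compounds, profile, general = NULL,
                             panel = default_target_panel(),
                             provenance = "in-memory") {
  stopifnot(is.data.frame(compounds),
            all(c("compound_id", "name", "smiles") %in% names(compounds)))
  n <- nrow(compounds)
  if (anyDuplicated(compounds$compound_id)) {
    stop("compound_id values must be unique")
  }
  profile <- as.matrix(profile)
  if (nrow(profile) != n || ncol(profile) != length(panel)) {
    stop("profile must be n_compounds x n_targets (",
         n, " x ", length(panel), ")")
  }
  if (!all(profile %in% c(0, 1))) stop("profile entries must be 0 or 1")
  storage.mode(profile) <- "integer"
  colnames(profile) <- panel$targets
  if (is.null(general)) {
    general <- matrix(0L, nrow = n, ncol = 0)
  } else {
    general <- as.matrix(general)
    if (nrow(general) != n) stop("general flags must have one row per compound")
    if (ncol(general) > 0 && !all(general %in% c(0, 1))) {
      stop("general flag entries must be 0 or 1")
    }
    storage.mode(general) <- "integer"
  }
  # a record with no specific activity and no family flag is retained but
  # marked profile-incomplete: its zeros mean "untested", not "inactive"
  zero_specific <- rowSums(profile) == 0
  zero_general <- if (ncol(general) > 0) rowSums(general) == 0 else rep(TRUE, n)
  compounds$profile_incomplete <- zero_specific & zero_general
  structure(list(compounds = compounds,
                 profile = profile,
                 general = general,
                 panel = panel,
                 provenance = provenance),
            class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  n <- nrow(x$compounds)
  n_spec <- sum(rowSums(x$profile) > 0)
  n_gen <- if (ncol(x$general) > 0) {
    sum(rowSums(x$profile) == 0 & rowSums(x$general) > 0)
  } else 0L
  cat(sprintf(paste0("compound_library: %d compounds over %d targets\n",
                     "  specific activity: %d | general-only: %d | profile-incomplete: %d\n",
                     "  provenance: %s\n"),
              n, length(x$panel), n_spec, n_gen,
              sum(x$compounds$profile_incomplete), x$provenance))
  invisible(x)
}

#' @export
length.compound_library <- function(x) nrow(x$compounds)

#' Extract the binary activity matrix of a library
#'
#' Returns the n x |panel| specific-activity matrix together with its row
#' margins (targets per compound) and column margins (compounds per
#' target). Family-level general flags are excluded: they lack protein
#' resolution and are reported separately.
#'
#' @param library a [compound_library()].
#' @return matrix with attributes \code{row_margin} and \code{col_margin}.
#' @export
activity_matrix <- function(library) {
  stopifnot(inherits(library, "compound_library"))
  m <- library$profile
  rownames(m) <- library$compounds$name
  structure(m, row_margin = rowSums(m), col_margin = colSums(m))
}

# 14-10-1 block pattern of an InChIKey
.inchikey_ok <- function(x) {
  grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}
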