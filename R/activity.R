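# Statistics over the binary multi-target activity profiles. All counts
# use the specific (protein-resolved) profile only; family-level general
# flags are reported separately because they lack protein resolution.

#' Target frequency ranking
#'
#' Number of compounds with reported activity per target, sorted
#' descending; ties keep panel order.
#'
#' @param x a [compound_library()] or a binary activity matrix with
#'   target columns.
#' @return data.frame \code{target}, \code{n_compounds}.
#' @export
target_frequency <- function(x) {
  m <- if (inherits(x, "compound_library")) activity_matrix(x) else as.matrix(x)
  counts <- colSums(m)
  ord <- order(-counts)            # stable: ties stay in panel order
  data.frame(target = colnames(m)[ord], n_compounds = as.integer(counts[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compounds active against exactly one target
#'
#' @param x a [compound_library()] or binary activity matrix.
#' @return list with \code{total} and \code{breakdown} (data.frame
#'   \code{target}, \code{n_compounds}, descending).
#' @export
single_target_compounds <- function(x) {
  m <- if (inherits(x, "compound_library")) activity_matrix(x) else as.matrix(x)
  if (nrow(m) == 0) {
    return(list(total = 0L,
                breakdown = data.frame(target = character(0),
                                       n_compounds = integer(0))))
  }
  single <- rowSums(m) == 1
  if (!any(single)) {
    return(list(total = 0L,
                breakdown = data.frame(target = character(0),
                                       n_compounds = integer(0))))
  }
  tgt <- colnames(m)[apply(m[single, , drop = FALSE], 1, which.max)]
  counts <- sort(table(tgt), decreasing = TRUE)
  list(total = sum(single),
       breakdown = data.frame(target = names(counts),
                              n_compounds = as.integer(counts),
                              row.names = NULL, stringsAsFactors = FALSE))
}

#' Top multi-target compounds
#'
#' Compounds ranked by the number of targets with reported activity,
#' descending; ties broken alphabetically by compound name.
#'
#' @param x a [compound_library()] or binary activity matrix with
#'   compound rownames.
#' @param k number of rows to return.
#' @return data.frame \code{name}, \code{n_targets}.
#' @export
multi_target_ranking <- function(x, k = 10) {
  stopifnot(k >= 1)
  m <- if (inherits(x, "compound_library")) activity_matrix(x) else as.matrix(x)
  nm <- rownames(m)
  if (is.null(nm)) nm <- paste0("compound_", seq_len(nrow(m)))
  rs <- rowSums(m)
  ord <- order(-rs, nm)
  utils::head(data.frame(name = nm[ord], n_targets = as.integer(rs[ord]),
                         row.names = NULL, stringsAsFactors = FALSE), k)
}

#' Activity-profile similarity of two compounds
#'
#' The Jaccard similarity of two binary profiles, sharing the
#' implementation (and the flagged all-zero convention) of [tanimoto()].
#'
#' @param row_i,row_j equal-length 0/1 vectors.
#' @return similarity in [0, 1].
#' @export
profile_similarity <- function(row_i, row_j) tanimoto(row_i, row_j)

#' Activity-population summary of a library
#'
#' @param library a [compound_library()].
#' @return list: \code{n_compounds}, \code{n_specific} (>= 1 specific
#'   target), \code{n_general_only} (family flags only),
#'   \code{n_profile_incomplete}.
#' @export
activity_summary <- function(library) {
  stopifnot(inherits(library, "compound_library"))
  spec <- rowSums(library$profile) > 0
  gen <- if (ncol(library$general) > 0) rowSums(library$general) > 0 else
    rep(FALSE, nrow(library$compounds))
  list(n_compounds = nrow(library$compounds),
       n_specific = sum(spec),
       n_general_only = sum(!spec & gen),
       n_profile_incomplete = sum(!spec & !gen))
}
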